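test_that("heterozygosities match hand-computed values", {
  ## all homozygous, one allele
  h <- heterozygosities(c(100, 100, 100), c(100, 100, 100))
  expect_equal(unname(h[c("ho", "he")]), c(0, 0))
  ## two A/B heterozygotes: Ho 1, He = (4/3) * 0.5
  h2 <- heterozygosities(c(100, 100), c(104, 104))
  expect_equal(unname(h2["ho"]), 1)
  expect_equal(unname(h2["he"]), 2 / 3, tolerance = 1e-12)
  ## missing genotypes are dropped
  h3 <- heterozygosities(c(100, NA, 100), c(104, 104, NA))
  expect_equal(unname(h3["n"]), 1)
  expect_identical(unname(heterozygosities(NA_integer_, NA_integer_)["ho"]),
                   NA_real_)
})

test_that("mean estimated He converges to Nei's unbiased value under HWE", {
  p <- c(0.5, 0.3, 0.2)
  n <- 24L
  target <- 1 - sum(p^2)  # the correction makes He unbiased for this
  set.seed(42)
  reps <- 400L
  hes <- replicate(reps, {
    g <- hweGenotypes(n, p)
    heterozygosities(g$a1, g$a2)[["he"]]
  })
  expect_lt(abs(mean(hes) - target), 3 * stats::sd(hes) / sqrt(reps))
})

test_that("Chakraborty null-allele estimator follows its closed form", {
  expect_equal(chakrabortyNull(0.4, 0.4), 0)
  expect_equal(chakrabortyNull(0, 0.3), 1)
  expect_equal(chakrabortyNull(0.053, 0.235), 0.632, tolerance = 5e-4)
  expect_true(is.na(chakrabortyNull(0, 0)))
  ## sign follows the heterozygote excess/deficit
  expect_lt(chakrabortyNull(0.875, 0.668), 0)
})

test_that("biallelic HWE enumeration matches a hand-enumerated array distribution", {
  ## genotype counts AA=1, AB=2, BB=1; allele counts (4,4)
  ## array weights over het counts {0,2,4}: 6, 48, 16 (total 70)
  p <- hweExact(c(1, 1, 1, 2), c(1, 2, 2, 2))
  expect_equal(p, 1)
  ## observed array all-homozygote (AA=2, BB=2): its weight 6/70 is the
  ## unique smallest, so the two-sided P is 6/70
  p2 <- hweExact(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(p2, 6 / 70, tolerance = 1e-12)
})

test_that("HWE is NA when the minor allele has fewer than two copies", {
  expect_true(is.na(hweExact(c(1, 1, 1), c(1, 1, 2))))
  expect_true(is.na(hweExact(c(1, 1, 1), c(1, 1, 1))))  # monomorphic
  expect_false(is.na(hweExact(c(1, 1, 1, 1), c(1, 1, 2, 2))))
})

test_that("HWE exact test holds its size under the null", {
  set.seed(123)
  reps <- 600L
  pvals <- replicate(reps, {
    g <- hweGenotypes(20L, c(0.5, 0.5))
    hweExact(g$a1, g$a2)
  })
  pvals <- pvals[!is.na(pvals)]
  rate <- mean(pvals <= 0.05)
  mcSe <- sqrt(0.05 * 0.95 / length(pvals))
  expect_lte(rate, 0.05 + 2 * mcSe)
})

test_that("Monte-Carlo HWE is seeded and deterministic", {
  set.seed(77)
  g <- hweGenotypes(15L, c(0.4, 0.35, 0.25))
  p1 <- hweExact(g$a1, g$a2, mcReps = 2000L, seed = 9L)
  p2 <- hweExact(g$a1, g$a2, mcReps = 2000L, seed = 9L)
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
})

test_that("Fisher exact enumeration reproduces known tables and matches fisher.test", {
  expect_equal(signif(fisherExact2x2(matrix(c(22, 8, 1, 7), 2,
                                            byrow = TRUE)), 2), 0.0032)
  expect_equal(fisherExact2x2(matrix(1, 2, 2)), 1)
  expect_equal(fisherExact2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE)),
               2 / choose(10, 5), tolerance = 1e-12)
  ## zero margin
  expect_equal(fisherExact2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)), 1)
  ## cross-check against the independent implementation on random tables
  set.seed(31)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) > 40 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisherExact2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
    ## transposition invariance
    expect_equal(fisherExact2x2(tab), fisherExact2x2(t(tab)),
                 tolerance = 1e-12)
  }
})

test_that("concordance builds the 2x2 table from locus records", {
  records <- data.frame(
    is_variable_insilico = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    amplified = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    polymorphic_pcr = c(TRUE, TRUE, FALSE, FALSE, TRUE, NA))
  conc <- concordance(records)
  expect_identical(unname(conc$table),
                   matrix(c(2L, 1L, 1L, 1L), 2, byrow = TRUE))
  expect_identical(conc$nConcordant, 3L)
  expect_identical(conc$n, 5L)
})

test_that("category summaries reproduce hand-computed means and SEs", {
  records <- data.frame(
    category = rep(c("immune", "growth"), c(4, 9)),
    n_alleles_observed = c(2, 2, 3, 3, 2, 2, 6, 2, 7, 2, 4, 2, 5))
  cs <- categorySummary(records)
  imm <- cs$summary[cs$summary$category == "immune", ]
  gro <- cs$summary[cs$summary$category == "growth", ]
  expect_equal(imm$mean, 2.5)
  expect_equal(round(imm$se, 2), 0.29)
  expect_equal(round(gro$mean, 2), 3.56)
  expect_equal(round(gro$se, 2), 0.67)
  expect_true(is.finite(cs$anova[["F"]]))
  ## single category: SE defined, ANOVA NA
  solo <- categorySummary(records[records$category == "immune", ])
  expect_true(is.na(solo$anova[["F"]]))
  one <- categorySummary(data.frame(category = "x",
                                    n_alleles_observed = 3))
  expect_true(is.na(one$summary$se))
})

test_that("Hochberg step-up correction follows the sequential rule", {
  ## m = 2, both p = 0.012: step-up rejects both at alpha 0.05
  r <- hochbergCorrect(c(0.012, 0.012), alpha = 0.05)
  expect_identical(r$reject, c(TRUE, TRUE))
  ## under a family of 21 tests the same p fails
  r21 <- hochbergCorrect(c(0.012, 0.012, rep(1, 19)), alpha = 0.05)
  expect_identical(r21$reject[1:2], c(FALSE, FALSE))
  expect_identical(hochbergCorrect(0.001)$reject, TRUE)
  expect_identical(hochbergCorrect(rep(1, 5))$reject, rep(FALSE, 5))
  expect_identical(hochbergCorrect(numeric(0))$reject, logical(0))
})

test_that("locusStats ties the per-locus statistics together", {
  geno <- data.frame(
    individual = rep(sprintf("i%02d", 1:6), 2),
    locus = rep(c("A", "B"), each = 6),
    allele1 = c(100, 100, 100, 104, 104, 100, rep(120, 6)),
    allele2 = c(100, 104, 104, 104, 100, 100, rep(120, 6)))
  st <- locusStats(geno, seed = 3L)
  expect_identical(st$locus, c("A", "B"))
  expect_identical(st$n_alleles, c(2L, 1L))
  expect_equal(st$ho[1], 3 / 6)
  expect_true(is.na(st$hwe_p[2]))
  expect_equal(st$null_freq[1],
               chakrabortyNull(st$ho[1], st$he[1]))
})

test_that("the LD pair count is n choose 2", {
  expect_identical(ldPairCount(21), 210L)
  expect_identical(ldPairCount(2), 1L)
})
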