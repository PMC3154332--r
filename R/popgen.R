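## popgen_stats: heterozygosities, HWE, null alleles, concordance,
## category summaries and multiple-test correction.

#' Observed and expected heterozygosity at one locus
#'
#' `Ho` is the fraction of heterozygous individuals; `He` is Nei's
#' unbiased expected heterozygosity with the small-sample correction,
#' `(2n/(2n-1)) * (1 - sum(p_i^2))`, the convention of Genepop.
#'
#' @param allele1,allele2 Integer vectors of allele sizes (one entry per
#'   individual; `NA` pairs are dropped as missing genotypes).
#' @return Named numeric vector `c(ho = , he = , n = )`; `ho`/`he` are
#'   `NA` when no non-missing genotypes remain.
#' @examples
#' heterozygosities(c(100, 100), c(104, 104))  # Ho 1, He 2/3
#' @export
heterozygosities <- function(allele1, allele2) {
  keep <- !is.na(allele1) & !is.na(allele2)
  a1 <- allele1[keep]; a2 <- allele2[keep]
  n <- length(a1)
  if (n == 0L) return(c(ho = NA_real_, he = NA_real_, n = 0))
  ho <- mean(a1 != a2)
  p <- as.numeric(table(c(a1, a2))) / (2 * n)
  he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
  c(ho = ho, he = he, n = n)
}

#' Chakraborty null-allele frequency estimator
#'
#' Estimates the frequency of a non-amplifying (null) allele from the
#' heterozygote deficit: `r = (He - Ho) / (He + Ho)`. Negative values
#' are normal when the true null frequency is near zero and samples are
#' small.
#'
#' @param ho,he Observed and expected heterozygosity, in `[0, 1]`.
#' @return The estimate `r`, or `NA` when `ho + he == 0`.
#' @examples
#' chakrabortyNull(0.053, 0.235)  # ~0.632
#' @export
chakrabortyNull <- function(ho, he) {
  stopifnot(all(is.na(ho) | (ho >= 0 & ho <= 1)),
            all(is.na(he) | (he >= 0 & he <= 1)))
  ifelse(is.na(ho) | is.na(he) | (ho + he) == 0, NA_real_,
         (he - ho) / (he + ho))
}

## Conditional log-probability of a diploid genotype array given its
## allele counts (Levene): log P = log n! + H log 2 - sum log(g_ij!)
## up to the allele-count constant, which cancels in comparisons.
genotypeArrayLogProb <- function(a1, a2) {
  het <- sum(a1 != a2)
  g <- paste(pmin(a1, a2), pmax(a1, a2))
  lfactorial(length(a1)) + het * log(2) -
    sum(lfactorial(as.numeric(table(g))))
}

#' Exact / Monte-Carlo Hardy-Weinberg test
#'
#' Tests for deviation from Hardy-Weinberg equilibrium conditional on
#' the observed allele counts. For biallelic loci the genotype-array
#' distribution is enumerated in full (Levene's conditional
#' distribution); otherwise a seeded Monte-Carlo test shuffles the
#' allele vector `mcReps` times and re-pairs it into genotypes. In both
#' cases the P-value is the (estimated) probability of an array at most
#' as likely as the observed one. Returns `NA` when the second most
#' common allele has fewer than 2 copies (a single heterozygote carrying
#' the only copy of the minor allele makes the test degenerate), and for
#' monomorphic loci.
#'
#' @inheritParams heterozygosities
#' @param mcReps Number of Monte-Carlo permutations (default 10000).
#' @param seed Integer seed for the permutation test (required for the
#'   Monte-Carlo branch).
#' @return Two-sided P-value, or `NA`.
#' @export
hweExact <- function(allele1, allele2, mcReps = 10000L, seed = 1L) {
  keep <- !is.na(allele1) & !is.na(allele2)
  a1 <- allele1[keep]; a2 <- allele2[keep]
  n <- length(a1)
  if (n == 0L) return(NA_real_)
  counts <- sort(table(c(a1, a2)), decreasing = TRUE)
  if (length(counts) < 2L || counts[2L] < 2L) return(NA_real_)
  if (length(counts) == 2L) return(hweEnumBiallelic(a1, a2))
  hweMonteCarlo(a1, a2, mcReps, seed)
}

## Full enumeration for two alleles: arrays are indexed by the
## heterozygote count h, which shares the parity of the minor allele
## count;  P(h) = n! nA! nB! 2^h / ((2n)! nAA! h! nBB!).
hweEnumBiallelic <- function(a1, a2) {
  n <- length(a1)
  counts <- sort(table(c(a1, a2)), decreasing = TRUE)
  nA <- as.integer(counts[1L]); nB <- as.integer(counts[2L])
  hObs <- sum(a1 != a2)
  hs <- seq.int(nB %% 2L, nB, by = 2L)
  lp <- lfactorial(n) + lfactorial(nA) + lfactorial(nB) -
    lfactorial(2L * n) + hs * log(2) -
    lfactorial((nA - hs) / 2) - lfactorial(hs) - lfactorial((nB - hs) / 2)
  p <- exp(lp)
  pObs <- p[match(hObs, hs)]
  sum(p[p <= pObs * (1 + 1e-7)])
}

hweMonteCarlo <- function(a1, a2, mcReps, seed) {
  lpObs <- genotypeArrayLogProb(a1, a2)
  pool <- c(a1, a2)
  n <- length(a1)
  withSeed(seed, {
    hits <- 0L
    for (i in seq_len(mcReps)) {
      perm <- sample(pool)
      b1 <- perm[seq_len(n)]; b2 <- perm[n + seq_len(n)]
      if (genotypeArrayLogProb(b1, b2) <= lpObs + 1e-9) hits <- hits + 1L
    }
    (hits + 1) / (mcReps + 1)
  })
}

## Evaluate expr under a local RNG state seeded with `seed`, restoring
## the caller's stream afterwards.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Full hypergeometric enumeration over all tables with the observed
#' margins; the two-sided P-value is the sum of the probabilities of
#' every table whose point probability does not exceed the observed
#' table's (with relative tolerance 1e-7 on the comparison), the
#' convention of common statistical software. A zero margin gives P = 1.
#'
#' @param tab 2x2 matrix (or object coercible to one) of nonnegative
#'   counts.
#' @return Two-sided P-value.
#' @examples
#' fisherExact2x2(matrix(c(22, 8, 1, 7), 2, 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  r1 <- sum(tab[1L, ]); r2 <- sum(tab[2L, ])
  c1 <- sum(tab[, 1L]); c2 <- sum(tab[, 2L])
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0L, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- stats::dhyper(tab[1L, 1L], r1, r2, c1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

#' Build the in silico vs PCR concordance table
#'
#' Cross-tabulates the in silico variability call against observed PCR
#' product polymorphism over loci with an interpretable PCR outcome, and
#' attaches the two-sided Fisher exact P.
#'
#' @param records Locus-record data.frame with logical columns
#'   `is_variable_insilico`, `amplified`, `polymorphic_pcr`
#'   (`polymorphic_pcr` may be `NA` where not amplified).
#' @return List with `table` (2x2 integer matrix, in silico
#'   classification on rows, polymorphic first), `nConcordant`, `n`, and
#'   `fisherP`.
#' @export
concordance <- function(records) {
  ok <- records$amplified & !is.na(records$polymorphic_pcr)
  r <- records[ok, , drop = FALSE]
  tab <- matrix(c(
    sum(r$is_variable_insilico & r$polymorphic_pcr),
    sum(r$is_variable_insilico & !r$polymorphic_pcr),
    sum(!r$is_variable_insilico & r$polymorphic_pcr),
    sum(!r$is_variable_insilico & !r$polymorphic_pcr)),
    nrow = 2L, byrow = TRUE,
    dimnames = list(insilico = c("polymorphic", "monomorphic"),
                    pcr = c("polymorphic", "monomorphic")))
  list(table = tab, nConcordant = tab[1L, 1L] + tab[2L, 2L],
       n = sum(tab), fisherP = fisherExact2x2(tab))
}

#' Per-category allele-count summaries with one-way ANOVA
#'
#' Mean and standard error (`sd/sqrt(n)`) of the observed allele count
#' per selection category, plus a standard one-way ANOVA across
#' categories. Restrict the input to scoreable polymorphic loci before
#' calling.
#'
#' @param records data.frame with columns `category` and
#'   `n_alleles_observed`.
#' @return List with `summary` (data.frame `category`, `n`, `mean`,
#'   `se`; `se = NA` for `n = 1`) and `anova` (named vector `F`, `df1`,
#'   `df2`, `p`; all `NA` with fewer than two categories).
#' @export
categorySummary <- function(records) {
  stopifnot(all(c("category", "n_alleles_observed") %in% names(records)))
  r <- records[!is.na(records$n_alleles_observed), , drop = FALSE]
  cats <- sort(unique(r$category))
  summ <- do.call(rbind, lapply(cats, function(cc) {
    x <- r$n_alleles_observed[r$category == cc]
    data.frame(category = cc, n = length(x), mean = mean(x),
               se = if (length(x) >= 2L) stats::sd(x) / sqrt(length(x))
                    else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (length(cats) >= 2L) {
    fit <- stats::aov(n_alleles_observed ~ factor(category), data = r)
    a <- summary(fit)[[1L]]
    anova <- c(F = a$`F value`[1L], df1 = a$Df[1L], df2 = a$Df[2L],
               p = a$`Pr(>F)`[1L])
  } else {
    anova <- c(F = NA_real_, df1 = NA_real_, df2 = NA_real_,
               p = NA_real_)
  }
  list(summary = summ, anova = anova)
}

#' Hochberg step-up multiple-test correction
#'
#' Sequential (step-up) Hochberg correction of a vector of P-values;
#' returns per-test reject/accept decisions at family-wise level
#' `alpha` together with the adjusted P-values
#' (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of P-values in `[0, 1]` (`NA` allowed,
#'   never rejected).
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `adjusted` and logical `reject`.
#' @export
hochbergCorrect <- function(p, alpha = 0.05) {
  if (length(p) == 0L)
    return(list(adjusted = numeric(0), reject = logical(0)))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  adj <- stats::p.adjust(p, method = "hochberg")
  list(adjusted = adj, reject = !is.na(adj) & adj <= alpha)
}

#' Number of pairwise locus comparisons
#'
#' Convenience count of locus pairs tested for linkage disequilibrium:
#' `choose(n, 2)`.
#'
#' @param nLoci Number of scoreable loci.
#' @return Integer pair count.
#' @export
ldPairCount <- function(nLoci) {
  as.integer(choose(nLoci, 2))
}

#' Read a genotype table (long TSV)
#'
#' Columns `individual`, `locus`, `allele1`, `allele2`; blank alleles
#' are missing genotypes.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readGenotypesTsv <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("individual", "locus", "allele1", "allele2") %in%
                  names(df)))
  df
}

#' Per-locus summary statistics of a genotype table
#'
#' Applies [heterozygosities()], [chakrabortyNull()] and [hweExact()]
#' to every locus of a long-format genotype table.
#'
#' @param genotypes data.frame as from [readGenotypesTsv()].
#' @param mcReps,seed Passed to [hweExact()]; each locus uses a seed
#'   offset by its index so locus results are independent of table
#'   order only through locus id order.
#' @return data.frame `locus`, `n`, `n_alleles`, `ho`, `he`,
#'   `null_freq`, `hwe_p`.
#' @export
locusStats <- function(genotypes, mcReps = 10000L, seed = 1L) {
  loci <- sort(unique(genotypes$locus))
  do.call(rbind, lapply(seq_along(loci), function(i) {
    g <- genotypes[genotypes$locus == loci[i], ]
    h <- heterozygosities(g$allele1, g$allele2)
    keep <- !is.na(g$allele1) & !is.na(g$allele2)
    data.frame(
      locus = loci[i], n = as.integer(h[["n"]]),
      n_alleles = length(unique(c(g$allele1[keep], g$allele2[keep]))),
      ho = h[["ho"]], he = h[["he"]],
      null_freq = chakrabortyNull(h[["ho"]], h[["he"]]),
      hwe_p = hweExact(g$allele1, g$allele2, mcReps = mcReps,
                       seed = seed + i),
      stringsAsFactors = FALSE)
  }))
}
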