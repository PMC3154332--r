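annFixture <- function() {
  data.frame(
    contig_id = c("c1", "c2", "c3", "c4", "c5"),
    isogroup_id = c("ig1", "ig1", "ig2", "ig3", "ig4"),
    go_terms = c("immune response; T cell activation",
                 "cell growth; proliferation",
                 "regulation of growth and immune function",
                 "ion transport", NA),
    annotated = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    mapped = c(TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

test_that("annotation matching is case-insensitive, per-pattern and NA-safe", {
  ann <- matchAnnotation(annFixture(), c("immun", "growth"))
  expect_identical(ann$category_tags,
                   c("immun", "growth", "immun;growth", "", ""))
  annUp <- annFixture()
  annUp$go_terms[1] <- "IMMUNE RESPONSE"
  expect_identical(matchAnnotation(annUp, "immun")$category_tags[1],
                   "immun")
})

test_that("each selection rule records its own failure", {
  ann <- annFixture()
  profs <- rbind(
    profRow("L1", "c1"),
    profRow("L2", "c2", coverage = 1L),            # fails coverage
    profRow("L3", "c3", flank = 10L),              # fails flank
    profRow("L4", "c4"),                           # fails mapped
    profRow("L5", "c5"),                           # fails annotated
    profRow("L6", "c6"),                           # no annotation row
    profRow("L7", "c3", is_variable = FALSE))
  cands <- selectCandidates(profs, ann,
                            selectionRules(requireVariable = TRUE,
                                           onePerIsogroup = FALSE))
  got <- setNames(cands$filter_failures, cands$locus_id)
  expect_identical(got[["L1"]], "")
  expect_identical(got[["L2"]], "coverage")
  expect_identical(got[["L3"]], "flank")
  expect_identical(got[["L4"]], "mapped")
  expect_identical(got[["L5"]], "annotated")
  expect_identical(got[["L6"]], "annotated;mapped")
  expect_identical(got[["L7"]], "variable")
  expect_identical(cands$selected, cands$filter_failures == "")
})

test_that("exactly one representative per isogroup survives, chosen deterministically", {
  ann <- annFixture()
  profs <- rbind(
    profRow("L1", "c1", n_alleles = 2L, depth = 10L),
    profRow("L2", "c2", n_alleles = 4L, depth = 5L))  # same isogroup ig1
  cands <- selectCandidates(profs, ann)
  expect_identical(cands$locus_id[cands$selected], "L2")
  expect_match(cands$filter_failures[cands$locus_id == "L1"],
               "isogroup_redundant")
  ## tie on alleles -> higher depth wins; full tie -> locus id order
  profs2 <- rbind(profRow("L1", "c1", n_alleles = 3L, depth = 20L),
                  profRow("L2", "c2", n_alleles = 3L, depth = 5L))
  expect_identical(
    selectCandidates(profs2, ann)$locus_id[
      selectCandidates(profs2, ann)$selected], "L1")
})

test_that("selection is idempotent and order-independent", {
  ann <- annFixture()
  profs <- rbind(profRow("L1", "c1"), profRow("L2", "c2", coverage = 0L),
                 profRow("L3", "c3"))
  a <- selectCandidates(profs, ann)
  b <- selectCandidates(profs[c(3, 1, 2), ], ann)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  ## selecting from the selected set changes nothing
  resel <- selectCandidates(a[, names(profs)], ann)
  expect_identical(resel$selected, a$selected)
})

test_that("relaxing a threshold never unselects a locus (filter stage)", {
  ann <- annFixture()
  set.seed(21)
  profs <- do.call(rbind, lapply(1:12, function(i)
    profRow(sprintf("L%02d", i), sprintf("c%d", (i %% 5) + 1L),
            flank = sample(c(10L, 40L), 1L),
            coverage = sample(0:5, 1L),
            is_variable = sample(c(TRUE, FALSE), 1L))))
  strict <- selectionRules(minFlankBp = 30L, minRegionCoverage = 2L,
                           requireVariable = TRUE,
                           onePerIsogroup = FALSE)
  for (relaxed in list(
    selectionRules(minFlankBp = 5L, minRegionCoverage = 2L,
                   requireVariable = TRUE, onePerIsogroup = FALSE),
    selectionRules(minFlankBp = 30L, minRegionCoverage = 0L,
                   requireVariable = TRUE, onePerIsogroup = FALSE),
    selectionRules(minFlankBp = 30L, minRegionCoverage = 2L,
                   requireVariable = FALSE, onePerIsogroup = FALSE))) {
    a <- selectCandidates(profs, ann, strict)
    b <- selectCandidates(profs, ann, relaxed)
    expect_true(all(b$selected[a$selected]))
  }
})

test_that("require_variable keeps only in silico variable loci; empty input is fine", {
  ann <- annFixture()
  profs <- rbind(profRow("L1", "c1", is_variable = TRUE),
                 profRow("L2", "c2", is_variable = FALSE))
  cands <- selectCandidates(profs, ann,
                            selectionRules(requireVariable = TRUE,
                                           onePerIsogroup = FALSE))
  expect_true(all(cands$is_variable[cands$selected]))
  empty <- selectCandidates(profs[0, ], ann)
  expect_identical(nrow(empty), 0L)
})

test_that("primer windows export as 0-based half-open BED", {
  cands <- data.frame(locus_id = "L1", contig_id = "c1",
                      start_1based = 101L, end_1based = 120L,
                      selected = TRUE, stringsAsFactors = FALSE)
  bed <- tempfile(fileext = ".bed")
  writePrimerWindowsBed(cands, bed, flankBp = 100L)
  fields <- strsplit(readLines(bed), "\t")[[1L]]
  expect_identical(fields, c("c1", "0", "220", "L1"))
})
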