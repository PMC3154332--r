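smallConfig <- function(...) {
  simulationConfig(nLoci = 4L, contigLength = 400L, meanDepth = 15,
                   readLengthMean = 200, readLengthSd = 15, ...)
}

test_that("identical seeds give byte-identical simulator outputs", {
  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  simulateReads(smallConfig(), seed = 5L, outDir = d1)
  simulateReads(smallConfig(), seed = 5L, outDir = d2)
  for (f in c("contigs.fasta", "reads.sam", "truth_loci.tsv",
              "truth_genotypes.tsv", "truth_reads.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
  ## different seed, different data
  d3 <- file.path(tempfile(), "c")
  simulateReads(smallConfig(), seed = 6L, outDir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "reads.sam"))),
    unname(tools::md5sum(file.path(d3, "reads.sam")))))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulateReads(smallConfig(), seed = 3L))
  expect_identical(runif(1), before)
})

test_that("emitted SAM re-parses and reads cover the embedded tracts", {
  sim <- simulateReads(smallConfig(), seed = 8L,
                       outDir = tempfile("rt"))
  bam <- Rsamtools::asBam(sim$paths$sam, destination = tempfile(),
                          overwrite = TRUE)
  recs <- Rsamtools::scanBam(bam)[[1L]]
  expect_identical(length(recs$qname), nrow(sim$reads))
  ## each locus has spanning reads per the truth table
  profs <- profileLoci(sim$paths$sam, sim$paths$fasta, sim$loci)
  for (p in profs) expect_gt(depthSpanning(p), 0L)
})

test_that("simulated truth is recovered exactly when no errors are injected", {
  cfg <- simulationConfig(nLoci = 8L, contigLength = 500L,
                          meanDepth = 25, readLengthMean = 250,
                          readLengthSd = 0, substitutionRate = 0,
                          slippageRate = 0, polymorphicFraction = 0.6)
  sim <- simulateReads(cfg, seed = 13L, outDir = tempfile("rec"))
  profs <- profileLoci(sim$paths$sam, sim$paths$fasta, sim$loci)
  for (i in seq_along(profs)) {
    p <- profs[[i]]
    truthUnits <- microsatMiner:::parseAlleleSpec(
      sim$truthLoci$alleles[i])$units
    sampledUnits <- sort(unique(sim$truthReads$read_units[
      sim$truthReads$locus_id == sim$truthLoci$locus_id[i]]))
    inferred <- as.integer(names(alleleHistogram(p)))
    expect_identical(p@nIrregular, 0L)
    ## no error process: inferred length classes are true alleles that
    ## were actually sampled, never fabrications
    expect_true(all(inferred %in% truthUnits))
    expect_true(all(inferred %in% sampledUnits))
    if (length(truthUnits) == 1L) {
      expect_identical(nAlleles(p), 1L)
      expect_false(isVariable(p))
    }
  }
})

test_that("monomorphic loci show off-consensus reads at about the slippage rate", {
  slip <- 0.02
  cfg <- simulationConfig(
    nLoci = 1L, contigLength = 854L,
    meanDepth = 10000 * 286 / 854,   # ~10,000 reads on one contig
    readLengthMean = 286, readLengthSd = 0,
    substitutionRate = 0, slippageRate = slip,
    polymorphicFraction = 0,
    lociSpec = data.frame(motif = "AC", alleles = "8:1"))
  sim <- simulateReads(cfg, seed = 17L, outDir = tempfile("slip"))
  profs <- profileLoci(sim$paths$sam, sim$paths$fasta, sim$loci)
  p <- profs[[1L]]
  frac <- p@nOffConsensus / depthSpanning(p)
  mcSe <- sqrt(slip * (1 - slip) / depthSpanning(p))
  expect_lt(abs(frac - slip), 3 * mcSe)
  ## truth cross-check: the slip flags in the truth table agree
  expect_lt(abs(mean(sim$truthReads$slip != 0) - slip),
            3 * sqrt(slip * (1 - slip) / nrow(sim$truthReads)))
})

test_that("realized mean depth tracks the configured depth over many contigs", {
  cfg <- simulationConfig(nLoci = 200L, contigLength = 600L,
                          meanDepth = 12, readLengthMean = 200,
                          readLengthSd = 20, substitutionRate = 0,
                          slippageRate = 0)
  sim <- simulateReads(cfg, seed = 19L)
  perContig <- tapply(nchar(sim$reads$seq), sim$reads$rname, sum) / 600
  expect_lt(abs(mean(perContig) - 12) / 12, 0.05)
})

test_that("an over-long tract is rejected with the locus named", {
  cfg <- simulationConfig(
    readLengthMean = 60,
    lociSpec = data.frame(motif = "AAAG", alleles = "12:1"))
  expect_error(simulateReads(cfg, seed = 1L), "sim001")
})

test_that("config YAML round trips", {
  cfg <- simulationConfig(nLoci = 7L, slippageRate = 0.03,
                          lociSpec = data.frame(
                            motif = c("AC", "TTG"),
                            alleles = c("6:0.5;7:0.5", "9:1")))
  path <- tempfile(fileext = ".yaml")
  writeConfigYaml(cfg, path)
  back <- readConfigYaml(path)
  expect_equal(back@slippageRate, cfg@slippageRate)
  expect_identical(back@lociSpec$motif, cfg@lociSpec$motif)
  expect_identical(back@lociSpec$alleles, cfg@lociSpec$alleles)
})

test_that("invalid configurations are rejected by the validity method", {
  expect_error(simulationConfig(slippageRate = 1.5), "rates")
  expect_error(simulationConfig(meanDepth = 0), "meanDepth")
  expect_error(simulationConfig(unitCountRange = c(8L, 5L)),
               "unitCountRange")
})

test_that("locus records join truth, profiles and the wet-lab outcome model", {
  cfg <- simulationConfig(nLoci = 12L, contigLength = 400L,
                          meanDepth = 15, readLengthMean = 200,
                          readLengthSd = 0, substitutionRate = 0,
                          slippageRate = 0)
  sim <- simulateReads(cfg, seed = 23L, outDir = tempfile("rec2"))
  tab <- profileTable(profileLoci(sim$paths$sam, sim$paths$fasta,
                                  sim$loci))
  rec <- makeLocusRecords(sim$truthLoci, tab,
                          pcrModel = list(amplifyProb = 1), seed = 2L)
  expect_identical(nrow(rec), 12L)
  expect_true(all(rec$amplified))
  ## deterministic truth model: PCR polymorphism == truth polymorphism
  expect_identical(rec$polymorphic_pcr,
                   sim$truthLoci$n_alleles_true >= 2L)
  expect_true(all(rec$n_alleles_observed[rec$polymorphic_pcr] >= 2L))
  expect_true(all(rec$n_alleles_observed[!rec$polymorphic_pcr] == 1L))
  ## concordance on a deterministic-truth model is diagonal-dominant
  conc <- concordance(rec)
  expect_identical(sum(conc$table), 12L)
  ## missing profile -> warning and skip
  expect_warning(
    rec2 <- makeLocusRecords(sim$truthLoci, tab[-1L, ], seed = 2L),
    "skipping")
  expect_identical(nrow(rec2), 11L)
  ## records TSV round trip
  path <- tempfile(fileext = ".tsv")
  writeLocusRecordsTsv(rec, path)
  back <- readLocusRecordsTsv(path)
  expect_identical(back$polymorphic_pcr, rec$polymorphic_pcr)
})
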