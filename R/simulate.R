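#' Configuration for the pooled-individual read simulator
#'
#' Describes a synthetic study emulating pooled-cDNA sequencing of a
#' discovery panel: a set of transcript contigs each carrying one
#' perfect microsatellite, per-individual diploid repeat genotypes drawn
#' from per-locus allele frequencies, and single-end reads with
#' substitution errors and repeat-slippage errors (whole-unit gains or
#' losses concentrated in the tract). Defaults reflect the study design
#' the package targets: 12 pooled individuals, ~19x mean depth and
#' ~286 bp mean read length.
#'
#' @slot nIndividuals Individuals in the pooled discovery panel.
#' @slot nLoci Number of loci (one repeat per contig).
#' @slot contigLength Contig length, bp.
#' @slot motifs Canonical motif pool sampled when `lociSpec` is empty.
#' @slot unitCountRange Inclusive range alleles are drawn from.
#' @slot polymorphicFraction Probability an auto-generated locus gets
#'   more than one allele.
#' @slot meanDepth Mean read depth per contig.
#' @slot readLengthMean,readLengthSd Read length distribution (normal,
#'   truncated below at 50 bp).
#' @slot substitutionRate Per-base substitution error probability.
#' @slot slippageRate Per-read probability that the read's repeat tract
#'   gains or loses one whole motif copy.
#' @slot lociSpec Optional explicit per-locus spec: data.frame with
#'   columns `motif` and `alleles` (`"units:freq;..."`); zero rows means
#'   auto-generate from the seed.
#' @seealso [simulationConfig()], [simulateReads()]
#' @export
setClass("SimulationConfig",
  representation(
    nIndividuals = "integer", nLoci = "integer", contigLength = "integer",
    motifs = "character", unitCountRange = "integer",
    polymorphicFraction = "numeric", meanDepth = "numeric",
    readLengthMean = "numeric", readLengthSd = "numeric",
    substitutionRate = "numeric", slippageRate = "numeric",
    lociSpec = "data.frame"))

setValidity("SimulationConfig", function(object) {
  msg <- character(0)
  rates <- c(object@substitutionRate, object@slippageRate,
             object@polymorphicFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "rates must lie in [0, 1]")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@nIndividuals < 1L) msg <- c(msg, "need >= 1 individual")
  if (length(object@unitCountRange) != 2L ||
      object@unitCountRange[1L] < 2L ||
      diff(object@unitCountRange) < 0L)
    msg <- c(msg, "unitCountRange must be c(lo, hi), lo >= 2")
  if (nrow(object@lociSpec) &&
      !all(c("motif", "alleles") %in% names(object@lociSpec)))
    msg <- c(msg, "lociSpec needs columns motif, alleles")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nLoci, "loci x",
      object@nIndividuals, "individuals\n")
  cat(sprintf("  contigs %d bp, depth %.1fx, reads %.0f+-%.0f bp\n",
              object@contigLength, object@meanDepth,
              object@readLengthMean, object@readLengthSd))
  cat(sprintf("  substitution rate %g /base, slippage rate %g /read\n",
              object@substitutionRate, object@slippageRate))
  if (nrow(object@lociSpec))
    cat("  explicit loci:", nrow(object@lociSpec), "\n")
  invisible(NULL)
})

#' @rdname SimulationConfig-class
#' @param nIndividuals,nLoci,contigLength,motifs,unitCountRange
#'   See slots.
#' @param polymorphicFraction,meanDepth,readLengthMean,readLengthSd
#'   See slots.
#' @param substitutionRate,slippageRate,lociSpec See slots.
#' @export
simulationConfig <- function(nIndividuals = 12L, nLoci = 20L,
                             contigLength = 854L,
                             motifs = c("AC", "AG", "AT", "AAC", "AAG",
                                        "AGG", "GTT", "AAAC", "AAAG",
                                        "ATCT"),
                             unitCountRange = c(5L, 12L),
                             polymorphicFraction = 0.5,
                             meanDepth = 19.4, readLengthMean = 286,
                             readLengthSd = 30,
                             substitutionRate = 0.001,
                             slippageRate = 0.01,
                             lociSpec = data.frame()) {
  methods::new("SimulationConfig",
    nIndividuals = as.integer(nIndividuals), nLoci = as.integer(nLoci),
    contigLength = as.integer(contigLength), motifs = motifs,
    unitCountRange = as.integer(unitCountRange),
    polymorphicFraction = polymorphicFraction, meanDepth = meanDepth,
    readLengthMean = readLengthMean, readLengthSd = readLengthSd,
    substitutionRate = substitutionRate, slippageRate = slippageRate,
    lociSpec = lociSpec)
}

parseAlleleSpec <- function(s) {
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], ":",
                    fixed = TRUE)
  units <- vapply(parts, function(p) as.integer(p[1L]), integer(1L))
  freqs <- vapply(parts, function(p) as.numeric(p[2L]), numeric(1L))
  if (abs(sum(freqs) - 1) > 1e-6)
    stop("allele frequencies must sum to 1: ", s)
  list(units = units, freqs = freqs)
}

formatAlleleSpec <- function(units, freqs) {
  paste(units, signif(freqs, 6), sep = ":", collapse = ";")
}

randomBases <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Alignment of a simulated read against the contig consensus.  The
## haplotype differs from the consensus only inside the tract (u vs c
## whole motif copies), so the CIGAR is piecewise: flank matches, one
## whole-unit insertion or deletion at the tract, soft clips where read
## tract bases cannot be placed.  1-based haplotype coordinates.
simCigar <- function(rs, re, ts, u, c, m) {
  cm <- c * m
  L1 <- max(0L, min(re, ts - 1L) - rs + 1L)
  L2 <- max(0L, min(re, ts + u * m - 1L) - max(rs, ts) + 1L)
  L3 <- max(0L, re - max(rs, ts + u * m) + 1L)
  cig <- function(...) {
    parts <- list(...)
    paste(vapply(parts, function(p)
      if (p[[1L]] > 0L) sprintf("%d%s", p[[1L]], p[[2L]]) else "",
      ""), collapse = "")
  }
  if (L1 > 0L) {
    pos <- rs
    if (L3 > 0L) {
      if (L2 >= cm) {
        cigar <- if (L2 > cm)
          cig(list(L1 + cm, "M"), list(L2 - cm, "I"), list(L3, "M"))
        else cig(list(L1 + cm + L3, "M"))
      } else {
        cigar <- cig(list(L1 + L2, "M"), list(cm - L2, "D"),
                     list(L3, "M"))
      }
    } else {
      matched <- min(L2, cm)
      cigar <- cig(list(L1 + matched, "M"), list(L2 - matched, "S"))
    }
  } else if (L2 > 0L) {
    matched <- min(L2, cm)
    if (L3 > 0L) {
      pos <- ts + cm - matched
      cigar <- cig(list(L2 - matched, "S"), list(matched + L3, "M"))
    } else {
      pos <- ts
      cigar <- cig(list(matched, "M"), list(L2 - matched, "S"))
    }
  } else {
    pos <- rs + (c - u) * m
    cigar <- cig(list(re - rs + 1L, "M"))
  }
  list(pos = as.integer(pos), cigar = cigar)
}

#' Simulate pooled multi-individual reads over microsatellite contigs
#'
#' Generates, deterministically for a given seed: contig consensus
#' sequences each embedding one perfect repeat tract; diploid repeat
#' genotypes for every individual drawn from the per-locus allele
#' frequencies; and single-end reads sampled uniformly from random
#' individuals' haplotypes, with per-base substitution errors and
#' whole-unit slippage errors in the tract. Alignment records carry
#' CIGARs that represent slipped or non-consensus repeat lengths as
#' whole-motif insertions/deletions against the consensus. Individual
#' labels are recorded in the truth tables but deliberately withheld
#' from the SAM, as in pooled sequencing.
#'
#' @param config A [SimulationConfig-class].
#' @param seed Integer seed; identical seeds give byte-identical
#'   outputs.
#' @param outDir Optional directory; when given, writes `contigs.fasta`,
#'   `reads.sam`, `truth_loci.tsv`, `truth_genotypes.tsv`,
#'   `truth_reads.tsv` and `config.yaml` there.
#' @return List with `contigs` (`DNAStringSet`), `loci` (truth
#'   `GRanges` with `locusId`, `motif`, `motifSize`, `unitCount`),
#'   `reads` (alignment data.frame), `truthLoci`, `truthGenotypes`,
#'   `truthReads` (data.frames) and, when `outDir` is given, `paths`.
#' @export
simulateReads <- function(config, seed, outDir = NULL) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  withSeed(seed, simulateReadsImpl(config, seed, outDir))
}

simulateReadsImpl <- function(config, seed, outDir) {
  nInd <- config@nIndividuals
  L <- config@contigLength
  m2 <- config@readLengthMean
  explicit <- nrow(config@lociSpec) > 0L
  nLoci <- if (explicit) nrow(config@lociSpec) else config@nLoci

  contigs <- character(nLoci)
  truthLoci <- vector("list", nLoci)
  truthGeno <- vector("list", nLoci)
  readRows <- vector("list", nLoci)
  truthReads <- vector("list", nLoci)
  genoMat <- vector("list", nLoci)

  for (i in seq_len(nLoci)) {
    locusId <- sprintf("sim%03d", i)
    contigId <- sprintf("contig%03d", i)
    if (explicit) {
      motif <- canonicalizeMotif(config@lociSpec$motif[i])
      sp <- parseAlleleSpec(config@lociSpec$alleles[i])
      units <- sp$units; freqs <- sp$freqs
    } else {
      motif <- sample(config@motifs, 1L)
      poly <- stats::runif(1) < config@polymorphicFraction
      nAll <- if (poly) sample(2:4, 1L, prob = c(0.5, 0.3, 0.2)) else 1L
      lo <- config@unitCountRange[1L]; hi <- config@unitCountRange[2L]
      units <- sort(sample(lo:hi, min(nAll, hi - lo + 1L)))
      g <- stats::rgamma(length(units), shape = 2)
      freqs <- g / sum(g)
    }
    m <- nchar(motif)
    if (max(units) * m + 20L > config@readLengthMean)
      stop(sprintf(
        "locus %s: tract (%d bp) plus anchors exceeds read length",
        locusId, max(units) * m))
    consensus <- units[order(-freqs, units)][1L]
    cm <- consensus * m

    ## contig with the tract embedded; boundary bases fixed so the
    ## tract is maximal and its coordinates are exactly the truth
    minFlank <- 60L
    stopifnot(L >= cm + 2L * minFlank)
    ts <- sample(seq.int(minFlank + 1L, L - cm - minFlank), 1L)
    seqChars <- strsplit(randomBases(L), "", fixed = TRUE)[[1L]]
    motifChars <- strsplit(motif, "", fixed = TRUE)[[1L]]
    seqChars[ts:(ts + cm - 1L)] <- rep(motifChars, consensus)
    notBase <- function(b) setdiff(c("A", "C", "G", "T"), b)[1L]
    seqChars[ts - 1L] <- notBase(seqChars[ts + m - 1L])
    seqChars[ts + cm] <- notBase(motifChars[1L])
    contig <- paste(seqChars, collapse = "")
    contigs[i] <- contig

    ## diploid genotypes for the pooled panel
    gm <- matrix(units[sample.int(length(units), 2L * nInd,
                                  replace = TRUE, prob = freqs)],
                 nrow = nInd)
    genoMat[[i]] <- gm
    truthGeno[[i]] <- data.frame(
      individual = sprintf("ind%02d", seq_len(nInd)),
      locus_id = locusId, allele1_units = gm[, 1L],
      allele2_units = gm[, 2L], stringsAsFactors = FALSE)

    nReads <- max(1L, as.integer(round(config@meanDepth * L / m2)))
    rows <- vector("list", nReads)
    truth <- vector("list", nReads)
    for (r in seq_len(nReads)) {
      ind <- sample(nInd, 1L)
      hap <- sample(2L, 1L)
      u0 <- gm[ind, hap]
      slip <- 0L
      if (stats::runif(1) < config@slippageRate) {
        slip <- sample(c(-1L, 1L), 1L)
        if (u0 + slip < 1L) slip <- 1L
      }
      u <- u0 + slip
      hapSeq <- paste0(substr(contig, 1L, ts - 1L),
                       strrep(motif, u),
                       substr(contig, ts + cm, L))
      hapLen <- nchar(hapSeq)
      len <- as.integer(round(stats::rnorm(1, m2, config@readLengthSd)))
      len <- max(50L, min(len, hapLen))
      rs <- sample.int(hapLen - len + 1L, 1L)
      re <- rs + len - 1L
      bases <- strsplit(substr(hapSeq, rs, re), "", fixed = TRUE)[[1L]]
      hitSub <- which(stats::runif(len) < config@substitutionRate)
      for (j in hitSub)
        bases[j] <- sample(setdiff(c("A", "C", "G", "T"), bases[j]), 1L)
      aln <- simCigar(rs, re, ts, u, consensus, m)
      qname <- sprintf("read_%s_%05d", locusId, r)
      rows[[r]] <- data.frame(
        qname = qname, rname = contigId, pos = aln$pos,
        cigar = aln$cigar, seq = paste(bases, collapse = ""),
        stringsAsFactors = FALSE)
      truth[[r]] <- data.frame(
        read_id = qname, locus_id = locusId,
        individual = sprintf("ind%02d", ind), haplotype = hap,
        genotype_units = u0, read_units = u, slip = slip,
        n_subs = length(hitSub), stringsAsFactors = FALSE)
    }
    readRows[[i]] <- do.call(rbind, rows)
    truthReads[[i]] <- do.call(rbind, truth)
    truthLoci[[i]] <- data.frame(
      locus_id = locusId, contig_id = contigId, motif = motif,
      motif_size = m, start = ts, end = ts + cm - 1L,
      consensus_units = consensus,
      alleles = formatAlleleSpec(units, freqs),
      n_alleles_true = length(units), stringsAsFactors = FALSE)
  }

  truthLoci <- do.call(rbind, truthLoci)
  truthGenotypes <- do.call(rbind, truthGeno)
  truthReads <- do.call(rbind, truthReads)
  reads <- do.call(rbind, readRows)
  names(contigs) <- truthLoci$contig_id
  contigSet <- Biostrings::DNAStringSet(contigs)

  loci <- GenomicRanges::GRanges(
    seqnames = truthLoci$contig_id,
    ranges = IRanges::IRanges(truthLoci$start, truthLoci$end))
  S4Vectors::mcols(loci) <- S4Vectors::DataFrame(
    locusId = truthLoci$locus_id, motif = truthLoci$motif,
    motifSize = as.integer(truthLoci$motif_size),
    unitCount = as.integer(truthLoci$consensus_units))

  ans <- list(contigs = contigSet, loci = loci, reads = reads,
              truthLoci = truthLoci, truthGenotypes = truthGenotypes,
              truthReads = truthReads)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(outDir, "contigs.fasta"),
      sam = file.path(outDir, "reads.sam"),
      truthLoci = file.path(outDir, "truth_loci.tsv"),
      truthGenotypes = file.path(outDir, "truth_genotypes.tsv"),
      truthReads = file.path(outDir, "truth_reads.tsv"),
      config = file.path(outDir, "config.yaml"))
    Biostrings::writeXStringSet(contigSet, paths$fasta)
    writeSam(reads, stats::setNames(nchar(contigs), names(contigs)),
             paths$sam)
    writeTsvAtomic(truthLoci, paths$truthLoci, list(seed = seed))
    writeTsvAtomic(truthGenotypes, paths$truthGenotypes,
                   list(seed = seed))
    writeTsvAtomic(truthReads, paths$truthReads, list(seed = seed))
    writeConfigYaml(config, paths$config)
    ans$paths <- paths
  }
  ans
}

#' Read / write a simulation config as YAML
#'
#' @param config A [SimulationConfig-class].
#' @param path YAML path.
#' @return `writeConfigYaml`: `path` invisibly; `readConfigYaml`: a
#'   `SimulationConfig`.
#' @export
writeConfigYaml <- function(config, path) {
  x <- list(nIndividuals = config@nIndividuals, nLoci = config@nLoci,
            contigLength = config@contigLength, motifs = config@motifs,
            unitCountRange = config@unitCountRange,
            polymorphicFraction = config@polymorphicFraction,
            meanDepth = config@meanDepth,
            readLengthMean = config@readLengthMean,
            readLengthSd = config@readLengthSd,
            substitutionRate = config@substitutionRate,
            slippageRate = config@slippageRate)
  if (nrow(config@lociSpec))
    x$lociSpec <- lapply(seq_len(nrow(config@lociSpec)), function(i)
      as.list(config@lociSpec[i, c("motif", "alleles")]))
  writeLinesAtomic(yaml::as.yaml(x), path)
}

#' @rdname writeConfigYaml
#' @export
readConfigYaml <- function(path) {
  x <- yaml::read_yaml(path)
  lociSpec <- if (!is.null(x$lociSpec))
    do.call(rbind, lapply(x$lociSpec, as.data.frame))
  else data.frame()
  x$lociSpec <- NULL
  do.call(simulationConfig, c(x, list(lociSpec = lociSpec)))
}

#' Join simulation truth and profiles into a locus-record table
#'
#' Combines the simulator truth, the in silico profiles computed from
#' the simulated reads, and a stochastic wet-lab outcome model into the
#' locus-record schema consumed by the validation statistics
#' ([concordance()], [categorySummary()],
#' [fitPolymorphismGlms()]). The outcome model amplifies each locus with
#' probability `amplifyProb`; amplified loci are polymorphic with
#' probability `pPolyGivenVariable` when the simulated truth holds
#' more than one allele and `pPolyGivenMono` otherwise (defaults make
#' PCR polymorphism deterministically equal to the truth).
#'
#' @param truthLoci Truth locus table from [simulateReads()].
#' @param profiles Profile table ([profileTable()]) computed on the
#'   simulated alignments at the truth loci.
#' @param pcrModel List: `amplifyProb` (default 0.76),
#'   `pPolyGivenVariable` (1), `pPolyGivenMono` (0).
#' @param seed Integer seed for the outcome model.
#' @return Locus-record data.frame with columns `locus_id`, `category`,
#'   `min_units`, `n_alleles_insilico`, `n_off_consensus`,
#'   `is_variable_insilico`, `motif_size`, `amplified`,
#'   `polymorphic_pcr`, `n_alleles_observed`. Loci without a profile are
#'   skipped with a warning.
#' @export
makeLocusRecords <- function(truthLoci, profiles,
                             pcrModel = list(), seed = 1L) {
  pm <- utils::modifyList(list(amplifyProb = 0.76,
                               pPolyGivenVariable = 1,
                               pPolyGivenMono = 0), pcrModel)
  j <- match(truthLoci$locus_id, profiles$locus_id)
  if (anyNA(j)) {
    warning("skipping loci without profiles: ",
            paste(truthLoci$locus_id[is.na(j)], collapse = ", "))
    truthLoci <- truthLoci[!is.na(j), , drop = FALSE]
    j <- j[!is.na(j)]
  }
  if (nrow(truthLoci) == 0L)
    return(data.frame(locus_id = character(0)))
  p <- profiles[j, , drop = FALSE]
  withSeed(seed, {
    n <- nrow(truthLoci)
    category <- sample(c("immune", "growth", "insilico"), n,
                       replace = TRUE, prob = c(13, 27, 10) / 50)
    amplified <- stats::runif(n) < pm$amplifyProb
    truthPoly <- truthLoci$n_alleles_true >= 2L
    pPoly <- ifelse(truthPoly, pm$pPolyGivenVariable, pm$pPolyGivenMono)
    polymorphic <- ifelse(amplified, stats::runif(n) < pPoly, NA)
    nObs <- ifelse(is.na(polymorphic), NA_integer_,
                   ifelse(polymorphic,
                          pmax(2L, truthLoci$n_alleles_true), 1L))
    data.frame(
      locus_id = truthLoci$locus_id, category = category,
      min_units = p$min_units,
      n_alleles_insilico = p$n_alleles_insilico,
      n_off_consensus = p$n_off_consensus,
      is_variable_insilico = p$is_variable,
      motif_size = truthLoci$motif_size,
      amplified = amplified, polymorphic_pcr = polymorphic,
      n_alleles_observed = nObs, stringsAsFactors = FALSE)
  })
}

#' @rdname makeLocusRecords
#' @param records Locus-record data.frame.
#' @param path TSV path.
#' @export
writeLocusRecordsTsv <- function(records, path) {
  writeTsvAtomic(records, path)
}

#' @rdname makeLocusRecords
#' @export
readLocusRecordsTsv <- function(path) {
  df <- readTsv(path)
  for (col in c("is_variable_insilico", "amplified", "polymorphic_pcr"))
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  df
}
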