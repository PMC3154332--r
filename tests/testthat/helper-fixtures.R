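## Shared test fixtures and independent oracles, all built in code.

## Independent brute-force repeat finder: per-position while-loop
## extension of every (start, period) pair, no vectorized run-length
## machinery shared with the implementation.
oracleScan <- function(seq, minUnits = 5L, motifSizes = 2:4) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  acgt <- c("A", "C", "G", "T")
  out <- list()
  for (m in motifSizes) {
    for (i in seq_len(max(0L, L - m))) {
      ## i must start a maximal periodic block at period m
      if (i > 1L && chars[i - 1L] %in% acgt &&
          chars[i - 1L] == chars[i - 1L + m]) next
      t <- i + m
      while (t <= L && chars[t - m] %in% acgt &&
             chars[t] == chars[t - m]) t <- t + 1L
      units <- (t - i) %/% m
      if (units < minUnits) next
      unit <- paste(chars[i:(i + m - 1L)], collapse = "")
      if (!all(strsplit(unit, "")[[1L]] %in% acgt)) next
      periodic <- FALSE
      for (d in seq_len(m - 1L)) {
        if (m %% d == 0L &&
            strrep(substr(unit, 1L, d), m / d) == unit) periodic <- TRUE
      }
      if (periodic) next
      out[[length(out) + 1L]] <- data.frame(
        start = i, end = i + units * m - 1L,
        motif = microsatMiner::canonicalizeMotif(unit),
        motifSize = m, unitCount = units, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motifSize = integer(0),
                      unitCount = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$motifSize), , drop = FALSE]
}

lociToDf <- function(gr) {
  data.frame(start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             motif = S4Vectors::mcols(gr)$motif,
             motifSize = S4Vectors::mcols(gr)$motifSize,
             unitCount = S4Vectors::mcols(gr)$unitCount,
             stringsAsFactors = FALSE)
}

randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Reconstruction of the published screenshot locus: a trinucleotide
## (TTG) tract of six consensus units with spanning reads carrying six
## or seven perfect copies (the seven-unit reads bear a 3-bp insertion
## CIGAR), two length variants in total.
fig1Contig <- function() {
  left <- "CCTGAGTCAAGGTCAGCAGATCGATTGACA"   # 30 bp
  right <- "ACCTGGATCAGCATTAGGATCCAGTCGGAC"  # 30 bp
  paste0(left, strrep("TTG", 6), right)      # tract at 31..48
}

fig1Reads <- function(n6 = 10L, n7 = 4L) {
  contig <- fig1Contig()
  reads6 <- data.frame(
    qname = sprintf("six_%02d", seq_len(n6)), rname = "isotig_fig1",
    pos = 21L, cigar = "40M", seq = substr(contig, 21L, 60L),
    stringsAsFactors = FALSE)
  seq7 <- paste0(substr(contig, 21L, 30L), strrep("TTG", 7L),
                 substr(contig, 49L, 58L))
  reads7 <- data.frame(
    qname = sprintf("seven_%02d", seq_len(n7)), rname = "isotig_fig1",
    pos = 21L, cigar = "28M3I10M", seq = seq7,
    stringsAsFactors = FALSE)
  rbind(reads6, reads7)
}

fig1SamFasta <- function(dir = tempfile("fig1")) {
  dir.create(dir, showWarnings = FALSE)
  contig <- fig1Contig()
  fasta <- file.path(dir, "contig.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(isotig_fig1 = contig)), fasta)
  sam <- file.path(dir, "reads.sam")
  writeSam(fig1Reads(), c(isotig_fig1 = nchar(contig)), sam)
  list(fasta = fasta, sam = sam, contig = contig)
}

## One-locus contig + arbitrary read list -> SAM/FASTA pair on disk.
samFixture <- function(reads, contig, contigName = "contig1",
                       dir = tempfile("sam")) {
  dir.create(dir, showWarnings = FALSE)
  fasta <- file.path(dir, "contig.fasta")
  seqs <- Biostrings::DNAStringSet(stats::setNames(contig, contigName))
  Biostrings::writeXStringSet(seqs, fasta)
  sam <- file.path(dir, "reads.sam")
  writeSam(reads, stats::setNames(nchar(contig), contigName), sam)
  list(fasta = fasta, sam = sam)
}

## Draw n diploid genotypes at Hardy-Weinberg proportions.
hweGenotypes <- function(n, p) {
  k <- length(p)
  a1 <- sample.int(k, n, replace = TRUE, prob = p)
  a2 <- sample.int(k, n, replace = TRUE, prob = p)
  list(a1 = a1, a2 = a2)
}

## Profile-table row constructor for selector tests.
profRow <- function(locus_id, contig_id = locus_id, n_alleles = 2L,
                    depth = 10L, is_variable = TRUE, flank = 50L,
                    coverage = 5L, min_units = 6L, n_off = 2L) {
  data.frame(locus_id = locus_id, contig_id = contig_id,
             depth_spanning = depth, n_alleles_insilico = n_alleles,
             consensus_units = min_units, n_off_consensus = n_off,
             min_units = min_units, is_variable = is_variable,
             flank_left_bp = flank, flank_right_bp = flank,
             min_coverage_region = coverage, stringsAsFactors = FALSE)
}
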