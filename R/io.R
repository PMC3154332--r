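## Shared readers/writers and small I/O utilities.
##
## Interchange dialect: tab-separated UTF-8, '.' decimal, header line,
## preceded by one '#' comment line recording tool version + parameters.
## Coordinates are 1-based inclusive in TSVs and 0-based half-open in BED.
## All writers are atomic (temp file in the target directory + rename).

toolHeader <- function(params = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("microsatMiner")),
                  error = function(e) "dev")
  extra <- if (length(params))
    paste0(" ", paste(names(params), unlist(params), sep = "=",
                      collapse = " ")) else ""
  sprintf("# microsatMiner %s%s", ver, extra)
}

writeTsvAtomic <- function(df, path, params = list()) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv.tmp")
  con <- file(tmp, open = "wt", encoding = "UTF-8")
  writeLines(toolHeader(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
}

writeLinesAtomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

## Accept SAM or BAM; return a coordinate-sorted, indexed BAM path.
## SAM input is converted next to a tempfile so re-runs are side-effect
## free with respect to the input directory.
ensureBam <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!file.exists(paste0(path, ".bai")))
      Rsamtools::indexBam(path)
    return(path)
  }
  dest <- tempfile(fileext = "")
  bam <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

#' Write alignments as a SAM file
#'
#' Emits a minimal coordinate-sorted SAM with `@HD`/`@SQ` headers for
#' every contig. Used by the read simulator; exported because hand-built
#' read sets (e.g. reconstructions of published alignment screenshots)
#' are convenient test and demonstration inputs.
#'
#' @param reads data.frame with columns `qname`, `rname`, `pos`,
#'   `cigar`, `seq` and optionally `mapq` (default 60) and `qual`
#'   (default all `"I"`).
#' @param contigLengths Named integer vector: contig id -> length.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(reads, contigLengths, path) {
  stopifnot(all(c("qname", "rname", "pos", "cigar", "seq") %in%
                  names(reads)))
  if (is.null(reads$mapq)) reads$mapq <- 60L
  if (is.null(reads$qual)) reads$qual <- strrep("I", nchar(reads$seq))
  reads <- reads[order(match(reads$rname, names(contigLengths)),
                       reads$pos, reads$qname), , drop = FALSE]
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contigLengths),
                      as.integer(contigLengths)))
  body <- sprintf("%s\t0\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$rname, as.integer(reads$pos),
                  as.integer(reads$mapq), reads$cigar, reads$seq,
                  reads$qual)
  writeLinesAtomic(c(header, body), path)
}

#' Packaged transcription of the published validation tables
#'
#' `table1Fixture()` returns the 21 scoreable polymorphic loci
#' (locus id, allele count, observed/expected heterozygosity, null
#' allele frequency, HWE P) with the selection category derived from the
#' locus index (Agt1-13 immune, Agt14-40 growth, Agt41-50 selected for
#' high in silico variability). `table2Fixture()` returns the 2x2
#' in silico vs PCR polymorphism concordance counts as a matrix with the
#' in silico classification on rows. `armSizes()` returns the number of
#' primer pairs designed per selection category.
#'
#' @return See above.
#' @export
table1Fixture <- function() {
  df <- readTsv(system.file("extdata", "table1_loci.tsv",
                            package = "microsatMiner", mustWork = TRUE))
  df$category <- agtCategory(df$locus_id)
  df
}

#' @rdname table1Fixture
#' @export
table2Fixture <- function() {
  df <- readTsv(system.file("extdata", "table2_concordance.tsv",
                            package = "microsatMiner", mustWork = TRUE))
  m <- as.matrix(df[, c("pcr_polymorphic", "pcr_monomorphic")])
  rownames(m) <- df$insilico
  m
}

#' @rdname table1Fixture
#' @export
armSizes <- function() {
  c(immune = 13L, growth = 27L, insilico = 10L)
}

## Selection category from the Agt locus index: 1-13 immune-related,
## 14-40 growth-related, 41-50 chosen for high in silico variability.
agtCategory <- function(locusId) {
  idx <- as.integer(sub("^Agt", "", locusId))
  ifelse(idx <= 13L, "immune", ifelse(idx <= 40L, "growth", "insilico"))
}
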