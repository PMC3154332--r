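#' Scan a contig sequence for perfect microsatellite tracts
#'
#' Finds every maximal perfect di-, tri- and tetranucleotide tandem
#' repeat with at least `minUnits` complete motif copies, following the
#' SSRIT-style search used for transcriptome microsatellite mining.
#' Each tract is reported exactly once, at its smallest period and under
#' its canonical (minimal-rotation) motif. Partial trailing motif copies
#' do not count towards the unit number and are excluded from the
#' reported coordinates, so that `end - start + 1 == motifSize * unitCount`.
#' Ambiguity characters (anything outside A/C/G/T, e.g. `N`) terminate
#' tracts; input is uppercased before scanning.
#'
#' @param sequence A character scalar or [Biostrings::DNAString] with the
#'   contig (consensus) sequence.
#' @param minUnits Minimum number of complete motif copies. Either a
#'   single integer applied to all motif sizes or a vector named by motif
#'   size (`c("2" = 5, "3" = 5, "4" = 5)`). Default 5.
#' @param motifSizes Integer vector of motif lengths to search,
#'   subset of 2:4.
#' @param contig Contig (seqname) to label the loci with.
#' @return A [GenomicRanges::GRanges] (1-based, inclusive) sorted by
#'   start, with metadata columns `locusId`, `motif` (canonical),
#'   `motifSize` and `unitCount`.
#' @seealso [scanFasta()] for multi-record FASTA input,
#'   [canonicalizeMotif()] for the motif normalization rules.
#' @examples
#' scanContig(paste0(strrep("G", 20), strrep("AC", 5), strrep("G", 20)))
#' @export
scanContig <- function(sequence, minUnits = 5L, motifSizes = 2:4,
                       contig = "contig") {
  if (methods::is(sequence, "DNAString") || methods::is(sequence, "BString"))
    sequence <- as.character(sequence)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!all(motifSizes %in% 2:4))
    stop("motifSizes must be a subset of 2:4")
  minUnits <- expandMinUnits(minUnits, motifSizes)

  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  L <- length(chars)
  ok <- chars %in% c("A", "C", "G", "T")
  hits <- list()
  for (m in sort(as.integer(motifSizes))) {
    minU <- minUnits[[as.character(m)]]
    if (L < m * minU) next
    ## positions i where a period-m comparison holds on valid bases
    eq <- chars[seq_len(L - m)] == chars[(m + 1L):L] & ok[seq_len(L - m)]
    runs <- rle(eq)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      tractLen <- runs$lengths[k] + m      # maximal periodic block length
      units <- tractLen %/% m
      if (units < minU) next
      i <- starts[k]
      unit <- paste(chars[i:(i + m - 1L)], collapse = "")
      if (isPeriodicMotif(unit)) next      # reported at its smaller period
      hits[[length(hits) + 1L]] <- list(
        start = i, end = i + units * m - 1L,
        motif = minimalRotation(unit), motifSize = m, unitCount = units)
    }
  }
  if (length(hits) == 0L)
    return(emptyRepeatLoci())
  df <- do.call(rbind, lapply(hits, as.data.frame))
  df <- df[order(df$start, df$motifSize), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = contig,
    ranges = IRanges::IRanges(start = df$start, end = df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locusId = sprintf("%s_%s_%d", contig, df$motif, df$start),
    motif = df$motif,
    motifSize = as.integer(df$motifSize),
    unitCount = as.integer(df$unitCount))
  gr
}

expandMinUnits <- function(minUnits, motifSizes) {
  if (is.null(names(minUnits))) {
    stopifnot(length(minUnits) == 1L, minUnits >= 1)
    minUnits <- stats::setNames(rep(as.integer(minUnits),
                                    length(motifSizes)),
                                as.character(motifSizes))
  }
  missing <- setdiff(as.character(motifSizes), names(minUnits))
  if (length(missing))
    stop("minUnits lacks entries for motif sizes: ",
         paste(missing, collapse = ", "))
  as.list(minUnits)
}

emptyRepeatLoci <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locusId = character(0), motif = character(0),
    motifSize = integer(0), unitCount = integer(0))
  gr
}

#' Scan a multi-record FASTA file for microsatellites
#'
#' Applies [scanContig()] to every record of a FASTA file. Record ids
#' (first whitespace-delimited token) become contig ids.
#'
#' @param fasta Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @inheritParams scanContig
#' @return A [GenomicRanges::GRanges] with one range per detected locus,
#'   seqnames = contig ids; empty (zero ranges) for an empty FASTA.
#' @export
scanFasta <- function(fasta, minUnits = 5L, motifSizes = 2:4) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  perContig <- lapply(seq_along(seqs), function(i)
    scanContig(seqs[[i]], minUnits = minUnits, motifSizes = motifSizes,
               contig = names(seqs)[i]))
  if (length(perContig) == 0L) return(emptyRepeatLoci())
  ans <- suppressWarnings(do.call(c, perContig))
  GenomeInfoDb::seqlevels(ans) <- names(seqs)
  ans
}

#' Write / read the locus table interchange TSV
#'
#' Coordinates in the TSV are 1-based inclusive. A leading `#` comment
#' line records the tool version and parameters; readers skip it.
#'
#' @param loci A `GRanges` as returned by [scanContig()]/[scanFasta()].
#' @param path Output (input) TSV path.
#' @param params Optional named list echoed into the header comment.
#' @return `writeLociTsv` returns `path` invisibly; `readLociTsv`
#'   returns the loci `GRanges`.
#' @export
writeLociTsv <- function(loci, path, params = list()) {
  df <- data.frame(
    locus_id = S4Vectors::mcols(loci)$locusId,
    contig_id = as.character(GenomicRanges::seqnames(loci)),
    motif = S4Vectors::mcols(loci)$motif,
    motif_size = S4Vectors::mcols(loci)$motifSize,
    start_1based = GenomicRanges::start(loci),
    end_1based = GenomicRanges::end(loci),
    unit_count = S4Vectors::mcols(loci)$unitCount,
    stringsAsFactors = FALSE)
  writeTsvAtomic(df, path, params)
}

#' @rdname writeLociTsv
#' @export
readLociTsv <- function(path) {
  df <- readTsv(path)
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig_id,
    ranges = IRanges::IRanges(start = df$start_1based,
                              end = df$end_1based))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locusId = df$locus_id, motif = df$motif,
    motifSize = as.integer(df$motif_size),
    unitCount = as.integer(df$unit_count))
  gr
}
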