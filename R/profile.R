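## assembly_profiler: per-read repeat-unit counting over read-to-contig
## alignments, and aggregation into in silico allele profiles.

parseCigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*")
    return(list(len = integer(0), op = character(0)))
  toks <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
       op = sub("^\\d+", "", toks))
}

cigarRefWidth <- function(cigar) {
  p <- parseCigar(cigar)
  sum(p$len[p$op %in% c("M", "=", "X", "D", "N")])
}

## Map every read base to its reference coordinate (NA for soft clips
## and insertions); for inserted bases record the insertion point: the
## 1-based reference position the insertion precedes.
walkAlignment <- function(pos, cigar, seq) {
  p <- parseCigar(cigar)
  n <- nchar(seq)
  refAt <- rep(NA_integer_, n)
  insBefore <- rep(NA_integer_, n)
  r <- as.integer(pos)   # next reference base to consume
  q <- 1L                # next read base to consume
  for (i in seq_along(p$op)) {
    len <- p$len[i]
    switch(p$op[i],
      "M" = , "=" = , "X" = {
        refAt[q:(q + len - 1L)] <- r:(r + len - 1L)
        r <- r + len; q <- q + len
      },
      "I" = {
        insBefore[q:(q + len - 1L)] <- r
        q <- q + len
      },
      "S" = { q <- q + len },
      "D" = , "N" = { r <- r + len },
      "H" = , "P" = NULL)
  }
  list(refAt = refAt, insBefore = insBefore,
       refStart = as.integer(pos), refEnd = r - 1L)
}

#' Count repeat units carried by one aligned read at a locus
#'
#' Classifies a read against a repeat locus and, when possible, counts
#' the number of complete motif copies the read carries. A read is
#' `non_spanning` unless its aligned reference span covers the full
#' tract plus `anchorLen` bases of flank on each side. For spanning
#' reads the read subsequence aligned between the two flank anchors is
#' extracted (insertions inside the tract are included, deletions shrink
#' it); if the two anchors do not exactly match the contig flanks, or
#' the extracted segment is not a whole number of perfect motif copies,
#' the read is `irregular` (a substitution inside the tract must not
#' fabricate a length allele); otherwise it is `counted` with that unit
#' count.
#'
#' @param read A list or one-row data.frame with elements `qname`,
#'   `rname`, `pos`, `cigar`, `seq`.
#' @param locus A single-range `GRanges` from [scanContig()].
#' @param refSeq The contig consensus sequence (character or
#'   `DNAString`) the locus lies on.
#' @param anchorLen Exact-match flank anchor length in bp (default 5).
#' @return A one-row data.frame: `readId`, `locusId`, `spans`,
#'   `unitCount` (`NA` unless counted), `status` in
#'   `counted | non_spanning | irregular`.
#' @export
countUnits <- function(read, locus, refSeq, anchorLen = 5L) {
  stopifnot(length(locus) == 1L, anchorLen >= 1L)
  if (methods::is(refSeq, "DNAString")) refSeq <- as.character(refSeq)
  contig <- as.character(GenomicRanges::seqnames(locus))
  if (as.character(read$rname) != contig)
    stop(sprintf("read %s is aligned to %s, not to locus contig %s",
                 read$qname, read$rname, contig))
  ts <- GenomicRanges::start(locus)
  te <- GenomicRanges::end(locus)
  if (ts - anchorLen < 1L || te + anchorLen > nchar(refSeq))
    stop(sprintf(
      "locus %s tract plus %d-bp anchors falls outside contig %s",
      S4Vectors::mcols(locus)$locusId, anchorLen, contig))

  obs <- function(status, units = NA_integer_)
    data.frame(readId = read$qname,
               locusId = S4Vectors::mcols(locus)$locusId,
               spans = status != "non_spanning",
               unitCount = units, status = status,
               stringsAsFactors = FALSE)

  w <- walkAlignment(read$pos, read$cigar, as.character(read$seq))
  if (w$refStart > ts - anchorLen || w$refEnd < te + anchorLen)
    return(obs("non_spanning"))

  bases <- strsplit(toupper(as.character(read$seq)), "", fixed = TRUE)[[1L]]
  pick <- function(lo, hi) {
    sel <- !is.na(w$refAt) & w$refAt >= lo & w$refAt <= hi
    paste(bases[sel], collapse = "")
  }
  leftAnchor <- pick(ts - anchorLen, ts - 1L)
  rightAnchor <- pick(te + 1L, te + anchorLen)
  refLeft <- toupper(substr(refSeq, ts - anchorLen, ts - 1L))
  refRight <- toupper(substr(refSeq, te + 1L, te + anchorLen))
  insInAnchor <- any(!is.na(w$insBefore) &
                       ((w$insBefore > ts - anchorLen & w$insBefore < ts) |
                        (w$insBefore > te + 1L &
                         w$insBefore <= te + anchorLen)))
  if (leftAnchor != refLeft || rightAnchor != refRight || insInAnchor)
    return(obs("irregular"))

  inTract <- (!is.na(w$refAt) & w$refAt >= ts & w$refAt <= te) |
    (!is.na(w$insBefore) & w$insBefore >= ts & w$insBefore <= te + 1L)
  segment <- paste(bases[inTract], collapse = "")
  m <- S4Vectors::mcols(locus)$motifSize
  unit <- toupper(substr(refSeq, ts, ts + m - 1L))  # tract-phase motif
  if (nchar(segment) %% m != 0L)
    return(obs("irregular"))
  k <- nchar(segment) %/% m
  if (k > 0L && segment != strrep(unit, k))
    return(obs("irregular"))
  obs("counted", as.integer(k))
}

#' Build the in silico allele profile of a locus
#'
#' Aggregates per-read observations (see [countUnits()]) into an
#' [InSilicoProfile-class]: the histogram of repeat-unit counts over
#' cleanly counted spanning reads, the consensus (modal) unit count,
#' the number of off-consensus reads, and the variability call. Ties for
#' the mode are broken towards the contig-consensus unit count, then
#' towards the smaller count. A locus is called variable when at least
#' one non-consensus length class holds at least `minMinorReads` reads;
#' the default of 1 replicates a classification in which even a single
#' discordant read marks a locus as variable, while larger values
#' implement the stricter "several discordant reads" policy.
#'
#' @param locus A single-range `GRanges` from [scanContig()].
#' @param observations data.frame of read observations for this locus
#'   (rbind of [countUnits()] rows).
#' @param minMinorReads Minimum reads in a non-consensus length class
#'   for the locus to be called variable (default 1).
#' @return An [InSilicoProfile-class] object. With zero counted reads
#'   the profile has depth 0, `isVariable = FALSE` and is flagged
#'   low-coverage.
#' @export
buildProfile <- function(locus, observations, minMinorReads = 1L) {
  stopifnot(minMinorReads >= 1L)
  locusId <- S4Vectors::mcols(locus)$locusId
  if (nrow(observations) &&
      !all(observations$locusId == locusId))
    stop("observations are not all for locus ", locusId)
  nIrr <- sum(observations$status == "irregular")
  nNon <- sum(observations$status == "non_spanning")
  counted <- observations$unitCount[observations$status == "counted"]
  if (length(counted) == 0L) {
    return(methods::new("InSilicoProfile",
      locusId = locusId, depthSpanning = 0L,
      alleleHistogram = stats::setNames(integer(0), character(0)),
      consensusUnits = NA_integer_, nAlleles = 0L,
      nOffConsensus = 0L, minUnitsObserved = NA_integer_,
      isVariable = FALSE, nIrregular = nIrr, nNonSpanning = nNon,
      lowCoverage = TRUE))
  }
  tab <- table(counted)
  units <- as.integer(names(tab))
  counts <- as.integer(tab)
  o <- order(units)
  units <- units[o]; counts <- counts[o]
  top <- which(counts == max(counts))
  consensus <- if (length(top) > 1L &&
                   S4Vectors::mcols(locus)$unitCount %in% units[top])
    S4Vectors::mcols(locus)$unitCount
  else units[top[1L]]  # units sorted ascending: smaller count wins ties
  minor <- counts[units != consensus]
  methods::new("InSilicoProfile",
    locusId = locusId,
    depthSpanning = length(counted),
    alleleHistogram = stats::setNames(counts, as.character(units)),
    consensusUnits = as.integer(consensus),
    nAlleles = length(units),
    nOffConsensus = length(counted) - counts[units == consensus],
    minUnitsObserved = min(units),
    isVariable = any(minor >= minMinorReads),
    nIrregular = nIrr, nNonSpanning = nNon,
    lowCoverage = FALSE)
}

#' Profile every locus of a contig set from read alignments
#'
#' Runs [countUnits()] for every read intersecting each repeat locus and
#' aggregates the results with [buildProfile()]. SAM input is converted
#' to sorted, indexed BAM internally.
#'
#' @param alignments Path to a SAM or BAM file with CIGAR-bearing
#'   read-to-contig alignments.
#' @param fasta Contig FASTA path or `DNAStringSet`.
#' @param loci `GRanges` of repeat loci ([scanFasta()] output).
#' @param anchorLen,minMinorReads See [countUnits()], [buildProfile()].
#' @return Named list of [InSilicoProfile-class] objects (one per locus,
#'   names = locus ids).
#' @export
profileLoci <- function(alignments, fasta, loci, anchorLen = 5L,
                        minMinorReads = 1L) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bam <- ensureBam(alignments)
  what <- c("qname", "flag", "rname", "pos", "cigar", "seq")
  recs <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = what))[[1L]]
  keep <- !is.na(recs$pos) & bitwAnd(recs$flag, 4L) == 0L
  reads <- data.frame(qname = recs$qname[keep],
                      rname = as.character(recs$rname[keep]),
                      pos = recs$pos[keep],
                      cigar = recs$cigar[keep],
                      seq = as.character(recs$seq[keep]),
                      stringsAsFactors = FALSE)
  reads$refEnd <- reads$pos +
    vapply(reads$cigar, cigarRefWidth, integer(1L)) - 1L

  profiles <- vector("list", length(loci))
  for (i in seq_along(loci)) {
    locus <- loci[i]
    contig <- as.character(GenomicRanges::seqnames(locus))
    if (!contig %in% names(seqs))
      stop("locus contig not in FASTA: ", contig)
    ts <- GenomicRanges::start(locus); te <- GenomicRanges::end(locus)
    hit <- reads$rname == contig & reads$pos <= te & reads$refEnd >= ts
    idx <- which(hit)
    obsList <- lapply(idx, function(j)
      countUnits(reads[j, ], locus, seqs[[contig]], anchorLen))
    obsDf <- if (length(obsList)) do.call(rbind, obsList)
      else data.frame(readId = character(0), locusId = character(0),
                      spans = logical(0), unitCount = integer(0),
                      status = character(0))
    profiles[[i]] <- buildProfile(locus, obsDf, minMinorReads)
  }
  names(profiles) <- S4Vectors::mcols(loci)$locusId
  profiles
}

#' Tabulate a set of locus profiles
#'
#' Flattens a list of [InSilicoProfile-class] objects into the profile
#' interchange table (one row per locus; histogram serialized as
#' `"units:count;..."`).
#'
#' @param profiles List of profiles from [profileLoci()].
#' @return data.frame with columns `locus_id`, `depth_spanning`,
#'   `n_alleles_insilico`, `consensus_units`, `n_off_consensus`,
#'   `min_units`, `is_variable`, `n_irregular`, `n_non_spanning`,
#'   `histogram`.
#' @export
profileTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) data.frame(
    locus_id = p@locusId,
    depth_spanning = p@depthSpanning,
    n_alleles_insilico = p@nAlleles,
    consensus_units = p@consensusUnits,
    n_off_consensus = p@nOffConsensus,
    min_units = p@minUnitsObserved,
    is_variable = p@isVariable,
    n_irregular = p@nIrregular,
    n_non_spanning = p@nNonSpanning,
    histogram = paste(names(p@alleleHistogram), p@alleleHistogram,
                      sep = ":", collapse = ";"),
    stringsAsFactors = FALSE)))
}

#' @rdname profileTable
#' @param path TSV path.
#' @param params Optional named list echoed into the header comment.
#' @export
writeProfilesTsv <- function(profiles, path, params = list()) {
  writeTsvAtomic(profileTable(profiles), path, params)
}

#' @rdname profileTable
#' @export
readProfilesTsv <- function(path) {
  df <- readTsv(path)
  df$is_variable <- as.logical(df$is_variable)
  df
}
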