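#' Canonicalize a microsatellite motif
#'
#' Reduces a short tandem-repeat motif to the lexicographically minimal
#' rotation of its cycle class, so that the same repeat tract is never
#' reported under two different rotations (e.g. `"CAC"`, `"ACC"` and
#' `"CCA"` all name the same dinucleotide-free trinucleotide repeat and
#' canonicalize to `"ACC"`). Motifs that are themselves a whole-number
#' repetition of a shorter string (e.g. `"ATAT"` = `"AT"` twice) are
#' rejected: such tracts belong to the smaller period.
#'
#' Reverse complements are deliberately not collapsed: transcript
#' consensus sequences are stranded, and a repeat is reported on the
#' strand it is given on.
#'
#' @param motif Character scalar, 2-4 uppercase or lowercase A/C/G/T.
#' @return The canonical (minimal-rotation) motif, uppercase.
#'   Periodic motifs raise an error of class `periodic_motif_error`;
#'   non-ACGT characters raise `invalid_motif_error`.
#' @examples
#' canonicalizeMotif("CAC")  # "ACC"
#' canonicalizeMotif("TTG")  # "GTT"
#' @export
canonicalizeMotif <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop(motifError("motif must be a single character string",
                    "invalid_motif_error"))
  motif <- toupper(motif)
  m <- nchar(motif)
  if (m < 2L || m > 4L)
    stop(motifError(sprintf("motif '%s' has length %d; expected 2-4",
                            motif, m), "invalid_motif_error"))
  chars <- strsplit(motif, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop(motifError(sprintf("motif '%s' contains non-ACGT characters",
                            motif), "invalid_motif_error"))
  if (isPeriodicMotif(motif))
    stop(motifError(sprintf(
      "motif '%s' is a repetition of a shorter motif", motif),
      "periodic_motif_error"))
  minimalRotation(motif)
}

motifError <- function(msg, class) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

## TRUE when the motif is a whole-number repetition of a proper divisor-
## length prefix (period 1 included, so homopolymer "units" are periodic).
isPeriodicMotif <- function(motif) {
  m <- nchar(motif)
  for (d in seq_len(m - 1L)) {
    if (m %% d != 0L) next
    unit <- substr(motif, 1L, d)
    if (strrep(unit, m %/% d) == motif) return(TRUE)
  }
  FALSE
}

minimalRotation <- function(motif) {
  m <- nchar(motif)
  doubled <- paste0(motif, motif)
  rots <- vapply(seq_len(m), function(i) substr(doubled, i, i + m - 1L), "")
  sort(rots)[1L]
}
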