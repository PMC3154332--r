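## candidate_selector: marker-selection filters over profiled loci.

#' Selection rule set for candidate microsatellite markers
#'
#' Bundles the marker-selection criteria: (i) sufficient flanking
#' sequence on both sides of the tract for primer design, quantified as
#' `minFlankBp` per side; (ii) minimum read coverage of the tract and
#' adjacent flanks (`minRegionCoverage`, default 2); (iii) functional
#' (BLAST/GO) annotation; (iv) mapping to a reference genome; at most
#' one representative per isogroup; and optionally in silico
#' variability.
#'
#' @param minFlankBp Minimum flanking sequence per side, bp (default 30:
#'   room for a primer plus slack; a configurable stand-in for
#'   "sufficient flanking sequence").
#' @param minRegionCoverage Minimum read depth across tract + flanks
#'   (default 2).
#' @param requireAnnotated,requireMapped Require the annotation /
#'   genome-mapping flag (default `TRUE`).
#' @param onePerIsogroup Keep a single representative per isogroup
#'   (default `TRUE`).
#' @param requireVariable Keep only loci called variable in silico
#'   (default `FALSE`; the selection arm targeting highly variable
#'   loci sets this).
#' @return A named list of class `mmSelectionRules`.
#' @export
selectionRules <- function(minFlankBp = 30L, minRegionCoverage = 2L,
                           requireAnnotated = TRUE, requireMapped = TRUE,
                           onePerIsogroup = TRUE,
                           requireVariable = FALSE) {
  stopifnot(minFlankBp >= 0L, minRegionCoverage >= 0L)
  structure(list(minFlankBp = as.integer(minFlankBp),
                 minRegionCoverage = as.integer(minRegionCoverage),
                 requireAnnotated = isTRUE(requireAnnotated),
                 requireMapped = isTRUE(requireMapped),
                 onePerIsogroup = isTRUE(onePerIsogroup),
                 requireVariable = isTRUE(requireVariable)),
            class = "mmSelectionRules")
}

#' Tag contigs by GO-term substring match
#'
#' Case-insensitive substring match of each pattern against the GO term
#' text of an annotation table, used to restrict candidates to
#' functional classes of interest (e.g. patterns `"immun"` and
#' `"growth"`). A contig matching several patterns receives every
#' matching tag; contigs missing from the table are untagged and
#' unannotated.
#'
#' @param annotations data.frame with columns `contig_id`,
#'   `isogroup_id`, `go_terms`, `annotated`, `mapped`.
#' @param patterns Character vector of substrings to match.
#' @return The annotation table with an added `category_tags` column
#'   (semicolon-joined matching patterns, `""` when none).
#' @export
matchAnnotation <- function(annotations, patterns) {
  stopifnot(is.data.frame(annotations),
            all(c("contig_id", "go_terms") %in% names(annotations)))
  tags <- vapply(annotations$go_terms, function(txt) {
    if (is.na(txt)) return("")
    hit <- patterns[vapply(patterns, function(p)
      grepl(p, txt, ignore.case = TRUE, fixed = FALSE), logical(1L))]
    paste(hit, collapse = ";")
  }, "", USE.NAMES = FALSE)
  annotations$category_tags <- tags
  annotations
}

#' Apply marker-selection filters to profiled loci
#'
#' Evaluates every selection rule against every locus and records which
#' rules each locus fails; a locus is selected when it fails none.
#' With `onePerIsogroup`, exactly one passing locus is retained per
#' isogroup: the one with the most in silico alleles, ties broken by
#' spanning depth and then locus id (deterministic); displaced loci are
#' marked with the failure `"isogroup_redundant"`.
#'
#' @param profiles Profile table (from [profileTable()] or
#'   [readProfilesTsv()]) augmented with per-locus columns `contig_id`,
#'   `flank_left_bp`, `flank_right_bp` and `min_coverage_region`
#'   (minimum depth over tract + flanks; see [regionCoverage()]).
#' @param annotations Optional annotation table (see
#'   [matchAnnotation()]); missing contigs count as unannotated and
#'   unmapped.
#' @param rules A [selectionRules()] object.
#' @param patterns Patterns forwarded to [matchAnnotation()] when
#'   `annotations` carries no `category_tags` column.
#' @return data.frame of candidates: profile columns plus `annotated`,
#'   `mapped`, `isogroup_id`, `category_tags`, `filter_failures`
#'   (semicolon-joined rule ids, `""` when none) and `selected`.
#' @export
selectCandidates <- function(profiles, annotations = NULL,
                             rules = selectionRules(),
                             patterns = c("immun", "growth")) {
  stopifnot(inherits(rules, "mmSelectionRules"))
  req <- c("locus_id", "contig_id", "flank_left_bp", "flank_right_bp",
           "min_coverage_region", "n_alleles_insilico",
           "depth_spanning", "is_variable")
  missing <- setdiff(req, names(profiles))
  if (length(missing))
    stop("profiles table lacks columns: ", paste(missing, collapse = ", "))
  df <- profiles
  if (nrow(df) == 0L) {
    df$annotated <- logical(0); df$mapped <- logical(0)
    df$isogroup_id <- character(0); df$category_tags <- character(0)
    df$filter_failures <- character(0); df$selected <- logical(0)
    return(df)
  }
  if (!is.null(annotations) && !"category_tags" %in% names(annotations))
    annotations <- matchAnnotation(annotations, patterns)
  if (is.null(annotations)) {
    df$annotated <- FALSE; df$mapped <- FALSE
    df$isogroup_id <- NA_character_; df$category_tags <- ""
  } else {
    j <- match(df$contig_id, annotations$contig_id)
    df$annotated <- !is.na(j) & isTRUE_v(annotations$annotated[j])
    df$mapped <- !is.na(j) & isTRUE_v(annotations$mapped[j])
    df$isogroup_id <- ifelse(is.na(j), NA_character_,
                             annotations$isogroup_id[j])
    df$category_tags <- ifelse(is.na(j), "", annotations$category_tags[j])
  }

  failures <- lapply(seq_len(nrow(df)), function(i) {
    f <- character(0)
    if (df$flank_left_bp[i] < rules$minFlankBp ||
        df$flank_right_bp[i] < rules$minFlankBp) f <- c(f, "flank")
    if (df$min_coverage_region[i] < rules$minRegionCoverage)
      f <- c(f, "coverage")
    if (rules$requireAnnotated && !df$annotated[i]) f <- c(f, "annotated")
    if (rules$requireMapped && !df$mapped[i]) f <- c(f, "mapped")
    if (rules$requireVariable && !isTRUE(df$is_variable[i]))
      f <- c(f, "variable")
    f
  })
  passing <- lengths(failures) == 0L

  if (rules$onePerIsogroup) {
    grouped <- passing & !is.na(df$isogroup_id)
    for (ig in unique(df$isogroup_id[grouped])) {
      idx <- which(grouped & df$isogroup_id == ig)
      if (length(idx) < 2L) next
      ord <- idx[order(-df$n_alleles_insilico[idx],
                       -df$depth_spanning[idx], df$locus_id[idx])]
      for (lose in ord[-1L]) {
        failures[[lose]] <- c(failures[[lose]], "isogroup_redundant")
        passing[lose] <- FALSE
      }
    }
  }
  df$filter_failures <- vapply(failures, paste, "", collapse = ";")
  df$selected <- passing
  ## deterministic output order regardless of input order
  df[order(df$locus_id), , drop = FALSE]
}

isTRUE_v <- function(x) !is.na(x) & (x == TRUE | x == "TRUE" | x == 1)

#' Minimum read depth over tract + flank windows
#'
#' Computes, per locus, the minimum aligned-base depth over the window
#' tract +/- `flankBp`, clipped to the contig — the quantity the
#' coverage selection criterion tests — plus the available flanking
#' sequence on each side.
#'
#' @param alignments SAM/BAM path.
#' @param fasta Contig FASTA path or `DNAStringSet` (for contig
#'   lengths).
#' @param loci Locus `GRanges`.
#' @param flankBp Flank window width in bp (default 30).
#' @return data.frame `locus_id`, `flank_left_bp`, `flank_right_bp`,
#'   `min_coverage_region`.
#' @export
regionCoverage <- function(alignments, fasta, loci, flankBp = 30L) {
  seqs <- if (methods::is(fasta, "DNAStringSet")) fasta
          else Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  bam <- ensureBam(alignments)
  res <- lapply(seq_along(loci), function(i) {
    locus <- loci[i]
    contig <- as.character(GenomicRanges::seqnames(locus))
    clen <- nchar(as.character(seqs[[contig]]))
    ts <- GenomicRanges::start(locus); te <- GenomicRanges::end(locus)
    lo <- max(1L, ts - flankBp); hi <- min(clen, te + flankBp)
    region <- GenomicRanges::GRanges(contig, IRanges::IRanges(lo, hi))
    S4Vectors::mcols(region)$locusId <- S4Vectors::mcols(locus)$locusId
    rep <- screenPrimerSites(bam, region, snpMinMinorReads = 10^9L)[[1L]]
    data.frame(locus_id = S4Vectors::mcols(locus)$locusId,
               flank_left_bp = ts - 1L,
               flank_right_bp = clen - te,
               min_coverage_region = minRegionDepth(rep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Export primer-design windows as BED
#'
#' Writes the tract +/- flank window of each selected candidate as a
#' BED interval (0-based half-open, per BED convention) for a
#' downstream primer-design run targeting 100-250 bp products.
#'
#' @param candidates Output of [selectCandidates()], needing columns
#'   `locus_id`, `contig_id`, `start_1based`, `end_1based`, `selected`.
#' @param path Output BED path.
#' @param flankBp Window flank width (default 100, half the maximum
#'   target product size).
#' @param selectedOnly Restrict to selected candidates (default `TRUE`).
#' @return `path`, invisibly.
#' @export
writePrimerWindowsBed <- function(candidates, path, flankBp = 100L,
                                  selectedOnly = TRUE) {
  df <- if (selectedOnly) candidates[candidates$selected, , drop = FALSE]
        else candidates
  lines <- sprintf("%s\t%d\t%d\t%s",
                   df$contig_id,
                   pmax(0L, df$start_1based - 1L - flankBp),
                   df$end_1based + flankBp,
                   df$locus_id)
  writeLinesAtomic(lines, path)
}
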