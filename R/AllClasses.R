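#' In silico allele profile of one microsatellite locus
#'
#' Read-level summary of a repeat locus built from spanning reads:
#' the allele histogram (repeat-unit count -> number of reads), the
#' consensus (modal) unit count, the number of reads differing from the
#' consensus, and the variability classification. Because the reads come
#' from pooled individuals, "alleles" here are distinct motif-length
#' classes among reads, not diploid genotype calls.
#'
#' @slot locusId Locus identifier.
#' @slot depthSpanning Number of spanning reads with a clean unit count.
#' @slot alleleHistogram Named integer vector: unit count (as name) ->
#'   read count, names sorted numerically.
#' @slot consensusUnits Modal unit count (ties broken towards the contig
#'   consensus count, then towards the smaller count); `NA` at depth 0.
#' @slot nAlleles Number of distinct unit counts observed.
#' @slot nOffConsensus Reads whose unit count differs from the consensus.
#' @slot minUnitsObserved Smallest unit count observed (`NA` at depth 0).
#' @slot isVariable `TRUE` when at least one non-consensus length class
#'   has at least `minMinorReads` reads (see [buildProfile()]).
#' @slot nIrregular Reads spanning the tract whose extracted segment was
#'   not a whole number of perfect motif copies with intact anchors.
#' @slot nNonSpanning Reads intersecting the tract without covering
#'   tract + both anchors.
#' @slot lowCoverage `TRUE` when no read could be counted.
#' @seealso [buildProfile()], [profileLoci()]
#' @export
setClass("InSilicoProfile",
  representation(
    locusId = "character",
    depthSpanning = "integer",
    alleleHistogram = "integer",
    consensusUnits = "integer",
    nAlleles = "integer",
    nOffConsensus = "integer",
    minUnitsObserved = "integer",
    isVariable = "logical",
    nIrregular = "integer",
    nNonSpanning = "integer",
    lowCoverage = "logical"))

setValidity("InSilicoProfile", function(object) {
  msg <- character(0)
  h <- object@alleleHistogram
  if (sum(h) != object@depthSpanning)
    msg <- c(msg, "sum(alleleHistogram) != depthSpanning")
  if (object@nAlleles != sum(h >= 1L))
    msg <- c(msg, "nAlleles != number of occupied histogram classes")
  if (object@depthSpanning > 0L) {
    cons <- as.character(object@consensusUnits)
    consCount <- if (cons %in% names(h)) h[[cons]] else 0L
    if (object@nOffConsensus != object@depthSpanning - consCount)
      msg <- c(msg, "nOffConsensus != depthSpanning - consensus class size")
    if (object@minUnitsObserved != min(as.integer(names(h))))
      msg <- c(msg, "minUnitsObserved != smallest histogram key")
  }
  if (object@isVariable && object@nAlleles < 2L)
    msg <- c(msg, "isVariable requires >= 2 length classes")
  if (length(msg)) msg else TRUE
})

#' @export
setMethod("show", "InSilicoProfile", function(object) {
  cat("InSilicoProfile for", object@locusId, "\n")
  cat("  spanning reads counted:", object@depthSpanning,
      "(irregular:", object@nIrregular,
      ", non-spanning:", paste0(object@nNonSpanning, ")"), "\n")
  if (object@depthSpanning > 0L) {
    cat("  allele histogram (units:reads):",
        paste(names(object@alleleHistogram), object@alleleHistogram,
              sep = ":", collapse = "; "), "\n")
    cat("  consensus units:", object@consensusUnits,
        " off-consensus reads:", object@nOffConsensus, "\n")
    cat("  inferred alleles:", object@nAlleles,
        " variable:", object@isVariable, "\n")
  } else {
    cat("  low coverage: no countable spanning reads\n")
  }
  invisible(NULL)
})

#' Primer binding-site SNP screen for one locus
#'
#' Per-column base-count screen of designated primer-site regions on a
#' profiled contig, used to flag candidate loci whose primer sites carry
#' sequence variants (a common cause of null alleles).
#'
#' @slot locusId Locus identifier.
#' @slot contig Contig the regions lie on.
#' @slot regionStart,regionEnd 1-based inclusive bounds of the screened
#'   region (union of columns screened).
#' @slot minDepth Minimum aligned-base depth over the region (alignment
#'   gaps and pads do not count towards depth); 0 if any column is
#'   uncovered.
#' @slot snps data.frame with one row per SNP column: `pos`, `major`,
#'   `minor`, `minorCount`, `depth`, `maf` (always in (0, 0.5]).
#' @seealso [screenPrimerSites()]
#' @export
setClass("PrimerSiteReport",
  representation(
    locusId = "character",
    contig = "character",
    regionStart = "integer",
    regionEnd = "integer",
    minDepth = "integer",
    snps = "data.frame"))

setValidity("PrimerSiteReport", function(object) {
  snps <- object@snps
  if (nrow(snps) &&
      (any(snps$maf <= 0) || any(snps$maf > 0.5)))
    return("SNP minor allele frequencies must lie in (0, 0.5]")
  TRUE
})

#' @export
setMethod("show", "PrimerSiteReport", function(object) {
  cat("PrimerSiteReport for", object@locusId, "on", object@contig,
      sprintf("[%d, %d]", object@regionStart, object@regionEnd), "\n")
  cat("  minimum depth:", object@minDepth, "\n")
  if (nrow(object@snps)) {
    cat("  SNPs:\n")
    print(object@snps, row.names = FALSE)
  } else cat("  no SNPs detected\n")
  invisible(NULL)
})

## --- accessors -------------------------------------------------------

#' @rdname InSilicoProfile-class
#' @param object An `InSilicoProfile`.
#' @export
setGeneric("alleleHistogram", function(object)
  standardGeneric("alleleHistogram"))
#' @rdname InSilicoProfile-class
#' @export
setMethod("alleleHistogram", "InSilicoProfile",
          function(object) object@alleleHistogram)

#' @rdname InSilicoProfile-class
#' @export
setGeneric("nAlleles", function(object) standardGeneric("nAlleles"))
#' @rdname InSilicoProfile-class
#' @export
setMethod("nAlleles", "InSilicoProfile", function(object) object@nAlleles)

#' @rdname InSilicoProfile-class
#' @export
setGeneric("consensusUnits", function(object)
  standardGeneric("consensusUnits"))
#' @rdname InSilicoProfile-class
#' @export
setMethod("consensusUnits", "InSilicoProfile",
          function(object) object@consensusUnits)

#' @rdname InSilicoProfile-class
#' @export
setGeneric("isVariable", function(object) standardGeneric("isVariable"))
#' @rdname InSilicoProfile-class
#' @export
setMethod("isVariable", "InSilicoProfile",
          function(object) object@isVariable)

#' @rdname InSilicoProfile-class
#' @export
setGeneric("depthSpanning", function(object)
  standardGeneric("depthSpanning"))
#' @rdname InSilicoProfile-class
#' @export
setMethod("depthSpanning", "InSilicoProfile",
          function(object) object@depthSpanning)

#' @rdname PrimerSiteReport-class
#' @param object A `PrimerSiteReport`.
#' @export
setGeneric("snpTable", function(object) standardGeneric("snpTable"))
#' @rdname PrimerSiteReport-class
#' @export
setMethod("snpTable", "PrimerSiteReport", function(object) object@snps)

#' @rdname PrimerSiteReport-class
#' @export
setGeneric("minRegionDepth", function(object)
  standardGeneric("minRegionDepth"))
#' @rdname PrimerSiteReport-class
#' @export
setMethod("minRegionDepth", "PrimerSiteReport",
          function(object) object@minDepth)
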