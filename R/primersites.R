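#' Screen primer binding sites for SNPs
#'
#' Computes per-column base counts over the aligned reads within
#' designated primer-site regions and reports columns carrying a SNP:
#' at least two distinct bases each supported by `snpMinMinorReads`
#' reads. Alignment gaps (SAM deletions, assembly pads) never count
#' towards column depth. This implements the null-allele pre-screen:
#' a variant under a primer, or low coverage that could hide one, flags
#' the locus as at risk of non-amplifying alleles.
#'
#' @param alignments SAM or BAM path (converted/indexed internally).
#' @param regions A `GRanges` of primer-site regions (typically two per
#'   locus) with a `locusId` metadata column, or a data.frame with
#'   columns `locus_id`, `contig_id`, `start`, `end` (1-based
#'   inclusive).
#' @param snpMinMinorReads Minimum reads supporting the minor base for a
#'   column to be reported as a SNP (default 2).
#' @return A list of [PrimerSiteReport-class] objects, one per region.
#'   A region with zero coverage yields `minDepth = 0` and no SNPs.
#' @examples
#' \dontrun{
#' rep <- screenPrimerSites("aln.sam",
#'   data.frame(locus_id = "L1", contig_id = "contig1",
#'              start = 10, end = 30))[[1]]
#' snpTable(rep)
#' }
#' @export
screenPrimerSites <- function(alignments, regions, snpMinMinorReads = 2L) {
  stopifnot(snpMinMinorReads >= 1L)
  if (is.data.frame(regions)) {
    gr <- GenomicRanges::GRanges(
      seqnames = regions$contig_id,
      ranges = IRanges::IRanges(regions$start, regions$end))
    S4Vectors::mcols(gr)$locusId <- regions$locus_id
    regions <- gr
  }
  bam <- ensureBam(alignments)
  lapply(seq_along(regions), function(i) {
    region <- regions[i]
    pp <- Rsamtools::PileupParam(
      max_depth = 100000L, min_base_quality = 0L, min_mapq = 0L,
      min_nucleotide_depth = 1L, distinguish_strands = FALSE,
      distinguish_nucleotides = TRUE, ignore_query_Ns = TRUE,
      include_deletions = FALSE, include_insertions = FALSE)
    sp <- Rsamtools::ScanBamParam(which = region)
    pile <- Rsamtools::pileup(bam, scanBamParam = sp, pileupParam = pp)
    rs <- GenomicRanges::start(region)
    re <- GenomicRanges::end(region)
    depthAt <- stats::setNames(integer(re - rs + 1L),
                               as.character(rs:re))
    snps <- data.frame(pos = integer(0), major = character(0),
                       minor = character(0), minorCount = integer(0),
                       depth = integer(0), maf = numeric(0),
                       stringsAsFactors = FALSE)
    if (nrow(pile)) {
      for (posn in unique(pile$pos)) {
        col <- pile[pile$pos == posn, ]
        cnt <- sort(stats::setNames(col$count,
                                    as.character(col$nucleotide)),
                    decreasing = TRUE)
        depth <- sum(cnt)
        depthAt[as.character(posn)] <- depth
        if (length(cnt) >= 2L && cnt[2L] >= snpMinMinorReads) {
          snps <- rbind(snps, data.frame(
            pos = posn, major = names(cnt)[1L], minor = names(cnt)[2L],
            minorCount = unname(cnt[2L]), depth = depth,
            maf = unname(cnt[2L]) / depth, stringsAsFactors = FALSE))
        }
      }
    }
    methods::new("PrimerSiteReport",
      locusId = as.character(S4Vectors::mcols(region)$locusId),
      contig = as.character(GenomicRanges::seqnames(region)),
      regionStart = rs, regionEnd = re,
      minDepth = as.integer(min(depthAt)),
      snps = snps)
  })
}
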