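#' Replicate-occupancy consensus intervals
#'
#' DiffBind-style consensus: the union of all replicate peaks is merged into
#' disjoint intervals, and each union interval is kept if peaks from at
#' least `min_count` distinct replicates overlap it by >= 1 bp.
#'
#' @param replicates list of [peak_set()] objects, one per biological
#'   replicate.
#' @param min_count minimum number of supporting replicates
#'   (1 <= min_count <= number of replicates).
#' @return a merged `peak_set` of supported union intervals.
#' @export
occupancy_consensus <- function(replicates, min_count) {
  if (length(replicates) == 0) stop("empty replicate list")
  stopifnot(all(vapply(replicates, is_peak_set, logical(1))))
  if (min_count < 1 || min_count > length(replicates))
    stop("min_count must be between 1 and the number of replicates")
  nonempty <- replicates[vapply(replicates, nrow, 0L) > 0]
  if (length(nonempty) == 0) return(peak_set(label = "consensus"))
  union_gr <- GenomicRanges::reduce(
    do.call(c, unname(lapply(nonempty, as_gr))))
  support <- Reduce(`+`, lapply(replicates, function(r) {
    if (nrow(r) == 0) integer(length(union_gr))
    else as.integer(IRanges::overlapsAny(union_gr, as_gr(r)))
  }))
  gr_as_peaks(GenomicRanges::sort(union_gr[support >= min_count]),
              label = "consensus")
}

#' High-confidence OCRs from pooled and replicate peak calls
#'
#' Reproduces the standard high-confidence open chromatin definition: peaks
#' called on the pooled (merged, depth-matched) alignment are retained, in
#' their original pooled coordinates, when they (a) do not touch the
#' blacklist and (b) overlap by >= 1 bp a replicate-occupancy consensus
#' interval supported by at least `min_count` biological replicates.
#'
#' @param pooled [peak_set()] of pooled-sample peak calls.
#' @param replicates list of per-biological-replicate `peak_set`s.
#' @param blacklist optional `peak_set` of artifact regions; any pooled peak
#'   touching it is dropped.
#' @param min_count replicate support required (default 2, the
#'   two-of-three rule).
#' @return a `peak_set` of high-confidence OCRs (subset of `pooled` rows).
#' @export
high_confidence <- function(pooled, replicates, blacklist = NULL,
                            min_count = 2) {
  stopifnot(is_peak_set(pooled))
  if (!is.null(blacklist) && nrow(blacklist) > 0)
    pooled <- subtract_peaks(pooled, blacklist, mode = "drop_if_touch")
  if (nrow(pooled) == 0) return(set_label(pooled, "high_confidence"))
  consensus <- occupancy_consensus(replicates, min_count)
  if (nrow(consensus) == 0)
    return(set_label(pooled[0, , drop = FALSE], "high_confidence"))
  hit <- IRanges::overlapsAny(as_gr(pooled), as_gr(consensus))
  out <- pooled[hit, , drop = FALSE]
  class(out) <- class(pooled)
  set_label(out, "high_confidence")
}

#' Attribute high-confidence OCRs to NeuN+ / NeuN- fractions
#'
#' Labels each bulk OCR by >= 1 bp overlap with the peak sets called in
#' sorted NeuN+ (neuron-enriched) and NeuN- (neuron-depleted) nuclei:
#' `both`, `neun_pos_only`, `neun_neg_only`, or `neither`. The four labels
#' partition the OCR set.
#'
#' @param bulk_hc high-confidence bulk [peak_set()].
#' @param neun_pos,neun_neg fraction peak sets.
#' @return a list with `table` (data.frame: ocr_id, chrom, start, end,
#'   label) and `counts` (named integer vector over the four labels).
#' @export
attribute_fractions <- function(bulk_hc, neun_pos, neun_neg) {
  stopifnot(is_peak_set(bulk_hc), is_peak_set(neun_pos),
            is_peak_set(neun_neg))
  lv <- c("both", "neun_pos_only", "neun_neg_only", "neither")
  if (nrow(bulk_hc) == 0) {
    tab <- data.frame(ocr_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    return(list(table = tab,
                counts = stats::setNames(integer(4), lv)))
  }
  gr <- as_gr(bulk_hc)
  in_pos <- if (nrow(neun_pos) > 0)
    IRanges::overlapsAny(gr, as_gr(neun_pos)) else rep(FALSE, nrow(bulk_hc))
  in_neg <- if (nrow(neun_neg) > 0)
    IRanges::overlapsAny(gr, as_gr(neun_neg)) else rep(FALSE, nrow(bulk_hc))
  label <- ifelse(in_pos & in_neg, "both",
                  ifelse(in_pos, "neun_pos_only",
                         ifelse(in_neg, "neun_neg_only", "neither")))
  tab <- data.frame(
    ocr_id = sprintf("OCR_%05d", seq_len(nrow(bulk_hc))),
    chrom = bulk_hc$chrom, start = bulk_hc$start, end = bulk_hc$end,
    label = factor(label, levels = lv), stringsAsFactors = FALSE)
  counts <- table(tab$label)
  list(table = tab, counts = stats::setNames(as.integer(counts), lv))
}

#' Union of OCRs with overlapping histone-mark regions
#'
#' For annotations such as "OCRs overlapping H3K4me1": keeps the OCRs that
#' overlap the histone set by >= 1 bp, unions them with the histone
#' intervals they touch, and merges, yielding one interval per connected
#' component of the overlap graph.
#'
#' @param ocrs a [peak_set()].
#' @param histone a `peak_set` of histone-modification regions.
#' @return a merged `peak_set`.
#' @export
histone_subset <- function(ocrs, histone) {
  stopifnot(is_peak_set(ocrs), is_peak_set(histone))
  if (nrow(ocrs) == 0 || nrow(histone) == 0)
    return(peak_set(label = paste0(peak_label(ocrs), "+histone")))
  gro <- as_gr(ocrs); grh <- as_gr(histone)
  keep_o <- IRanges::overlapsAny(gro, grh)
  keep_h <- IRanges::overlapsAny(grh, gro)
  if (!any(keep_o))
    return(peak_set(label = paste0(peak_label(ocrs), "+histone")))
  gr <- GenomicRanges::reduce(c(gro[keep_o], grh[keep_h]))
  gr_as_peaks(GenomicRanges::sort(gr),
              label = paste0(peak_label(ocrs), "+histone"))
}
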