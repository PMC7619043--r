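## Per-chromosome IRanges view of a peak set (1-based closed), in order of
## first appearance of each chromosome. Set operations run per chromosome
## on plain IRanges, which avoids the heavier machinery of whole-genome
## containers in the simulation-heavy code paths.
ir_by_chrom <- function(x, chrom_levels = unique(x$chrom)) {
  idx <- split(seq_len(nrow(x)),
               factor(x$chrom, levels = chrom_levels))
  lapply(idx, function(i)
    IRanges::IRanges(start = x$start[i] + 1, end = x$end[i]))
}

## Reassemble a peak_set from a named list of IRanges (1-based closed).
peaks_from_ir <- function(irl, label = "") {
  n <- vapply(irl, length, 0L)
  keep <- n > 0
  out <- peak_set(rep(names(irl)[keep], n[keep]),
                  unlist(lapply(irl[keep], IRanges::start),
                         use.names = FALSE) - 1,
                  unlist(lapply(irl[keep], IRanges::end),
                         use.names = FALSE),
                  label = label)
  attr(out, "sorted") <- TRUE
  out
}

#' Merge overlapping or nearby intervals
#'
#' Collapses a peak set to the minimal sorted set of intervals covering the
#' same bases. Intervals separated by at most `gap` bp are joined; at
#' `gap = 0` this includes bookended intervals (`[a,b)` + `[b,c)` ->
#' `[a,c)`), matching `bedtools merge`.
#'
#' @param x a [peak_set()].
#' @param gap maximum separation (bp, >= 0) at which intervals are joined.
#' @return a merged `peak_set`, sorted within each chromosome.
#' @export
merge_peaks <- function(x, gap = 0) {
  stopifnot(is_peak_set(x), gap >= 0)
  if (nrow(x) == 0) return(x)
  irl <- lapply(ir_by_chrom(x), IRanges::reduce, min.gapwidth = gap + 1)
  peaks_from_ir(irl, label = peak_label(x))
}

#' Base-level intersection of two peak sets
#'
#' Returns exactly the bases present in both sets, as merged intervals.
#'
#' @param a,b [peak_set()] objects.
#' @return a merged `peak_set` of shared bases.
#' @export
intersect_peaks <- function(a, b) {
  stopifnot(is_peak_set(a), is_peak_set(b))
  if (nrow(a) == 0 || nrow(b) == 0) return(peak_set(label = peak_label(a)))
  shared <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(shared) == 0) return(peak_set(label = peak_label(a)))
  ia <- ir_by_chrom(a, shared); ib <- ir_by_chrom(b, shared)
  irl <- lapply(shared, function(ch) IRanges::intersect(ia[[ch]], ib[[ch]]))
  names(irl) <- shared
  peaks_from_ir(irl, label = peak_label(a))
}

#' Remove blacklisted regions from a peak set
#'
#' `drop_if_touch` discards every peak that overlaps the blacklist by >= 1 bp
#' (the rule used for excluding assembly artifact regions from peak calls);
#' `clip` keeps only non-overlapped bases, splitting peaks where necessary
#' and returning them merged.
#'
#' @param a a [peak_set()].
#' @param blacklist a `peak_set` of regions to remove.
#' @param mode `"drop_if_touch"` or `"clip"`.
#' @return a `peak_set`.
#' @export
subtract_peaks <- function(a, blacklist, mode = c("drop_if_touch", "clip")) {
  mode <- match.arg(mode)
  stopifnot(is_peak_set(a), is_peak_set(blacklist))
  if (nrow(a) == 0 || nrow(blacklist) == 0) return(a)
  lv <- unique(a$chrom)
  ia <- ir_by_chrom(a, lv)
  ib <- ir_by_chrom(blacklist, lv)
  if (mode == "drop_if_touch") {
    hit <- logical(nrow(a))
    idx <- split(seq_len(nrow(a)), factor(a$chrom, levels = lv))
    for (ch in lv)
      hit[idx[[ch]]] <- IRanges::overlapsAny(ia[[ch]], ib[[ch]])
    out <- a[!hit, , drop = FALSE]
    class(out) <- class(a)
    return(out)
  }
  irl <- lapply(lv, function(ch) IRanges::setdiff(ia[[ch]], ib[[ch]]))
  names(irl) <- lv
  peaks_from_ir(irl, label = peak_label(a))
}

#' Extend peaks by a flank on each side, clipped to chromosome bounds
#'
#' Each interval `[s,e)` becomes `[max(0, s - flank), min(L, e + flank))`
#' where `L` is the chromosome length; the result is re-merged. This is the
#' +/- 500 bp expansion applied to annotations before partitioned
#' heritability regression.
#'
#' @param x a [peak_set()].
#' @param flank bp to add on each side (>= 0).
#' @param genome a [genome_model()] providing chromosome lengths.
#' @return a merged `peak_set` of extended intervals.
#' @export
extend_peaks <- function(x, flank, genome) {
  stopifnot(is_peak_set(x), flank >= 0, inherits(genome, "genome_model"))
  if (nrow(x) == 0) return(x)
  len <- chrom_length(genome, x$chrom)
  if (any(x$end > len))
    stop("interval(s) extend beyond chromosome length in genome model")
  out <- peak_set(x$chrom,
                  pmax(0, x$start - flank),
                  pmin(len, x$end + flank),
                  label = peak_label(x))
  merge_peaks(out)
}

#' Count mutually overlapping peaks between two sets
#'
#' Counts, for each set, how many of its peaks overlap any peak of the
#' other set by at least `min_bp` bases. The Venn-style overlap reported
#' for peak-set comparisons is the minimum of the two counts, so the
#' summed Venn areas never exceed either set's size.
#'
#' @param a,b merged [peak_set()] objects.
#' @param min_bp minimum overlap in bp (>= 1).
#' @return a list with `n_a_hit`, `n_b_hit`, `venn_overlap`.
#' @export
count_overlapping <- function(a, b, min_bp = 1) {
  stopifnot(is_peak_set(a), is_peak_set(b), min_bp >= 1)
  if (nrow(a) == 0 || nrow(b) == 0)
    return(list(n_a_hit = 0L, n_b_hit = 0L, venn_overlap = 0L))
  count_hits <- function(x, y) {
    shared <- intersect(unique(x$chrom), unique(y$chrom))
    if (length(shared) == 0) return(0L)
    ix <- ir_by_chrom(x, shared); iy <- ir_by_chrom(y, shared)
    sum(vapply(shared, function(ch)
      sum(IRanges::overlapsAny(ix[[ch]], iy[[ch]], minoverlap = min_bp)),
      0L))
  }
  n_a <- count_hits(a, b)
  n_b <- count_hits(b, a)
  list(n_a_hit = n_a, n_b_hit = n_b, venn_overlap = min(n_a, n_b))
}
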