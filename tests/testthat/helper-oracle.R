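# Per-base boolean-mask oracle for interval arithmetic on a single toy
# chromosome, plus random fixture generators. Everything here works on
# logical vectors indexed 1..L (base b of a 0-based half-open interval
# [s,e) occupies mask positions s+1 .. e), independently of the package's
# GenomicRanges-backed implementation.

mask_from_peaks <- function(ps, L) {
  m <- logical(L)
  for (i in seq_len(nrow(ps))) m[(ps$start[i] + 1):ps$end[i]] <- TRUE
  m
}

peaks_from_mask <- function(m, chrom = "chr1", label = "") {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  if (!any(keep)) return(peak_set(label = label))
  peak_set(rep(chrom, sum(keep)), starts[keep], ends[keep], label = label)
}

# close gaps of length <= gap between TRUE runs
mask_close_gaps <- function(m, gap) {
  if (gap == 0 || !any(m)) return(m)
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k] && k > 1 && k < length(r$values) &&
        r$lengths[k] <= gap)
      m[starts[k]:ends[k]] <- TRUE
  }
  m
}

random_peaks <- function(n, L, max_len = 200, chrom = "chr1") {
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(len, function(l) sample.int(L - l + 1, 1) - 1, 0)
  peak_set(rep(chrom, n), start, start + len)
}

# oracle for the majority-coverage counter: per target peak, total covered
# bases strictly above min_frac of its width
oracle_majority_count <- function(target, state_mask, min_frac = 0.5) {
  sum(vapply(seq_len(nrow(target)), function(i) {
    s <- target$start[i]; e <- target$end[i]
    sum(state_mask[(s + 1):e]) > min_frac * (e - s)
  }, logical(1)))
}

# oracle for replicate occupancy: per-base count of replicates covering it
oracle_occupancy <- function(replicates, L, min_count) {
  cover <- Reduce(`+`, lapply(replicates, function(r)
    as.integer(mask_from_peaks(r, L))))
  union_mask <- cover > 0
  # connected components of the union; keep those touched by >= min_count
  # distinct replicates
  comp <- peaks_from_mask(union_mask)
  keep <- vapply(seq_len(nrow(comp)), function(i) {
    idx <- (comp$start[i] + 1):comp$end[i]
    n_reps <- sum(vapply(replicates, function(r)
      any(mask_from_peaks(r, L)[idx]), logical(1)))
    n_reps >= min_count
  }, logical(1))
  comp[keep, , drop = FALSE]
}

toy_genome <- function(L = 10000, chroms = "chr1") {
  genome_model(chroms, rep(L, length(chroms)))
}

expect_same_intervals <- function(a, b) {
  expect_equal(unname(as.matrix(as.data.frame(a)[, c("start", "end")])),
               unname(as.matrix(as.data.frame(b)[, c("start", "end")])))
  expect_equal(a$chrom, b$chrom)
}
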