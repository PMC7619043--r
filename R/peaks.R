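#' Peak sets: BED-convention genomic intervals
#'
#' A `peak_set` is the universal currency of the pipeline: a data.frame of
#' genomic intervals in BED convention (0-based start, exclusive end), with
#' optional `name` and `score` columns and a free-text label describing the
#' set (e.g. `"bulk_hc"`, `"NeuN+"`).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end numeric vectors; 0-based half-open coordinates with
#'   `0 <= start < end`.
#' @param name optional interval labels.
#' @param score optional numeric scores.
#' @param label free-text label for the whole set.
#' @return An object of class `peak_set` (a data.frame with columns `chrom`,
#'   `start`, `end`, `name`, `score`).
#' @examples
#' peak_set("chr1", 100, 200, label = "toy")
#' @export
peak_set <- function(chrom = character(), start = numeric(),
                     end = numeric(), name = NA_character_,
                     score = NA_real_, label = "") {
  n <- length(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    stop(sprintf("invalid interval at row %d: start (%s) >= end (%s)",
                 bad, format(start[bad]), format(end[bad])))
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   stringsAsFactors = FALSE)
  structure(df, class = c("peak_set", "data.frame"),
            label = label, sorted = FALSE)
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("peak_set '%s': %d interval(s), %s bp total\n",
              attr(x, "label"), nrow(x),
              format(total_width(x), big.mark = ",")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' @rdname peak_set
#' @param x object to coerce/test.
#' @export
is_peak_set <- function(x) inherits(x, "peak_set")

#' Set or get the label of a peak set
#' @param x a `peak_set`.
#' @param value new label.
#' @return the label, or the relabelled set.
#' @export
set_label <- function(x, value) { attr(x, "label") <- value; x }

#' @rdname set_label
#' @export
peak_label <- function(x) attr(x, "label")

#' Total genomic width covered by the intervals of a set
#'
#' Sums interval widths as stored; overlapping intervals are counted twice
#' unless the set has been [merge_peaks()]-ed.
#'
#' @param x a `peak_set`.
#' @return total bp (numeric scalar).
#' @export
total_width <- function(x) sum(x$end - x$start)

## GRanges shuttle: peak_set is BED 0-based half-open, GRanges 1-based closed.
as_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

gr_as_peaks <- function(gr, label = "") {
  peak_set(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr) - 1,
           GenomicRanges::end(gr),
           label = label)
}

#' Read a BED file into a peak set
#'
#' Accepts BED3+ (tab-delimited, no header; `#`, `track` and `browser` lines
#' are skipped). Coordinates are taken verbatim: BED files are already
#' 0-based half-open. Input order is preserved.
#'
#' @param path path to a BED file.
#' @param label set label; defaults to the file name.
#' @param chrom_style passed to [normalize_chroms()].
#' @return a [peak_set()].
#' @export
read_bed <- function(path, label = basename(path), chrom_style = "asis") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(peak_set(label = label))
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 3))
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 lineno[which(nf < 3)[1]]))
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 |
                 start != round(start) | end != round(end))
  if (length(bad) > 0)
    stop(sprintf("malformed BED line %d: coordinates must be non-negative integers",
                 lineno[bad[1]]))
  rev_bad <- which(start >= end)
  if (length(rev_bad) > 0)
    stop(sprintf("invalid interval on line %d: start >= end", lineno[rev_bad[1]]))
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
                 NA_character_)
  name[nf < 4] <- NA_character_
  score <- rep(NA_real_, length(fields))
  has5 <- nf >= 5
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5)))
  peak_set(normalize_chroms(chrom, chrom_style), start, end,
           name = name, score = score, label = label)
}

#' Write a peak set as BED
#'
#' Writes BED3 when neither names nor scores are present, BED5 otherwise
#' (missing names become ".", missing scores 0), so that
#' `read_bed(write_bed(x))` round-trips canonical 3- and 5-column files.
#'
#' @param x a [peak_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(is_peak_set(x))
  if (nrow(x) == 0) {
    file.create(path)
    return(invisible(path))
  }
  if (all(is.na(x$name)) && all(is.na(x$score))) {
    dt <- data.table::data.table(x$chrom, format_bp(x$start), format_bp(x$end))
  } else {
    dt <- data.table::data.table(
      x$chrom, format_bp(x$start), format_bp(x$end),
      ifelse(is.na(x$name), ".", x$name),
      ifelse(is.na(x$score), "0", format_bp(x$score)))
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)
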