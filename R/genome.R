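#' Genome model: chromosome names and lengths
#'
#' A genome model is the coordinate frame of the pipeline: an ordered set of
#' chromosome names with their lengths in bp. It bounds interval clipping in
#' [extend_peaks()] and the placement of matched random regions in
#' [simulate_matched_set()].
#'
#' @param chrom_names character vector of unique chromosome identifiers.
#' @param chrom_lengths integer-like vector of positive lengths (bp), one per
#'   chromosome.
#' @return An object of class `genome_model`: a data.frame with columns
#'   `chrom` and `length`.
#' @examples
#' genome_model(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_model <- function(chrom_names, chrom_lengths) {
  chrom_names <- as.character(chrom_names)
  chrom_lengths <- as.numeric(chrom_lengths)
  if (length(chrom_names) != length(chrom_lengths))
    stop("chrom_names and chrom_lengths must have equal length")
  if (anyDuplicated(chrom_names))
    stop("duplicate chromosome names: ",
         paste(unique(chrom_names[duplicated(chrom_names)]), collapse = ", "))
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("chromosome lengths must be positive finite numbers")
  if (any(chrom_lengths != round(chrom_lengths)))
    stop("chromosome lengths must be whole numbers of bp")
  structure(
    data.frame(chrom = chrom_names, length = chrom_lengths,
               stringsAsFactors = FALSE),
    class = c("genome_model", "data.frame")
  )
}

#' Read a two-column chrom.sizes file
#'
#' Standard UCSC-style chromosome sizes: tab- or whitespace-delimited
#' `name<TAB>length`, no header.
#'
#' @param path path to the chrom.sizes file.
#' @return A [genome_model()].
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("chrom.sizes needs two columns: name, length")
  genome_model(dt[[1]], dt[[2]])
}

#' Write a genome model as a chrom.sizes file
#' @param genome a [genome_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  stopifnot(inherits(genome, "genome_model"))
  data.table::fwrite(data.table::as.data.table(unclass(genome)), path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i))
    stop("chromosome(s) absent from genome model: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  genome$length[i]
}

#' Normalize chromosome-name dialects
#'
#' Peak files from different sources disagree on the "chr" prefix
#' ("chr1" vs "1"). This applies a single rule at ingestion so all sets share
#' one dialect.
#'
#' @param chroms character vector of chromosome names.
#' @param style `"chr"` to ensure the prefix, `"plain"` to strip it,
#'   `"asis"` to leave names untouched.
#' @return character vector of normalized names.
#' @export
normalize_chroms <- function(chroms, style = c("asis", "chr", "plain")) {
  style <- match.arg(style)
  switch(style,
    asis  = chroms,
    chr   = ifelse(startsWith(chroms, "chr"), chroms, paste0("chr", chroms)),
    plain = sub("^chr", "", chroms)
  )
}
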