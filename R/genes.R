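#' Gene models: TSS plus gene body
#'
#' A minimal gene model table for peak-to-gene assignment: one row per gene
#' with its chromosome, strand, transcription start site (TSS, a 0-based
#' genomic coordinate) and gene-body interval (0-based half-open).
#'
#' @param gene_id character gene identifiers.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param tss TSS coordinate (0-based bp).
#' @param body_start,body_end gene body, 0-based half-open.
#' @return a data.frame of class `gene_models`.
#' @export
gene_models <- function(gene_id, chrom, strand, tss, body_start, body_end) {
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  tss <- as.numeric(tss)
  body_start <- as.numeric(body_start); body_end <- as.numeric(body_end)
  if (any(body_start >= body_end)) stop("gene body must have start < end")
  if (any(tss < body_start | tss > body_end))
    stop("TSS must lie within (or at the edge of) the gene body")
  structure(
    data.frame(gene_id = as.character(gene_id), chrom = as.character(chrom),
               strand = strand, tss = tss,
               body_start = body_start, body_end = body_end,
               stringsAsFactors = FALSE),
    class = c("gene_models", "data.frame")
  )
}

#' Read gene models from a TSV
#'
#' Expects a header line with columns
#' `gene_id, chrom, strand, tss, body_start, body_end` (coordinates 0-based,
#' body half-open).
#'
#' @param path TSV path.
#' @return a [gene_models()] table.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("gene_id", "chrom", "strand")))
  need <- c("gene_id", "chrom", "strand", "tss", "body_start", "body_end")
  if (!all(need %in% names(dt)))
    stop("gene model TSV must have columns: ", paste(need, collapse = ", "))
  gene_models(dt$gene_id, dt$chrom, dt$strand, dt$tss,
              dt$body_start, dt$body_end)
}

#' @rdname read_gene_models
#' @param genes a [gene_models()] table.
#' @export
write_gene_models <- function(genes, path) {
  data.table::fwrite(data.table::as.data.table(unclass(genes)), path,
                     sep = "\t")
  invisible(path)
}

## Strand-agnostic TSS windows [tss - w, tss + w) as a GRanges.
tss_window_gr <- function(genes, window) {
  GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(start = pmax(0, genes$tss - window) + 1,
                     end = genes$tss + window)
  )
}

#' Classify peaks as TSS-proximal, gene body, or distal
#'
#' Each peak gets the first matching category in priority order:
#' TSS-proximal (overlaps a `[tss - tss_window, tss + tss_window)` window of
#' any gene by >= 1 bp), then gene body (overlaps any body), then distal.
#' Any-overlap, not midpoint, decides membership.
#'
#' @param x a [peak_set()].
#' @param genes a [gene_models()] table.
#' @param tss_window half-width of the TSS window in bp (default 5 kb).
#' @return a list with `category` (factor per peak) and `fractions` (named
#'   fractions summing to 1 over `tss_proximal`, `gene_body`, `distal`).
#' @export
annotate_vs_genes <- function(x, genes, tss_window = 5000) {
  stopifnot(is_peak_set(x), inherits(genes, "gene_models"), tss_window > 0)
  lv <- c("tss_proximal", "gene_body", "distal")
  if (nrow(x) == 0) {
    return(list(category = factor(character(), levels = lv),
                fractions = stats::setNames(rep(NA_real_, 3), lv)))
  }
  gr <- as_gr(x)
  near_tss <- suppressWarnings(
    IRanges::overlapsAny(gr, tss_window_gr(genes, tss_window)))
  body_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$body_start + 1, genes$body_end))
  in_body <- suppressWarnings(IRanges::overlapsAny(gr, body_gr))
  category <- factor(ifelse(near_tss, "tss_proximal",
                            ifelse(in_body, "gene_body", "distal")),
                     levels = lv)
  list(category = category,
       fractions = prop.table(table(category)))
}

#' Assign peaks to genes by strand-aware TSS windows
#'
#' A gene's window runs from `upstream` bp before to `downstream` bp after
#' its TSS in the direction of transcription: `[tss - upstream,
#' tss + downstream)` on the + strand and `[tss - downstream,
#' tss + upstream)` on the - strand (genomic axis). A peak is assigned to
#' every gene whose window it overlaps by >= 1 bp. The defaults reproduce
#' the 30 kb upstream / 100 bp downstream convention used to tie OCRs to
#' genes.
#'
#' @param x a [peak_set()].
#' @param genes a [gene_models()] table.
#' @param upstream,downstream window extents in bp (>= 0).
#' @return a list (one element per peak) of assigned `gene_id`s; a peak with
#'   no gene gets `character(0)`.
#' @export
assign_to_tss_windows <- function(x, genes, upstream = 30000,
                                  downstream = 100) {
  stopifnot(is_peak_set(x), inherits(genes, "gene_models"),
            upstream >= 0, downstream >= 0)
  if (nrow(x) == 0) return(list())
  plus <- genes$strand == "+"
  wstart <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  wend <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  keep <- wend > pmax(0, wstart)
  win <- GenomicRanges::GRanges(
    genes$chrom[keep],
    IRanges::IRanges(pmax(0, wstart[keep]) + 1, wend[keep]))
  ids <- genes$gene_id[keep]
  hits <- suppressWarnings(GenomicRanges::findOverlaps(as_gr(x), win))
  out <- rep(list(character(0)), nrow(x))
  if (length(hits) > 0) {
    sp <- split(ids[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    out[as.integer(names(sp))] <- lapply(sp, unique)
  }
  out
}
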