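#' Squared LD correlation between two SNPs from dosages
#'
#' `r²` as the squared Pearson correlation of genotype dosage vectors — the
#' local stand-in for population-reference LD lookups.
#'
#' @param g1,g2 numeric dosage vectors (0/1/2), equal length >= 2.
#' @return `r²` in `[0, 1]`.
#' @export
r_squared <- function(g1, g2) {
  if (length(g1) != length(g2) || length(g1) < 2)
    stop("dosage vectors must have equal length >= 2")
  if (stats::var(g1) == 0 || stats::var(g2) == 0)
    stop("monomorphic SNP: zero variance dosages")
  min(stats::cor(g1, g2)^2, 1)
}

#' GWAS SNP records
#'
#' @param snp_id SNP identifiers.
#' @param chrom chromosome.
#' @param pos 1-based position.
#' @param gwas_p association p-value, in (0, 1].
#' @param trait trait label.
#' @return data.frame of class `snp_records`.
#' @export
snp_records <- function(snp_id, chrom, pos, gwas_p, trait = "trait") {
  gwas_p <- as.numeric(gwas_p)
  if (any(gwas_p <= 0 | gwas_p > 1)) stop("gwas_p must be in (0, 1]")
  structure(
    data.frame(snp_id = as.character(snp_id), chrom = as.character(chrom),
               pos = as.numeric(pos), gwas_p = gwas_p,
               trait = rep_len(as.character(trait), length(snp_id)),
               stringsAsFactors = FALSE),
    class = c("snp_records", "data.frame"))
}

#' Greedy distance clumping of significant SNPs into loci
#'
#' Repeatedly takes the smallest-p unassigned SNP as a locus index and
#' absorbs every unassigned SNP within `window_bp` on the same chromosome.
#' Ties on p are broken by position (leftmost first). All input SNPs are
#' expected to be genome-wide significant already.
#'
#' @param sig_snps a [snp_records()] table of significant SNPs.
#' @param window_bp clumping half-width (default 500 kb).
#' @return a data.frame: `snp_id, chrom, pos, gwas_p, trait, locus_id,
#'   index_snp, is_index`.
#' @export
define_loci <- function(sig_snps, window_bp = 5e5) {
  stopifnot(inherits(sig_snps, "data.frame"))
  n <- nrow(sig_snps)
  out <- as.data.frame(sig_snps)
  out$locus_id <- NA_character_
  out$index_snp <- NA_character_
  out$is_index <- FALSE
  if (n == 0) return(out)
  ord <- order(out$gwas_p, out$pos)
  assigned <- rep(FALSE, n)
  locus <- 0L
  for (i in ord) {
    if (assigned[i]) next
    locus <- locus + 1L
    members <- which(!assigned & out$chrom == out$chrom[i] &
                       abs(out$pos - out$pos[i]) <= window_bp)
    lid <- sprintf("locus_%03d", locus)
    out$locus_id[members] <- lid
    out$index_snp[members] <- out$snp_id[i]
    out$is_index[i] <- TRUE
    assigned[members] <- TRUE
  }
  out
}

#' Prioritize GWAS SNPs by open chromatin, LD and eQTL evidence
#'
#' The fine-mapping filter chain: keep SNPs that (1) lie inside a
#' high-confidence OCR (1-based position inside the unextended interval),
#' (2) reach genome-wide significance (`gwas_p < gwas_threshold`, strict),
#' and (3) are in strong LD with the index SNP of their locus
#' (`r² > r2_threshold`, strict). Passing SNPs are annotated with histone
#' membership, the NeuN attribution of the containing OCR, their best
#' fetal-brain eQTL below `eqtl_threshold`, and r² with the top eQTL SNP of
#' each implicated transcript.
#'
#' SNPs absent from the LD panel cannot be tested against their index and
#' are excluded (with a message naming them).
#'
#' @param gwas a [snp_records()] table (all traits/SNPs; filtering happens
#'   here).
#' @param ocrs high-confidence [peak_set()].
#' @param panel a [snp_panel()] with genotypes (dosage LD source).
#' @param h3k4me1,h3k4me3 optional histone `peak_set`s.
#' @param attribution optional attribution table from
#'   [attribute_fractions()] (`$table`).
#' @param eqtl optional data.frame `snp_id, transcript, p`.
#' @param gwas_threshold,r2_threshold,eqtl_threshold strict cutoffs
#'   (defaults 5e-8, 0.8, 5e-5).
#' @param clump_window_bp passed to [define_loci()].
#' @return a data.frame of class `prioritized_snps`: one row per retained
#'   SNP with `snp_id, trait, locus_id, index_snp, chrom, pos, gwas_p,
#'   r2_index, in_ocr, in_h3k4me1, in_h3k4me3, neun_label,
#'   eqtl_transcript, eqtl_p, r2_top_eqtl` (multiple transcripts
#'   semicolon-joined).
#' @export
prioritize_snps <- function(gwas, ocrs, panel,
                            h3k4me1 = NULL, h3k4me3 = NULL,
                            attribution = NULL, eqtl = NULL,
                            gwas_threshold = 5e-8, r2_threshold = 0.8,
                            eqtl_threshold = 5e-5,
                            clump_window_bp = 5e5) {
  stopifnot(is_peak_set(ocrs), inherits(panel, "snp_panel"))
  empty <- prioritized_empty()
  sig <- gwas[gwas$gwas_p < gwas_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  loci <- define_loci(sig, window_bp = clump_window_bp)
  in_ocr <- snp_in_set(loci, ocrs)
  cand <- loci[in_ocr, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)

  geno_of <- function(id) {
    j <- match(id, panel$snps$snp_id)
    if (is.na(j)) return(NULL)
    panel$genotypes[, j]
  }
  r2_index <- vapply(seq_len(nrow(cand)), function(i) {
    g1 <- geno_of(cand$snp_id[i]); g2 <- geno_of(cand$index_snp[i])
    if (is.null(g1) || is.null(g2)) return(NA_real_)
    r_squared(g1, g2)
  }, numeric(1))
  if (anyNA(r2_index))
    message("excluded (absent from LD panel): ",
            paste(unique(cand$snp_id[is.na(r2_index)]), collapse = ", "))
  keep <- !is.na(r2_index) & r2_index > r2_threshold
  cand <- cand[keep, , drop = FALSE]
  r2_index <- r2_index[keep]
  if (nrow(cand) == 0) return(empty)

  ann_of <- function(set) {
    if (is.null(set) || nrow(set) == 0) rep(FALSE, nrow(cand))
    else snp_in_set(cand, set)
  }
  neun <- rep(NA_character_, nrow(cand))
  if (!is.null(attribution)) {
    ocr_gr <- GenomicRanges::GRanges(
      attribution$chrom,
      IRanges::IRanges(attribution$start + 1, attribution$end))
    snp_gr <- GenomicRanges::GRanges(cand$chrom,
                                     IRanges::IRanges(cand$pos, cand$pos))
    hits <- GenomicRanges::findOverlaps(snp_gr, ocr_gr, select = "first")
    neun <- as.character(attribution$label[hits])
  }

  eq_tr <- rep(NA_character_, nrow(cand))
  eq_p <- rep(NA_real_, nrow(cand))
  eq_r2 <- rep(NA_character_, nrow(cand))
  if (!is.null(eqtl) && nrow(eqtl) > 0) {
    eq <- eqtl[eqtl$p < eqtl_threshold, , drop = FALSE]
    ## top eQTL SNP per transcript, over the full (unthresholded) table
    top <- do.call(rbind, lapply(split(eqtl, eqtl$transcript), function(d)
      d[which.min(d$p), , drop = FALSE]))
    for (i in seq_len(nrow(cand))) {
      rows <- eq[eq$snp_id == cand$snp_id[i], , drop = FALSE]
      if (nrow(rows) == 0) next
      rows <- rows[order(rows$p), , drop = FALSE]
      eq_tr[i] <- paste(rows$transcript, collapse = ";")
      eq_p[i] <- min(rows$p)
      r2s <- vapply(rows$transcript, function(tr) {
        top_snp <- top$snp_id[top$transcript == tr]
        g1 <- geno_of(cand$snp_id[i]); g2 <- geno_of(top_snp)
        if (is.null(g1) || is.null(g2)) return(NA_real_)
        r_squared(g1, g2)
      }, numeric(1))
      eq_r2[i] <- paste(sprintf("%.3f", r2s), collapse = ";")
    }
  }

  out <- data.frame(
    snp_id = cand$snp_id, trait = cand$trait, locus_id = cand$locus_id,
    index_snp = cand$index_snp, chrom = cand$chrom, pos = cand$pos,
    gwas_p = cand$gwas_p, r2_index = r2_index, in_ocr = TRUE,
    in_h3k4me1 = ann_of(h3k4me1), in_h3k4me3 = ann_of(h3k4me3),
    neun_label = neun, eqtl_transcript = eq_tr, eqtl_p = eq_p,
    r2_top_eqtl = eq_r2, stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("prioritized_snps", "data.frame")
  out
}

prioritized_empty <- function() {
  out <- data.frame(
    snp_id = character(), trait = character(), locus_id = character(),
    index_snp = character(), chrom = character(), pos = numeric(),
    gwas_p = numeric(), r2_index = numeric(), in_ocr = logical(),
    in_h3k4me1 = logical(), in_h3k4me3 = logical(),
    neun_label = character(), eqtl_transcript = character(),
    eqtl_p = numeric(), r2_top_eqtl = character(),
    stringsAsFactors = FALSE)
  class(out) <- c("prioritized_snps", "data.frame")
  out
}

## TRUE per row of a (chrom, pos) table whose base lies inside the set.
snp_in_set <- function(snps, set) {
  if (nrow(set) == 0 || nrow(snps) == 0) return(rep(FALSE, nrow(snps)))
  gr <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos, snps$pos))
  IRanges::overlapsAny(gr, as_gr(set))
}
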