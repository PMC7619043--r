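#' SNP panel: positions plus LD information
#'
#' The LD reference for partitioned-heritability regression and for r²
#' computation. SNPs are sorted by (chrom, pos) and organised into LD
#' blocks; LD is supplied either as a genotype dosage matrix (individuals x
#' SNPs, 0/1/2) from which within-block r² is computed, or directly as
#' per-block correlation (r) matrices.
#'
#' @param snp_id character SNP identifiers.
#' @param chrom chromosome per SNP.
#' @param pos 1-based position per SNP.
#' @param block integer LD-block index per SNP; blocks must be contiguous
#'   runs in (chrom, pos) order. Defaults to one block per chromosome.
#' @param genotypes optional individuals x SNPs dosage matrix.
#' @param ld_blocks optional list of per-block correlation matrices
#'   (symmetric, unit diagonal), one per block level.
#' @return an object of class `snp_panel`.
#' @export
snp_panel <- function(snp_id, chrom, pos, block = NULL, genotypes = NULL,
                      ld_blocks = NULL) {
  pos <- as.numeric(pos)
  n <- length(snp_id)
  chrom <- rep_len(as.character(chrom), n)
  stopifnot(length(pos) == n)
  ord <- order(match(chrom, unique(chrom)), pos)
  if (any(ord != seq_len(n)))
    stop("SNPs must be sorted by (chrom, pos)")
  if (is.null(block)) block <- match(chrom, unique(chrom))
  block <- as.integer(block)
  if (any(diff(block) < 0)) stop("block indices must be non-decreasing")
  if (is.null(genotypes) && is.null(ld_blocks))
    stop("provide genotypes or ld_blocks")
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    if (ncol(genotypes) != n)
      stop("genotypes must have one column per SNP")
  }
  nb <- length(unique(block))
  if (!is.null(ld_blocks)) {
    if (length(ld_blocks) != nb)
      stop("need one LD matrix per block")
    sizes <- tabulate(match(block, sort(unique(block))))
    for (b in seq_len(nb)) {
      R <- ld_blocks[[b]]
      if (nrow(R) != sizes[b] || ncol(R) != sizes[b])
        stop("LD matrix ", b, " does not match block size")
      if (max(abs(R - t(R))) > 1e-8 || max(abs(diag(R) - 1)) > 1e-8)
        stop("LD matrices must be symmetric with unit diagonal")
    }
  }
  structure(list(
    snps = data.frame(snp_id = as.character(snp_id), chrom = chrom,
                      pos = pos, block = block, stringsAsFactors = FALSE),
    genotypes = genotypes, ld_blocks = ld_blocks), class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d SNPs, %d LD block(s), LD from %s\n",
              nrow(x$snps), length(unique(x$snps$block)),
              if (is.null(x$genotypes)) "correlation matrices"
              else sprintf("%d genotyped individuals", nrow(x$genotypes))))
  invisible(x)
}

## Per-block r^2 matrix (list indexed by block order).
block_r2 <- function(panel) {
  blocks <- split(seq_len(nrow(panel$snps)), panel$snps$block)
  if (!is.null(panel$ld_blocks))
    return(lapply(panel$ld_blocks, function(R) R^2))
  lapply(blocks, function(idx) {
    R <- suppressWarnings(stats::cor(panel$genotypes[, idx, drop = FALSE]))
    R[is.na(R)] <- 0
    R^2
  })
}

#' Binary annotation matrix for partitioned heritability
#'
#' Column 1 is always the all-SNPs base category; further columns are the
#' supplied binary memberships (e.g. the extended-OCR annotation and
#' baseline-like covariate categories).
#'
#' @param n_snps number of SNPs.
#' @param categories named list of 0/1 (or logical) membership vectors.
#' @return numeric matrix `n_snps x (1 + length(categories))` with
#'   column names `c("base", names(categories))`.
#' @export
annotation_matrix <- function(n_snps, categories = list()) {
  if (length(categories) > 0 &&
      (is.null(names(categories)) || any(!nzchar(names(categories)))))
    stop("categories must be named")
  cols <- c(list(base = rep(1, n_snps)),
            lapply(categories, function(v) {
              v <- as.numeric(v)
              if (length(v) != n_snps) stop("category length != n_snps")
              if (!all(v %in% c(0, 1))) stop("memberships must be 0/1")
              v
            }))
  do.call(cbind, cols)
}

#' Flag SNPs inside (flank-extended) peaks
#'
#' A SNP at 1-based position `pos` is in-annotation when its base lies
#' inside a peak after extension by `flank` bp on each side; in 0-based
#' half-open terms, when `start <= pos - 1 < end` for some extended peak.
#' The default 500 bp flank matches the expansion applied to open-chromatin
#' annotations before heritability regression.
#'
#' @param panel a [snp_panel()] (or data.frame with `chrom`, `pos`).
#' @param peaks a [peak_set()].
#' @param flank bp of symmetric extension (default 500).
#' @param genome a [genome_model()] for clipping.
#' @return numeric 0/1 vector, one entry per SNP.
#' @export
annotate_snps <- function(panel, peaks, flank = 500, genome) {
  snps <- if (inherits(panel, "snp_panel")) panel$snps else panel
  stopifnot(is_peak_set(peaks))
  if (nrow(peaks) == 0) return(numeric(nrow(snps)))
  ext <- if (flank > 0) extend_peaks(peaks, flank, genome) else
    merge_peaks(peaks)
  snp_gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, snps$pos))
  as.numeric(IRanges::overlapsAny(snp_gr, as_gr(ext)))
}

#' Stratified LD scores
#'
#' `l[j, c] = sum over block-mates k within window_bp of r²(j,k) * A[k,c]`,
#' including the self term `r²(j,j) = 1`, so the base-category score is
#' always >= 1. LD is block-diagonal: SNPs in different blocks contribute
#' nothing to each other.
#'
#' @param panel a [snp_panel()].
#' @param annotations an [annotation_matrix()].
#' @param window_bp LD window in bp (default `Inf` = whole block).
#' @return numeric matrix, SNPs x categories.
#' @export
ld_scores <- function(panel, annotations, window_bp = Inf) {
  stopifnot(inherits(panel, "snp_panel"), window_bp > 0)
  n <- nrow(panel$snps)
  if (nrow(annotations) != n)
    stop("annotation matrix rows != number of SNPs")
  r2 <- block_r2(panel)
  blocks <- split(seq_len(n), panel$snps$block)
  out <- matrix(0, n, ncol(annotations),
                dimnames = list(NULL, colnames(annotations)))
  for (b in seq_along(blocks)) {
    idx <- blocks[[b]]
    R2 <- r2[[b]]
    if (is.finite(window_bp)) {
      d <- abs(outer(panel$snps$pos[idx], panel$snps$pos[idx], `-`))
      R2 <- R2 * (d <= window_bp)
    }
    out[idx, ] <- R2 %*% annotations[idx, , drop = FALSE]
  }
  out
}

#' GWAS summary statistics container
#'
#' @param snp_id SNP identifiers, aligned with the panel.
#' @param chisq per-SNP chi-square association statistics (`z²`).
#' @param N GWAS sample size (scalar or per-SNP).
#' @return an object of class `gwas_summary`.
#' @export
gwas_summary <- function(snp_id, chisq, N) {
  chisq <- as.numeric(chisq)
  if (any(chisq < 0)) stop("chi-square statistics must be >= 0")
  if (any(N <= 0)) stop("N must be positive")
  structure(list(snp_id = as.character(snp_id), chisq = chisq,
                 N = rep_len(as.numeric(N), length(chisq))),
            class = "gwas_summary")
}

#' Read a GWAS summary TSV
#'
#' Expects header columns `snp, chr, pos, N` plus either `z` or `chisq`.
#'
#' @param path TSV path.
#' @return a [gwas_summary()].
#' @export
read_gwas <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  chisq <- if ("chisq" %in% names(dt)) dt$chisq
  else if ("z" %in% names(dt)) dt$z^2
  else stop("GWAS TSV needs a 'z' or 'chisq' column")
  gwas_summary(dt$snp, chisq, dt$N)
}

#' Fit the simplified stratified LD-score regression
#'
#' Weighted least squares of GWAS chi-square statistics on annotation-
#' stratified LD scores under the model
#' `E[chisq_j] = N * sum_c tau_c * l(j,c) + 1` (intercept fixed at 1 by
#' default; `free_intercept = TRUE` estimates it instead). Regression
#' weights are `1 / max(l_total(j), 1)` with `l_total` the base-category LD
#' score. Standard errors and the coefficient covariance come from a
#' delete-one block jackknife over `n_blocks` contiguous SNP blocks.
#'
#' This is a deliberately simplified estimator: block-diagonal LD, no
#' MAF-stratified reference weights, no iterative reweighting. Its contract
#' is parameter recovery on data generated under the same model, not
#' numeric agreement with the published LDSC software.
#'
#' @param gwas a [gwas_summary()].
#' @param ld LD-score matrix from [ld_scores()].
#' @param annotations the matching [annotation_matrix()].
#' @param n_blocks jackknife blocks (default 20; >= 2).
#' @param free_intercept estimate the intercept instead of fixing it at 1.
#' @return an object of class `h2_fit`: list with `tau`, `se`, `z`, `p`,
#'   `cov`, `jack` (delete-one coefficient matrix), `intercept`,
#'   `annotations`, `N`.
#' @export
fit_partitioned <- function(gwas, ld, annotations, n_blocks = 20,
                            free_intercept = FALSE) {
  stopifnot(inherits(gwas, "gwas_summary"), n_blocks >= 2)
  n <- length(gwas$chisq)
  if (nrow(ld) != n || nrow(annotations) != n)
    stop("gwas, ld and annotations disagree on the number of SNPs")
  if (n_blocks > n) stop("more jackknife blocks than SNPs")
  X <- gwas$N * ld
  if (free_intercept) X <- cbind(X, intercept = 1)
  y <- if (free_intercept) gwas$chisq else gwas$chisq - 1
  w <- 1 / pmax(ld[, 1], 1)
  solve_wls <- function(keep) {
    Xk <- X[keep, , drop = FALSE]
    XtW <- t(Xk * w[keep])
    M <- XtW %*% Xk
    qrM <- qr(M)
    if (qrM$rank < ncol(Xk)) {
      bad <- setdiff(colnames(Xk), colnames(Xk)[qrM$pivot[seq_len(qrM$rank)]])
      stop("singular design; collinear categories: ",
           paste(bad, collapse = ", "))
    }
    drop(qr.coef(qrM, XtW %*% y[keep]))
  }
  tau_full <- solve_wls(rep(TRUE, n))
  grp <- pmin(ceiling(seq_len(n) / (n / n_blocks)), n_blocks)
  raw <- vapply(seq_len(n_blocks), function(b) solve_wls(grp != b),
                numeric(ncol(X)))
  jack <- if (is.matrix(raw)) t(raw) else matrix(raw, ncol = 1)
  colnames(jack) <- colnames(X)
  B <- n_blocks
  pseudo <- sweep(-(B - 1) * jack, 2, B * tau_full, `+`)
  covar <- stats::cov(pseudo) / B
  se <- sqrt(diag(covar))
  intercept <- if (free_intercept) tau_full[["intercept"]] else 1
  k <- if (free_intercept) seq_len(ncol(X) - 1) else seq_len(ncol(X))
  tau <- tau_full[k]
  z <- tau / se[k]
  structure(list(tau = tau, se = se[k], z = z,
                 p = 2 * stats::pnorm(-abs(z)),
                 cov = covar[k, k, drop = FALSE],
                 jack = jack[, k, drop = FALSE],
                 intercept = intercept,
                 annotations = annotations, N = gwas$N[1]),
            class = "h2_fit")
}

## h2 proportions implied by tau for each non-base category.
props_from_tau <- function(tau, A) {
  h_per_snp <- drop(A %*% tau)
  total <- sum(h_per_snp)
  vapply(seq_len(ncol(A))[-1], function(c)
    sum(h_per_snp[A[, c] == 1]) / total, numeric(1))
}

#' Partitioned-heritability fold enrichment
#'
#' For each (non-base) annotation category: the proportion of SNP
#' heritability attributed to SNPs in the category, divided by the
#' proportion of SNPs in the category. Per-SNP heritability is
#' `sum_c tau_c * A[j,c]`; proportions are sums of per-SNP heritability
#' over category members relative to the genome-wide total. Fold standard
#' errors come from the fit's delete-one-block jackknife; `z` and `p` are
#' the coefficient (tau) Z-test against zero.
#'
#' @param fit an `h2_fit` from [fit_partitioned()].
#' @return a data.frame of class `partitioned_h2_result`, one row per
#'   non-base category: `category, prop_snps, prop_h2, fold, se_fold, tau,
#'   se_tau, z, p`.
#' @export
fold_enrichment <- function(fit) {
  stopifnot(inherits(fit, "h2_fit"))
  A <- fit$annotations
  if (ncol(A) < 2) stop("no categories beyond the base annotation")
  prop_snps <- colMeans(A)[-1]
  if (any(prop_snps == 0)) stop("category with zero SNPs")
  prop_h2 <- props_from_tau(fit$tau, A)
  fold <- pmax(prop_h2, 0) / prop_snps
  B <- nrow(fit$jack)
  jack_fold <- t(apply(fit$jack, 1, function(tau_b)
    pmax(props_from_tau(tau_b, A), 0) / prop_snps))
  jack_fold <- matrix(jack_fold, nrow = B)
  pseudo <- sweep(-(B - 1) * jack_fold, 2, B * fold, `+`)
  se_fold <- sqrt(diag(stats::cov(pseudo)) / B)
  out <- data.frame(category = colnames(A)[-1],
                    prop_snps = prop_snps, prop_h2 = prop_h2,
                    fold = fold, se_fold = se_fold,
                    tau = fit$tau[-1], se_tau = fit$se[-1],
                    z = fit$z[-1], p = fit$p[-1],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("partitioned_h2_result", "data.frame")
  out
}

#' Fold enrichment from printed proportions
#'
#' The headline enrichment statistic is simply the proportion of SNP
#' heritability in an annotation divided by the proportion of SNPs in it;
#' both arguments may be fractions or percentages (consistently).
#'
#' @param prop_h2 proportion of SNP heritability in the annotation.
#' @param prop_snps proportion of SNPs in the annotation.
#' @return the fold enrichment.
#' @examples
#' fold_from_proportions(23.9, 3.3) # ~ 7.2
#' @export
fold_from_proportions <- function(prop_h2, prop_snps) {
  if (any(prop_snps <= 0)) stop("prop_snps must be positive")
  prop_h2 / prop_snps
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / n_traits`, rounded to two significant figures for display
#' (0.05 over seven traits gives .0071).
#'
#' @param alpha family-wise error rate (default 0.05).
#' @param n_traits number of traits tested (>= 1).
#' @return the display-rounded threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_traits) {
  stopifnot(alpha > 0, n_traits >= 1)
  signif(alpha / n_traits, 2)
}
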