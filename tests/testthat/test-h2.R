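make_panel_no_ld <- function(n, chrom = "chr1") {
  # independent SNPs: identity LD, one block
  snp_panel(sprintf("s%03d", 1:n), rep(chrom, n), seq(1000, by = 1000,
                                                      length.out = n),
            block = rep(1L, n), ld_blocks = list(diag(n)))
}

test_that("SNP annotation respects BED coordinates and the 500 bp flank", {
  g <- genome_model("chr1", 1e6)
  panel <- make_panel_no_ld(4)
  panel$snps$pos <- c(1000, 1001, 2500, 2501)
  # peak [1500,2000) extended by 500 -> [1000,2500), i.e. 1-based
  # positions 1001..2500; position 1000 sits one base short of it
  ann <- annotate_snps(panel, peak_set("chr1", 1500, 2000), flank = 500,
                       genome = g)
  expect_equal(ann, c(0, 1, 1, 0))
  expect_equal(annotate_snps(panel, peak_set(), 500, g), rep(0, 4))
  expect_equal(annotate_snps(panel, peak_set("chr1", 0, 1e6), 500, g),
               rep(1, 4))
})

test_that("LD scores include the self term and sum annotation-weighted r2", {
  p <- make_panel_no_ld(4)
  A <- annotation_matrix(4, list(cat = c(1, 1, 0, 0)))
  l <- ld_scores(p, A)
  expect_equal(unname(l[, "base"]), rep(1, 4))
  expect_equal(unname(l[, "cat"]), c(1, 1, 0, 0))

  # two perfectly correlated SNPs both in the category
  R <- matrix(c(1, 1, 1, 1), 2)
  p2 <- snp_panel(c("a", "b"), "chr1", c(100, 200), block = c(1L, 1L),
                  ld_blocks = list(R))
  l2 <- ld_scores(p2, annotation_matrix(2, list(cat = c(1, 1))))
  expect_equal(unname(l2[, "cat"]), c(2, 2))
})

test_that("LD scores from genotypes match brute-force all-pairs r2", {
  set.seed(500)
  n <- 50
  geno <- matrix(sample(0:2, 40 * n, replace = TRUE), 40, n)
  p <- snp_panel(sprintf("s%02d", 1:n), "chr1",
                 seq(500, by = 500, length.out = n),
                 block = rep(1L, n), genotypes = geno)
  A <- annotation_matrix(n, list(cat = rep(c(1, 0), n / 2)))
  l <- ld_scores(p, A)
  # oracle: explicit double loop over pairs
  for (j in c(1, 17, 50)) {
    base_j <- sum(vapply(1:n, function(k) cor(geno[, j], geno[, k])^2,
                         0))
    cat_j <- sum(vapply(which(A[, "cat"] == 1), function(k)
      cor(geno[, j], geno[, k])^2, 0))
    expect_equal(unname(l[j, "base"]), base_j, tolerance = 1e-12)
    expect_equal(unname(l[j, "cat"]), cat_j, tolerance = 1e-12)
  }
})

test_that("the regression recovers tau exactly on noiseless single-category data", {
  n <- 100; N <- 1000; tau <- 2e-4
  p <- make_panel_no_ld(n)
  A <- annotation_matrix(n)
  l <- ld_scores(p, A)  # all ones
  gwas <- gwas_summary(p$snps$snp_id, rep(N * tau + 1, n), N)
  fit <- fit_partitioned(gwas, l, A, n_blocks = 10)
  expect_equal(unname(fit$tau[1]), tau, tolerance = 1e-12)
  expect_equal(unname(fit$se[1]), 0, tolerance = 1e-10)
})

test_that("with trivial weights the fit matches ordinary least squares", {
  set.seed(42)
  n <- 400; N <- 5000
  p <- make_panel_no_ld(n)
  A <- annotation_matrix(n, list(cat = rep(c(1, 0), each = n / 2)))
  l <- ld_scores(p, A)  # base = 1 everywhere -> weights all 1
  chisq <- 1 + N * (1e-4 + 2e-4 * A[, "cat"]) + rnorm(n, 0, 0.5)
  chisq <- pmax(chisq, 0)
  gwas <- gwas_summary(p$snps$snp_id, chisq, N)
  fit <- fit_partitioned(gwas, l, A, n_blocks = 20)
  ref <- lm(I(chisq - 1) ~ 0 + I(N * l[, "base"]) + I(N * l[, "cat"]))
  expect_equal(unname(fit$tau), unname(coef(ref)), tolerance = 1e-10)
})

test_that("collinear categories raise a named singular-design error", {
  n <- 50
  p <- make_panel_no_ld(n)
  dup <- rep(c(1, 0), each = n / 2)
  A <- annotation_matrix(n, list(cat = dup, copy = dup))
  l <- ld_scores(p, A)
  gwas <- gwas_summary(p$snps$snp_id, rchisq(n, 1), 1000)
  expect_error(fit_partitioned(gwas, l, A, n_blocks = 5), "singular")
})

test_that("heritability proportions are conserved over a disjoint partition", {
  # partition categories alongside the base (which they jointly tile);
  # proportions computed from any tau must sum to one
  n <- 60
  half <- rep(c(1, 0), each = n / 2)
  A <- annotation_matrix(n, list(left = half, right = 1 - half))
  fit <- structure(list(tau = c(base = 1e-4, left = 3e-4, right = 5e-5),
                        se = rep(1e-5, 3), z = rep(5, 3), p = rep(0, 3),
                        jack = matrix(rep(c(1e-4, 3e-4, 5e-5), each = 6),
                                      6),
                        annotations = A, N = 1000, intercept = 1),
                   class = "h2_fit")
  fe <- fold_enrichment(fit)
  expect_equal(sum(fe$prop_h2), 1, tolerance = 1e-12)
  expect_equal(sum(fe$prop_snps), 1)
})

test_that("an all-SNPs annotation has fold exactly 1", {
  # fold semantics independent of the regression: category == genome
  A <- annotation_matrix(10, list(all = rep(1, 10)))
  fit <- structure(list(tau = c(base = 1e-4, all = 2e-4),
                        se = c(1e-5, 1e-5), z = c(10, 20), p = c(0, 0),
                        jack = matrix(rep(c(1e-4, 2e-4), each = 4), 4),
                        annotations = A, N = 1000, intercept = 1),
                   class = "h2_fit")
  fe <- fold_enrichment(fit)
  expect_equal(fe$fold, 1)
  expect_equal(fe$prop_h2, 1)
})

test_that("single-seed recovery: estimated tau near truth, fold near target", {
  st <- generate_study(synthetic_config(seed = 5))
  ld <- ld_scores(st$panel, st$annotations)
  fit <- fit_partitioned(st$gwas, ld, st$annotations, n_blocks = 20)
  expect_lt(abs(fit$tau[["ocr"]] - st$tau[["ocr"]]),
            4 * fit$se[[which(names(fit$tau) == "ocr")]])
  fe <- fold_enrichment(fit)
  expect_equal(fe$prop_snps[fe$category == "ocr"], st$truth$prop_snps_ocr)
})

test_that("Bonferroni display threshold divides alpha by the trait count", {
  expect_equal(bonferroni_threshold(0.05, 7), 0.0071)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 5), 0.002)
})

test_that("fold from printed proportions reproduces the headline ratio", {
  expect_equal(round(fold_from_proportions(23.9, 3.3), 1), 7.2)
  expect_equal(fold_from_proportions(0.5, 0.5), 1)
  expect_error(fold_from_proportions(0.2, 0), "positive")
})
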