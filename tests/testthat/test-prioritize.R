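test_that("r_squared matches the textbook Pearson formula", {
  expect_equal(r_squared(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(r_squared(c(0, 1, 2, 1), 2 - c(0, 1, 2, 1)), 1)
  g1 <- c(0, 0, 1, 1, 2, 2); g2 <- c(0, 1, 0, 1, 2, 2)
  # hand computation: r = cov / (sd1 sd2) with n-1 denominators
  r_hand <- (sum((g1 - mean(g1)) * (g2 - mean(g2))) / 5) /
    (sqrt(sum((g1 - mean(g1))^2) / 5) * sqrt(sum((g2 - mean(g2))^2) / 5))
  expect_equal(r_squared(g1, g2), r_hand^2)
  expect_error(r_squared(c(1, 1, 1), c(0, 1, 2)), "monomorphic")
  expect_error(r_squared(1, 2), "length")
})

test_that("greedy clumping reproduces a hand-run locus partition", {
  # two SNPs 10 kb apart -> one locus
  two <- snp_records(c("a", "b"), "chr1", c(1e6, 1e6 + 1e4), c(1e-9, 1e-10))
  expect_equal(length(unique(define_loci(two)$locus_id)), 1)
  # different chromosomes -> two loci
  split <- snp_records(c("a", "b"), c("chr1", "chr2"), c(1e6, 1e6),
                       c(1e-9, 1e-10))
  expect_equal(length(unique(define_loci(split)$locus_id)), 2)
  # 5-SNP fixture spanning two 500 kb windows (hand-run greedy):
  # s5 (1e-20, pos 950k) absorbs s4 (900k); s1 (1e-12, 100k) absorbs
  # s2 (150k) and s3 (200k)
  five <- snp_records(paste0("s", 1:5), "chr1",
                      c(1e5, 1.5e5, 2e5, 9e5, 9.5e5),
                      c(1e-12, 1e-9, 1e-10, 10^-8.5, 1e-20))
  res <- define_loci(five, window_bp = 5e5)
  expect_equal(res$index_snp, c("s1", "s1", "s1", "s5", "s5"))
  expect_equal(res$is_index, c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(length(unique(res$locus_id)), 2)
})

# A hand-built fine-mapping fixture: one locus on chr1 whose index SNP
# (rs_idx) sits outside open chromatin while rs_hit, inside an OCR, is in
# perfect LD with it and acts as eQTL for two transcripts; rs_low is in
# weak LD; rs_edge has r2 exactly at the cutoff; rs_border sits exactly at
# the genome-wide threshold.
make_fixture <- function() {
  set.seed(909)
  ids <- c("rs_idx", "rs_hit", "rs_low", "rs_edge", "rs_border", "rs_top2")
  pos <- c(100000, 101000, 102000, 103000, 104000, 105000)
  g_idx <- c(0, 0, 1, 1, 2, 2, 0, 1, 2, 1)
  g_low <- sample(0:2, 10, replace = TRUE)
  g_edge <- c(0, 0, 1, 1, 2, 2, 1, 1, 2, 1)  # high but imperfect LD
  geno <- cbind(g_idx, g_idx, g_low, g_edge, g_idx, 2 - g_idx)
  colnames(geno) <- NULL
  panel <- snp_panel(ids, "chr1", pos, block = rep(1L, 6),
                     genotypes = geno)
  # OCR covers rs_hit, rs_low, rs_edge and rs_border (not the index)
  ocrs <- peak_set("chr1", 100500, 104500, label = "hc")
  gwas <- snp_records(ids, "chr1", pos,
                      c(1e-12, 1e-9, 1e-9, 1e-9, 5e-8, 0.5))
  eqtl <- data.frame(
    snp_id = c("rs_hit", "rs_hit", "rs_top2"),
    transcript = c("TR_A", "TR_B", "TR_B"),
    p = c(1e-8, 2e-7, 1e-9), stringsAsFactors = FALSE)
  list(panel = panel, ocrs = ocrs, gwas = gwas, eqtl = eqtl,
       r2_edge = r_squared(g_idx, g_edge))
}

test_that("the filter chain keeps exactly the planted SNP with its eQTL evidence", {
  fx <- make_fixture()
  res <- prioritize_snps(fx$gwas, fx$ocrs, fx$panel, eqtl = fx$eqtl,
                         r2_threshold = fx$r2_edge)
  # rs_hit passes everything; rs_low fails LD; rs_edge is exactly at the
  # cutoff (strict >); rs_border is exactly at 5e-8 (strict <); rs_idx is
  # outside the OCR
  expect_equal(res$snp_id, "rs_hit")
  expect_equal(res$r2_index, 1)
  expect_equal(res$eqtl_transcript, "TR_A;TR_B")
  expect_equal(res$eqtl_p, 1e-8)
  # r2 with top eQTL: TR_A's top is rs_hit itself (r2 1), TR_B's top is
  # rs_top2 = mirrored index (r2 1)
  expect_equal(res$r2_top_eqtl, "1.000;1.000")
})

test_that("boundary SNPs at exact thresholds are excluded by strictness", {
  fx <- make_fixture()
  res <- prioritize_snps(fx$gwas, fx$ocrs, fx$panel,
                         r2_threshold = fx$r2_edge)
  expect_false("rs_edge" %in% res$snp_id)    # r2 == cutoff
  expect_false("rs_border" %in% res$snp_id)  # p == 5e-8
  # relaxing the cutoff just below admits rs_edge
  res2 <- prioritize_snps(fx$gwas, fx$ocrs, fx$panel,
                          r2_threshold = fx$r2_edge - 1e-9)
  expect_true("rs_edge" %in% res2$snp_id)
})

test_that("with r2 cutoff 0 all significant OCR SNPs in loci are returned", {
  fx <- make_fixture()
  res <- prioritize_snps(fx$gwas, fx$ocrs, fx$panel, r2_threshold = 0)
  expect_setequal(res$snp_id, c("rs_hit", "rs_low", "rs_edge"))
  # an index SNP inside an OCR always passes its own LD filter
  gwas2 <- fx$gwas
  gwas2$pos[gwas2$snp_id == "rs_idx"] <- 101500  # move index into the OCR
  fx$panel$snps$pos[1] <- 101500
  res2 <- prioritize_snps(gwas2, fx$ocrs, fx$panel, r2_threshold = 0.99)
  expect_true("rs_idx" %in% res2$snp_id)
  expect_equal(res2$r2_index[res2$snp_id == "rs_idx"], 1)
})

test_that("SNPs absent from the panel are excluded with a message", {
  fx <- make_fixture()
  gwas <- rbind(fx$gwas,
                snp_records("rs_ghost", "chr1", 101200, 1e-10))
  expect_message(res <- prioritize_snps(gwas, fx$ocrs, fx$panel),
                 "rs_ghost")
  expect_false("rs_ghost" %in% res$snp_id)
})

test_that("planted causal OCR SNPs in the synthetic study are recovered", {
  st <- generate_study(synthetic_config(seed = 21))
  hc <- high_confidence(st$pooled, st$replicates, st$blacklist)
  att <- attribute_fractions(hc, st$neun_pos, st$neun_neg)
  res <- prioritize_snps(st$gwas_records, hc, st$panel,
                         h3k4me1 = st$h3k4me1, h3k4me3 = st$h3k4me3,
                         attribution = att$table, eqtl = st$eqtl)
  planted <- st$truth$planted
  expect_setequal(res$snp_id, planted$causal_snp)
  for (k in seq_len(nrow(planted))) {
    row <- res[res$snp_id == planted$causal_snp[k], ]
    expect_equal(row$index_snp, planted$index_snp[k])
    expect_equal(row$r2_index, 1)
    expect_setequal(strsplit(row$eqtl_transcript, ";")[[1]],
                    strsplit(planted$transcripts[k], ";")[[1]])
  }
})
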