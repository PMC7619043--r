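test_that("read_bed maps BED lines to 0-based half-open intervals", {
  f <- withr::local_tempfile(lines = c("chr1\t100\t200",
                                       "chr2\t0\t50",
                                       "# a comment",
                                       "chr1\t300\t400\tpeak_a\t7"))
  ps <- read_bed(f)
  expect_equal(nrow(ps), 3)
  expect_equal(ps$chrom, c("chr1", "chr2", "chr1"))
  expect_equal(ps$start, c(100, 0, 300))
  expect_equal(ps$end, c(200, 50, 400))
  expect_equal(ps$name[3], "peak_a")
  expect_equal(ps$score[3], 7)

  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(read_bed(empty)), 0)
})

test_that("read_bed rejects malformed and inverted records, naming the line", {
  f <- withr::local_tempfile(lines = c("chr1\t10\t20", "chr1\t200\t100"))
  expect_error(read_bed(f), "line 2")
  g <- withr::local_tempfile(lines = c("chr1\tfoo\t20"))
  expect_error(read_bed(g), "line 1")
  h <- withr::local_tempfile(lines = c("chr1\t10"))
  expect_error(read_bed(h), "line 1")
})

test_that("read_bed/write_bed round-trips canonical BED3 and BED5 bit-exactly", {
  for (lines in list(c("chr1\t100\t200", "chr2\t0\t5000000"),
                     c("chr1\t100\t200\tp1\t10", "chr1\t500\t900\tp2\t0"))) {
    f <- withr::local_tempfile(lines = lines)
    out <- withr::local_tempfile()
    write_bed(read_bed(f), out)
    expect_identical(readLines(out), lines)
  }
})

test_that("merge joins overlapping, bookended and near intervals per the gap rule", {
  a <- peak_set(c("chr1", "chr1"), c(100, 150), c(200, 250))
  expect_same_intervals(merge_peaks(a), peak_set("chr1", 100, 250))
  b <- peak_set(c("chr1", "chr1"), c(100, 200), c(200, 300))
  expect_same_intervals(merge_peaks(b), peak_set("chr1", 100, 300))
  d <- peak_set(c("chr1", "chr1"), c(0, 20), c(10, 30))
  expect_equal(nrow(merge_peaks(d, gap = 5)), 2)   # distance 10 > 5
  expect_equal(nrow(merge_peaks(d, gap = 10)), 1)  # joined at gap = 10
  expect_same_intervals(merge_peaks(merge_peaks(a)), merge_peaks(a))
})

test_that("intersect returns exactly the shared bases", {
  a <- peak_set("chr1", 100, 200)
  b <- peak_set("chr1", 150, 250)
  expect_same_intervals(intersect_peaks(a, b), peak_set("chr1", 150, 200))
  expect_equal(nrow(intersect_peaks(a, peak_set("chr1", 500, 600))), 0)
  dup <- peak_set(c("chr1", "chr1"), c(0, 50), c(100, 150))
  expect_same_intervals(intersect_peaks(dup, dup), merge_peaks(dup))
})

test_that("subtract drops or clips blacklist overlaps", {
  a <- peak_set("chr1", 0, 100)
  bl <- peak_set("chr1", 50, 60)
  expect_equal(nrow(subtract_peaks(a, bl, "drop_if_touch")), 0)
  clipped <- subtract_peaks(a, bl, "clip")
  expect_same_intervals(clipped,
                        peak_set(c("chr1", "chr1"), c(0, 60), c(50, 100)))
  expect_same_intervals(subtract_peaks(a, peak_set(), "clip"), a)
  # clip removes every base of self-subtraction
  expect_equal(nrow(subtract_peaks(a, a, "clip")), 0)
})

test_that("extend flanks, clips to chromosome bounds and re-merges", {
  g <- genome_model("chr1", 400)
  expect_same_intervals(
    extend_peaks(peak_set("chr1", 100, 200), 500, g),
    peak_set("chr1", 0, 400))
  g2 <- genome_model("chr1", 1e6)
  expect_same_intervals(
    extend_peaks(peak_set("chr1", 1000, 2000), 500, g2),
    peak_set("chr1", 500, 2500))
  a <- peak_set(c("chr1", "chr1"), c(0, 50), c(100, 150))
  expect_same_intervals(extend_peaks(a, 0, g2), merge_peaks(a))
  expect_error(extend_peaks(peak_set("chrX", 0, 10), 10, g2), "chrX")
})

test_that("count_overlapping follows the min-of-both-sides Venn convention", {
  a <- merge_peaks(peak_set("chr1", 0, 100))
  b <- merge_peaks(peak_set(c("chr1", "chr1"), c(50, 70), c(60, 80)))
  res <- count_overlapping(a, b)
  expect_equal(res$n_a_hit, 1)
  expect_equal(res$n_b_hit, 2)
  expect_equal(res$venn_overlap, 1)
  expect_equal(count_overlapping(a, peak_set("chr1", 500, 600))$venn_overlap, 0)
  k <- merge_peaks(random_peaks(5, 10000))
  res2 <- count_overlapping(k, k)
  expect_equal(res2$venn_overlap, nrow(k))
})

test_that("interval ops agree with the per-base mask oracle on random cases", {
  set.seed(101)
  L <- 10000
  g <- toy_genome(L)
  for (case in 1:300) {
    a <- random_peaks(sample.int(15, 1), L)
    b <- random_peaks(sample.int(15, 1), L)
    ma <- mask_from_peaks(a, L); mb <- mask_from_peaks(b, L)
    expect_same_intervals(merge_peaks(a), peaks_from_mask(ma))
    expect_same_intervals(intersect_peaks(a, b), peaks_from_mask(ma & mb))
    expect_same_intervals(subtract_peaks(merge_peaks(a), b, "clip"),
                          peaks_from_mask(ma & !mb))
    gap <- sample(0:50, 1)
    expect_same_intervals(merge_peaks(a, gap = gap),
                          peaks_from_mask(mask_close_gaps(ma, gap)))
  }
})

test_that("extend then clip to genome bounds is a no-op", {
  set.seed(11)
  g <- toy_genome(5000)
  for (i in 1:50) {
    ext <- extend_peaks(random_peaks(8, 5000), sample(0:1000, 1), g)
    expect_true(all(ext$start >= 0 & ext$end <= 5000))
  }
})

test_that("genome model enforces unique names and positive lengths", {
  expect_error(genome_model(c("chr1", "chr1"), c(10, 20)), "duplicate")
  expect_error(genome_model("chr1", 0), "positive")
  f <- withr::local_tempfile(lines = "chr1\t1000")
  expect_equal(read_chrom_sizes(f)$length, 1000)
})

test_that("peak classification prioritises TSS over gene body over distal", {
  genes <- gene_models(c("g1", "g2"), c("chr1", "chr1"), c("+", "+"),
                       tss = c(50000, 200000),
                       body_start = c(50000, 200000),
                       body_end = c(80000, 240000))
  peaks <- peak_set(rep("chr1", 3), c(49900, 70000, 150000),
                    c(50100, 70500, 150500))
  res <- annotate_vs_genes(peaks, genes, tss_window = 5000)
  expect_equal(as.character(res$category),
               c("tss_proximal", "gene_body", "distal"))
  expect_equal(sum(res$fractions), 1)
  # gene-free chromosome -> distal
  off <- annotate_vs_genes(peak_set("chr9", 0, 100), genes)
  expect_equal(as.character(off$category), "distal")
})

test_that("TSS-window assignment is strand-aware and multi-gene", {
  genes <- gene_models(c("plus", "minus"), c("chr1", "chr1"), c("+", "-"),
                       tss = c(50000, 50000),
                       body_start = c(50000, 20000),
                       body_end = c(90000, 50000))
  # + strand: window [20000, 50100); peak 20-25 kb upstream is inside
  expect_equal(assign_to_tss_windows(peak_set("chr1", 25000, 26000),
                                     genes[1, ], upstream = 30000,
                                     downstream = 100)[[1]], "plus")
  # - strand: mirrored window [49900, 80000) on the genomic axis
  g2 <- genes[2, , drop = FALSE]; class(g2) <- class(genes)
  expect_equal(assign_to_tss_windows(peak_set("chr1", 60000, 61000),
                                     g2, 30000, 100)[[1]], "minus")
  # peak overlapping both windows reports both genes
  both <- assign_to_tss_windows(peak_set("chr1", 49950, 50050), genes,
                                30000, 100)[[1]]
  expect_setequal(both, c("plus", "minus"))
  # outside every window
  expect_length(assign_to_tss_windows(peak_set("chr1", 900000, 900100),
                                      genes, 30000, 100)[[1]], 0)
})

test_that("minus-strand TSS window matches a per-base construction", {
  # oracle: mark the window bases directly on the genomic axis
  tss <- 50000; up <- 30000; down <- 100
  L <- 100000
  win_mask <- logical(L)
  win_mask[(tss - down + 1):(tss + up)] <- TRUE  # [tss-down, tss+up)
  genes <- gene_models("m", "chr1", "-", tss, 20000, 50000)
  set.seed(42)
  for (i in 1:50) {
    p <- random_peaks(1, L)
    hit <- length(assign_to_tss_windows(p, genes, up, down)[[1]]) > 0
    expect_equal(hit, any(mask_from_peaks(p, L) & win_mask))
  }
})
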