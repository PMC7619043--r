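test_that("matched simulation preserves layout and respects bounds", {
  g <- genome_model(c("chr1", "chr2"), c(1000, 5000))
  template <- peak_set(c("chr1", "chr2", "chr2"), c(0, 100, 2000),
                       c(100, 400, 2050))
  for (seed in 1:20) {
    sim <- simulate_matched_set(template, g, seed = seed)
    # per-chromosome counts and length multisets are invariant
    expect_equal(table(sim$chrom), table(template$chrom))
    for (ch in unique(template$chrom)) {
      expect_equal(sort(sim$end[sim$chrom == ch] - sim$start[sim$chrom == ch]),
                   sort(template$end[template$chrom == ch] -
                          template$start[template$chrom == ch]))
    }
    len <- chrom <- NULL
    expect_true(all(sim$start >= 0))
    expect_true(all(sim$end <= c(1000, 5000)[match(sim$chrom,
                                                   c("chr1", "chr2"))]))
  }
  # same seed, same draw
  expect_identical(as.data.frame(simulate_matched_set(template, g, seed = 9)),
                   as.data.frame(simulate_matched_set(template, g, seed = 9)))
  expect_error(
    simulate_matched_set(peak_set("chr1", 0, 1001),
                         genome_model("chr1", 1000), seed = 1),
    "absent|longer")
})

test_that("majority-overlap counting uses a strict >50% summed-coverage rule", {
  target <- peak_set("chr1", 0, 100)
  expect_equal(overlap_count_majority(target, merge_peaks(peak_set("chr1", 0, 51))), 1)
  expect_equal(overlap_count_majority(target, merge_peaks(peak_set("chr1", 0, 50))), 0)
  split <- merge_peaks(peak_set(c("chr1", "chr1"), c(0, 60), c(30, 90)))
  expect_equal(overlap_count_majority(target, split), 1)          # 30+30 > 50
  expect_equal(overlap_count_majority(target, split, per_region = "max"), 0)
})

test_that("majority counter agrees with the per-base oracle on random cases", {
  set.seed(404)
  L <- 10000
  for (i in 1:100) {
    target <- random_peaks(sample.int(10, 1), L)
    state <- merge_peaks(random_peaks(sample.int(10, 1), L, max_len = 500))
    sm <- mask_from_peaks(state, L)
    expect_equal(overlap_count_majority(target, state),
                 oracle_majority_count(target, sm))
  }
})

test_that("empirical p-values carry the +1 correction and the two-sided rule", {
  # observed overlap beyond anything a matched draw can plausibly reach:
  # all 20 target peaks are fully covered; random placements on a 1 Mb
  # chromosome virtually never cover even one majority overlap each
  g <- genome_model("chr1", 1e6)
  starts <- seq(0, by = 20, length.out = 20)
  target <- peak_set(rep("chr1", 20), starts, starts + 10)
  states <- annotation_map(list(covered = peak_set("chr1", 0, 400)))
  res <- permutation_enrichment(target, states, n_sim = 1000, genome = g,
                                seed = 5)
  expect_equal(res$observed, 20)
  expect_equal(res$p_over, 1 / 1001)
  expect_equal(res$p_under, 1)
  expect_gt(res$fold, 1)
  expect_equal(res$p_two, res$p_over + (1 - res$p_under))

  # rule (a)/(b) arithmetic on the returned components, over random runs
  set.seed(6)
  L <- 50000
  g2 <- toy_genome(L)
  for (i in 1:10) {
    tgt <- random_peaks(10, L)
    st <- annotation_map(list(s = merge_peaks(random_peaks(8, L, 2000))))
    r <- permutation_enrichment(tgt, st, n_sim = 49, genome = g2, seed = i)
    expect_gte(r$p_over + r$p_under, 1 + 1 / 50)
    if (!is.na(r$fold) && r$fold > 1)
      expect_equal(r$p_two, min(1, r$p_over + (1 - r$p_under)))
    if (!is.na(r$fold) && r$fold < 1)
      expect_equal(r$p_two, min(1, r$p_under + (1 - r$p_over)))
  }
})

test_that("enrichment results are bit-reproducible given seed and n_sim", {
  set.seed(77)
  L <- 50000
  g <- toy_genome(L)
  tgt <- random_peaks(15, L)
  st <- annotation_map(list(a = merge_peaks(random_peaks(10, L, 1000)),
                            b = merge_peaks(random_peaks(5, L, 3000))))
  r1 <- permutation_enrichment(tgt, st, n_sim = 100, genome = g, seed = 123)
  r2 <- permutation_enrichment(tgt, st, n_sim = 100, genome = g, seed = 123)
  expect_identical(r1, r2)
})

test_that("degenerate states yield NA or infinite fold without aborting", {
  g <- genome_model("chr1", 1e6)
  target <- peak_set("chr1", 0, 100)
  # a state that can never reach majority coverage of anything
  states <- annotation_map(list(empty_ish = peak_set("chr1", 999990, 999991)))
  r <- permutation_enrichment(target, states, n_sim = 20, genome = g,
                              seed = 1)
  expect_true(is.na(r$fold) || is.infinite(r$fold))
  expect_equal(r$p_two, 1)
})

test_that("densifying a planted state strictly increases observed overlap", {
  set.seed(88)
  L <- 100000
  g <- toy_genome(L)
  starts <- seq(1000, by = 2000, length.out = 40)
  target <- peak_set(rep("chr1", 40), starts, starts + 300)
  cover_half <- merge_peaks(peak_set(rep("chr1", 20), starts[1:20] - 50,
                                     starts[1:20] + 350))
  cover_all <- merge_peaks(peak_set(rep("chr1", 40), starts - 50,
                                    starts + 350))
  expect_gt(overlap_count_majority(target, cover_all),
            overlap_count_majority(target, cover_half))
})
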