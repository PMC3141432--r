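test_that("percentile ranks follow the mid-rank convention", {
  nulls <- seq_len(1000)
  expect_equal(percentile_rank(2000, nulls)$percentile, 100)
  expect_equal(percentile_rank(-5, nulls)$percentile, 0)
  expect_equal(percentile_rank(3, rep(3, 100))$percentile, 50)
  expect_error(percentile_rank(1, numeric(0)), "empty")
})

test_that("matched null windows respect the genic tolerance exhaustively", {
  s <- small_world(101)
  pan <- s$panel
  ctr <- pan$snps$pos_bp[250]
  nw <- sample_matched_windows(pan, "1", ctr, 2e5, c("grp1", "grp2"),
                               n = 300, seed = 9)
  expect_length(nw$centers, 300)
  focal_frac <- nw$focal$genic_frac
  expect_true(all(abs(nw$genic_frac - focal_frac) <= 0.10 + 1e-12))
  expect_true(all(nw$n_snps > 0))
  expect_true(all(abs(nw$centers - ctr) > 2 * 2e5))   # focal excluded
  # determinism
  nw2 <- sample_matched_windows(pan, "1", ctr, 2e5, c("grp1", "grp2"),
                                n = 300, seed = 9)
  expect_identical(nw$centers, nw2$centers)
})

test_that("a homogeneous genic track accepts every candidate window", {
  s <- small_world(102)
  pan <- s$panel
  pan$snps$genic <- TRUE
  ctr <- pan$snps$pos_bp[250]
  nw <- sample_matched_windows(pan, "1", ctr, 2e5, c("grp1", "grp2"),
                               n = 100, seed = 3)
  expect_equal(unique(nw$genic_frac), 1)
  # rejections can only come from the focal-overlap / empty-window rules
  expect_lt(nw$n_draws, 1e4)
})

test_that("unmatchable genic content errors with the achieved count", {
  s <- small_world(103)
  pan <- s$panel
  # focal window all genic, everything else non-genic, zero tolerance
  ctr <- pan$snps$pos_bp[250]
  pan$snps$genic <- abs(pan$snps$pos_bp - ctr) <= 2e5
  expect_error(
    sample_matched_windows(pan, "1", ctr, 2e5, c("grp1", "grp2"),
                           n = 50, tolerance = 0, seed = 1,
                           max_draws = 2e4),
    "acceptable null windows")
})

test_that("GSF_ST is the mean of exactly G - 1 pairwise ranks", {
  expect_equal(gsfst(c(10, 20, 30, 40, 50, 60), 7), 35)
  expect_equal(gsfst(rep(42.5, 6), 7), 42.5)
  expect_error(gsfst(c(10, 20, 30), 7), "exactly 6")
})

test_that("sliding windows tile the region as specified", {
  # 2.7 Mb region, 400 kb window, 200 kb step -> 13 windows; first center
  # at start + 200 kb, last center at end - 200 kb
  st <- sweepscan:::sliding_starts(29.8e6, 32.5e6, 4e5, 2e5)
  expect_length(st, 13)
  centers <- st + 2e5
  expect_equal(centers[1], 30.0e6)
  expect_equal(centers[length(centers)], 32.3e6)
  expect_true(all(st + 4e5 <= 32.5e6))
  # divisible case has no shifted final window
  st2 <- sweepscan:::sliding_starts(0, 1e6, 4e5, 2e5)
  expect_equal(st2, c(0, 2e5, 4e5, 6e5))
})

test_that("constant-theta panels give mid percentiles everywhere", {
  pan <- constant_theta_panel(n_per_pop = 20, m = 300, spacing = 1e4)
  sl <- sliding_scan(pan, "1", 5e5, 2.5e6, c("p1", "p2"), window = 4e5,
                     step = 2e5, n = 50, seed = 4)
  expect_true(all(sl$mean_fst == 1))
  expect_true(all(sl$percentile == 50))   # every null window ties the focal
})

test_that("pairwise matrix is symmetric with an undefined diagonal", {
  s <- simulate_panel(sim_config(n_pops = 3, haplotypes_per_pop = 40,
                                 n_snps = 400, chrom_length_bp = 2e7,
                                 seed = 105))
  pan <- s$panel
  ctr <- pan$snps$pos_bp[200]
  M <- pairwise_matrix(pan, "1", ctr, 2e5, n_null = 50, seed = 6)
  expect_equal(dim(M), c(3, 3))
  expect_true(all(is.na(diag(M))))
  expect_equal(M, t(M))
  expect_equal(sum(!is.na(M)), 6)        # 3 unique off-diagonal cells
  # a pair monomorphic across the chromosome yields an NA cell
  pan2 <- pan
  r1 <- panel_rows(pan2, "pop1", by = "population")
  r2 <- panel_rows(pan2, "pop2", by = "population")
  pan2$alleles[c(r1, r2), ] <- 0L
  M2 <- pairwise_matrix(pan2, "1", ctr, 2e5, n_null = 50, seed = 6)
  expect_true(is.na(M2["pop1", "pop2"]))
})

test_that("focal-window percentiles are roughly uniform under exchangeability", {
  # small smoke version of the calibration; the full 200-replicate KS test
  # lives in the acceptance suite
  pr <- vapply(1:40, function(r) {
    s <- small_world(200 + r)
    fi <- 100 + 7 * r
    window_percentile(s$panel, "1", s$panel$snps$pos_bp[fi], 2e5,
                      c("grp1", "grp2"), n = 100, seed = r)$percentile
  }, 0)
  expect_gt(mean(pr), 25)
  expect_lt(mean(pr), 75)
  expect_gt(stats::sd(pr), 10)   # not collapsed onto a single rank
})
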