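test_that("ld_pair reproduces the worked LD examples", {
  # perfect coupling: only 00 and 11 haplotypes
  a <- c(rep(1L, 50), rep(0L, 50))
  lp <- ld_pair(a, a)
  expect_equal(lp$d_prime, 1)
  expect_equal(lp$r2, 1)
  expect_gt(lp$ci_low, 0.9)
  expect_equal(lp$ci_high, 1)
  # all four haplotypes equally frequent: no LD
  a2 <- c(rep(1L, 50), rep(0L, 50))
  b2 <- rep(c(1L, 0L), 50)
  lp2 <- ld_pair(a2, b2)
  expect_equal(lp2$d_prime, 0)
  expect_equal(lp2$r2, 0)
  # counts (11:45, 10:5, 01:5, 00:45)
  a3 <- c(rep(1L, 50), rep(0L, 50))
  b3 <- c(rep(1L, 45), rep(0L, 5), rep(1L, 5), rep(0L, 45))
  lp3 <- ld_pair(a3, b3)
  expect_equal(lp3$d_prime, 0.8)
  expect_equal(lp3$r2, 0.64)
  expect_error(ld_pair(rep(0L, 10), a2[1:10]), "monomorphic")
})

test_that("fast pair classification agrees with the grid-CI route", {
  set.seed(17)
  th <- list(ci_low = 0.70, ci_high = 0.98, recomb_high = 0.90, prop = 0.95)
  for (i in 1:300) {
    n <- sample(c(30, 60, 120), 1)
    pA <- runif(1, 0.1, 0.9); pB <- runif(1, 0.1, 0.9)
    rho <- runif(1, -0.8, 0.9)
    a <- rbinom(n, 1, pA)
    b <- ifelse(runif(n) < abs(rho), if (rho > 0) a else 1L - a,
                rbinom(n, 1, pB))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    slow <- sweepscan:::classify_pair(ld_pair(a, b), th)
    n11 <- sum(a & b); n10 <- sum(a & !b); n01 <- sum(!a & b)
    fast <- sweepscan:::classify_counts(n11, n10, n01, n - n11 - n10 - n01, th)
    expect_equal(fast, slow)
  }
})

test_that("gabriel_blocks handles the canonical small cases", {
  set.seed(1)
  h <- rbinom(100, 1, 0.5)
  # two perfectly coupled SNPs -> one 2-SNP block
  pan <- toy_panel(cbind(h, h), pos_bp = c(100, 200),
                   pops = rep("p1", 50))
  expect_equal(gabriel_blocks(pan, "1"), list(c(1L, 2L)))
  # two independent SNPs -> two singleton cores
  g <- rep(c(0L, 1L), 50)
  pan2 <- toy_panel(cbind(h, g), pos_bp = c(100, 200), pops = rep("p1", 50))
  expect_equal(gabriel_blocks(pan2, "1"), list(1L, 2L))
  # (1,2) strong LD, (2,3) strong recombination -> block {1,2} + {3}
  pan3 <- toy_panel(cbind(h, h, g), pos_bp = c(100, 200, 300),
                    pops = rep("p1", 50))
  blocks <- gabriel_blocks(pan3, "1")
  expect_equal(blocks, list(c(1L, 2L), 3L))
  # low-MAF markers are ignored for block building
  rare <- c(rep(1L, 2), rep(0L, 98))
  pan4 <- toy_panel(cbind(h, rare, h), pos_bp = c(100, 200, 300),
                    pops = rep("p1", 50))
  expect_equal(gabriel_blocks(pan4, "1"), list(c(1L, 3L)))
  expect_error(gabriel_blocks(pan, "1", start = 1e6, end = 2e6), "empty")
})

test_that("cores partition the chromosomes of a block", {
  s <- small_world(401)
  pan <- s$panel
  rows <- panel_rows(pan, "grp1")
  blocks <- gabriel_blocks(pan, "1", rows = rows, start = 1e6, end = 3e6)
  for (blk in blocks) {
    cores <- core_haplotypes(pan, blk, rows)
    expect_equal(sum(cores$count), length(rows))
    expect_equal(sort(unlist(cores$carriers)), sort(rows))
    expect_equal(cores$freq, cores$count / length(rows))
  }
})

test_that("EHH reproduces the pair-enumeration examples", {
  pan <- ehh_example_panel()
  expect_equal(ehh(pan, 1L, 1:4, "downstream", 0), 1)
  expect_equal(ehh(pan, 1L, 1:4, "downstream", 2000), 1 / 6)
  expect_equal(rehh(pan, 1L, 1:4, 5:10, "downstream", 2000), 0.625)
  expect_error(ehh(pan, 1L, 1L, "downstream", 100), ">= 2 carrier")
  expect_error(rehh(pan, 1L, 1:4, 5L, "downstream", 100), ">= 2 chromosomes")
})

test_that("REHH limiting cases: identical decay and homozygous core", {
  # core and others both fully homozygous to the horizon -> REHH = 1
  al <- rbind(matrix(c(1L, 0L, 0L), 4, 3, byrow = TRUE),
              matrix(c(0L, 1L, 1L), 4, 3, byrow = TRUE))
  pan <- toy_panel(al, pos_bp = c(1e3, 2e3, 3e3))
  expect_equal(rehh(pan, 1L, 1:4, 5:8, "downstream", 2000), 1)
  # homozygous core (EHH 1) over others with extensions {d,d,e,f}:
  # pooled EHH = C(2,2)/C(4,2) = 1/6, so REHH = 6
  al2 <- rbind(matrix(c(1L, 0L, 0L), 4, 3, byrow = TRUE),
               c(0L, 0L, 0L), c(0L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  pan2 <- toy_panel(al2, pos_bp = c(1e3, 2e3, 3e3))
  expect_equal(ehh(pan2, 1L, 1:4, "downstream", 2000), 1)
  expect_equal(rehh(pan2, 1L, 1:4, 5:8, "downstream", 2000), 6)
})

test_that("EHH curves are non-increasing in distance on simulated panels", {
  s <- small_world(402)
  pan <- s$panel
  rows <- panel_rows(pan, "grp1")
  blocks <- gabriel_blocks(pan, "1", rows = rows, start = 8e6, end = 1e7)
  for (blk in blocks[1:min(5, length(blocks))]) {
    cores <- core_haplotypes(pan, blk, rows)
    carriers <- cores$carriers[[1]]
    if (length(carriers) < 2) next
    for (dir in c("upstream", "downstream")) {
      vals <- vapply(c(0, 1e5, 3e5, 6e5, 1e6, 3e6), function(d)
        ehh(pan, blk, carriers, dir, d), 0)
      expect_true(all(diff(vals) <= 1e-12))
      expect_equal(vals[1], 1)
    }
  }
})

test_that("empirical p ranks REHH within frequency bins", {
  rec <- data.frame(block = seq_len(200), block_start = 1, block_end = 2,
                    core = "x", freq = rep(0.32, 200), n_carriers = 10,
                    direction = "upstream", distance = 3e5, ehh = 0.5,
                    rehh = c(seq_len(199), 500))
  # query is the largest of its 200-record bin: its null set is the other
  # 199 records -> p = 1/200
  out <- rehh_empirical_p(rec, queries = rec[200, ])
  expect_equal(out$p, 1 / 200)
  expect_false(out$widened)
  # median query
  out2 <- rehh_empirical_p(rec, queries = rec[100, ])
  expect_equal(out2$p, (1 + 100) / 200, tolerance = 0.02)
  # underpopulated bin widens to neighbours and flags it
  rec2 <- rec
  rec2$freq[1:5] <- 0.62
  out3 <- rehh_empirical_p(rec2, queries = rec2[1, ])
  expect_true(out3$widened)
  expect_gte(out3$n_bin, 20)
})

test_that("focal_core_records finds the core carrying an allele", {
  s <- small_world(403)
  pan <- s$panel
  rec <- rehh_scan(pan, "grp1", "1", start = 9e6, end = 1.1e7)
  blocks <- attr(rec, "blocks")
  expect_false(is.null(blocks))
  fi <- blocks[[1]][1]
  for (allele in 0:1) {
    fc <- focal_core_records(rec, fi, allele)
    if (nrow(fc) == 0) next
    pos <- match(fi, blocks[[fc$block[1]]])
    expect_true(all(substr(fc$core, pos, pos) == as.character(allele)))
  }
  # a SNP outside every block returns zero rows
  outside <- setdiff(seq_len(n_snps(pan)), unlist(blocks))
  if (length(outside))
    expect_equal(nrow(focal_core_records(rec, outside[1], 1)), 0)
})

test_that("a spiked partial sweep elevates the focal core's REHH", {
  # pilot-calibrated smoke version of the f = 0.3 / 0.3 cM detection
  # (measured per-replicate detection ~0.7; P(>= 3 of 10) > 0.998); the
  # full 50-replicate check at the spec thresholds is in the acceptance
  # suite
  hits <- 0L
  for (r in 1:10) {
    s <- simulate_panel(sim_config(seed = 20000 + r))
    pan <- s$panel
    fi <- which.min(abs(pan$snps$pos_bp - 2e7))
    rows2 <- panel_rows(pan, "pop2", by = "population")
    while (length(unique(pan$alleles[rows2, fi])) < 2) fi <- fi + 1L
    pan <- spike_sweep(pan, sweep_spec(fi, "pop2", 0.3, 0.3,
                                       seed = 21000 + r))
    info <- attr(pan, "sweep_info")
    rec <- rehh_scan(pan, "grp2", "1", distance = 3e5)
    fc <- focal_core_records(rec, fi, info$allele)
    if (nrow(fc) > 0 &&
        any(rehh_empirical_p(rec, queries = fc)$p < 0.01, na.rm = TRUE))
      hits <- hits + 1L
  }
  expect_gte(hits, 3L)
})
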