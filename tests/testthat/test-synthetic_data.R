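test_that("the generator is seed-deterministic and validates its config", {
  a <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 20,
                                 n_snps = 100, seed = 5))
  b <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 20,
                                 n_snps = 100, seed = 5))
  expect_identical(a$panel$alleles, b$panel$alleles)
  expect_identical(a$panel$snps, b$panel$snps)
  expect_error(sim_config(F_target = 1), "F_target")
  expect_error(sim_config(ancestral_freq_range = c(0.5, 0.4)), "degenerate")
})

test_that("no differentiation: mean per-SNP theta stays below 0.01", {
  s <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 100,
                                 n_snps = 1000, F_target = 0, seed = 21))
  th <- fst_snp(s$panel, c("grp1", "grp2"))
  expect_gte(mean(th, na.rm = TRUE), 0)
  expect_lt(mean(th, na.rm = TRUE), 0.01)
})

test_that("mean per-SNP theta matches the Balding-Nichols oracle expectation", {
  # Frozen from a 2e5-SNP run of the independently coded a/b-component
  # estimator (scratch pilot): E[mean theta-hat] = 0.08391 at F = 0.1,
  # 0.14938 at F = 0.2 (2 pops, 100 haplotypes each). The per-SNP ratio
  # with clamping is NOT unbiased for F at r = 2 - the module contract is
  # agreement with the oracle, not with F itself.
  s <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 100,
                                 n_snps = 2000, F_target = 0.1, seed = 22))
  expect_lt(abs(mean(fst_snp(s$panel, c("grp1", "grp2")), na.rm = TRUE) -
                0.08391), 0.012)
  s2 <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 100,
                                  n_snps = 2000, F_target = 0.2, seed = 23))
  expect_lt(abs(mean(fst_snp(s2$panel, c("grp1", "grp2")), na.rm = TRUE) -
                0.14938), 0.012)
})

test_that("per-population frequencies match the Beta moments", {
  F <- 0.2
  s <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 20,
                                 n_snps = 10000, F_target = F, seed = 31))
  tr <- attr(s$panel, "sim_truth")
  dev <- tr$pop_freqs - rep(tr$p_anc, each = 2)   # Beta draw minus mean
  expect_lt(abs(mean(dev)), 0.005)
  v_obs <- mean(dev^2)
  v_exp <- F * mean(tr$p_anc * (1 - tr$p_anc))
  expect_lt(abs(v_obs - v_exp), 0.05 * v_exp)
})

test_that("complete-copy limit: f = 1 with huge decay clones the donor", {
  s <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 40,
                                 n_snps = 200, seed = 41))
  pan <- spike_sweep(s$panel, sweep_spec(100L, "pop1", 1, 1e6, seed = 1))
  rows <- panel_rows(pan, "pop1", by = "population")
  expect_true(all(apply(pan$alleles[rows, ], 2,
                        function(col) length(unique(col)) == 1)))
  # EHH of the focal carriers is 1 at every distance
  for (d in c(1e5, 1e6, 1e7))
    expect_equal(ehh(pan, 100L, rows, "downstream", d), 1)
})

test_that("spiking never touches non-target populations or distal sites", {
  s <- simulate_panel(sim_config(n_pops = 3, haplotypes_per_pop = 40,
                                 n_snps = 300, seed = 51))
  pan0 <- s$panel
  pan1 <- spike_sweep(pan0, sweep_spec(150L, "pop2", 0.5, 0.2, seed = 2))
  other <- panel_rows(pan0, c("pop1", "pop3"), by = "population")
  expect_identical(pan1$alleles[other, ], pan0$alleles[other, ])
  # outside the maximal copied interval the target rows are unchanged too
  info <- attr(pan1, "sweep_info")
  target <- panel_rows(pan0, "pop2", by = "population")
  changed <- which(colSums(pan1$alleles[target, ] != pan0$alleles[target, ]) > 0)
  if (length(changed)) {
    cm <- pan0$snps$pos_cM
    # all changed columns lie within a contiguous cM envelope around focal
    expect_true(all(abs(cm[changed] - cm[150]) <=
                    max(abs(cm[changed] - cm[150]))))
    lo <- min(changed); hi <- max(changed)
    outside <- setdiff(seq_len(n_snps(pan0)), lo:hi)
    expect_identical(pan1$alleles[target, outside],
                     pan0$alleles[target, outside])
  }
  expect_error(spike_sweep(pan0, sweep_spec(150L, "nope", 0.5, 0.2)),
               "absent")
})

test_that("spiking requires a polymorphic focal site", {
  s <- simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 20,
                                 n_snps = 50, seed = 61))
  pan <- s$panel
  rows <- panel_rows(pan, "pop1", by = "population")
  pan$alleles[rows, 10] <- 0L
  expect_error(spike_sweep(pan, sweep_spec(10L, "pop1", 0.5, 0.2)),
               "monomorphic")
})
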