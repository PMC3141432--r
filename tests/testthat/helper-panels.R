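# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# minimal hand-built panel: explicit allele matrix, evenly spaced SNPs
toy_panel <- function(alleles, pos_bp = NULL, pops = NULL, groups = NULL,
                      genic = FALSE, chrom = "1", pos_cM = NULL) {
  alleles <- as.matrix(alleles)
  m <- ncol(alleles)
  n_ind <- nrow(alleles) / 2
  if (is.null(pos_bp)) pos_bp <- seq_len(m) * 1000
  if (is.null(pos_cM)) pos_cM <- pos_bp / 1e6
  if (is.null(pops)) pops <- rep("p1", n_ind)
  if (is.null(groups)) groups <- pops
  haplotype_panel(
    alleles,
    data.frame(snp_id = paste0("s", seq_len(m)), chrom = chrom,
               pos_bp = pos_bp, pos_cM = pos_cM,
               genic = rep(genic, length.out = m)),
    data.frame(sample_id = paste0("i", seq_len(n_ind)),
               population = pops, group = groups))
}

# panel with a fixed difference between two one-population groups at every
# SNP: per-SNP theta is exactly 1 everywhere (a "constant-theta" field)
constant_theta_panel <- function(n_per_pop = 20, m = 200, spacing = 1e4) {
  alleles <- rbind(matrix(0L, n_per_pop, m), matrix(1L, n_per_pop, m))
  toy_panel(alleles, pos_bp = seq_len(m) * spacing,
            pops = rep(c("p1", "p2"), each = n_per_pop / 2))
}

# the EHH worked example: 4 carriers with extensions {a,a,b,c}, 6 others
# with extensions {d,d,d,e,f,f}; core SNP at column 1
ehh_example_panel <- function() {
  al <- rbind(
    c(1, 0, 0), c(1, 0, 0),            # carriers, extension a
    c(1, 1, 0),                        # carrier, extension b
    c(1, 0, 1),                        # carrier, extension c
    c(0, 0, 0), c(0, 0, 0), c(0, 0, 0),# others, extension d
    c(0, 1, 0),                        # other, extension e
    c(0, 0, 1), c(0, 0, 1))            # others, extension f
  toy_panel(al, pos_bp = c(1000, 2000, 3000))
}

# independently coded W&C 1984 haploid estimator via the a/b variance
# components (the oracle route; the package uses the mean-square form)
oracle_wc_theta <- function(n, x) {
  p <- x / n
  r <- length(n); N <- sum(n); nbar <- N / r
  nc <- (N - sum(n^2) / N) / (r - 1)
  pbar <- sum(n * p) / N
  if (pbar <= 0 || pbar >= 1) return(NA_real_)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r) / (nbar - 1))
  if (a + b == 0) return(NA_real_)
  max(0, min(1, a / (a + b)))
}

# brute-force two-sided Fisher p by explicit enumeration over one margin
# (binomial-coefficient route, independent of dhyper)
oracle_fisher <- function(kA, nA, kB, nB) {
  k <- kA + kB
  support <- max(0, k - nB):min(k, nA)
  w <- choose(nA, support) * choose(nB, k - support)
  pr <- w / sum(w)
  obs <- pr[match(kA, support)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# small default simulated world used in several tests
small_world <- function(seed, ...) {
  simulate_panel(sim_config(n_pops = 2, haplotypes_per_pop = 60,
                            n_snps = 500, chrom_length_bp = 2e7,
                            seed = seed, ...))
}
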