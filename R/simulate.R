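# Synthetic structured panels under the Balding-Nichols model, plus an
# optional spiked partial sweep. The baseline is linkage equilibrium between
# SNPs: the null REHH distribution is then exchangeable and any haplotype
# signal is attributable solely to spike_sweep().

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the Balding-Nichols panel simulator
#'
#' Defaults emulate a sparse genotyping-array panel over a 40 Mb chromosome:
#' 1200 SNPs (about one per 33 kb), a uniform recombination rate of
#' 1 cM/Mb, ancestral allele frequencies uniform on (0.05, 0.95) as after
#' array-style common-variant ascertainment, a between-population
#' differentiation of F = 0.05 (typical of human continental comparisons),
#' and 40% of SNPs genic in contiguous blocks.
#'
#' @param n_pops number of populations
#' @param haplotypes_per_pop chromosome copies per population (even)
#' @param n_snps SNP count
#' @param chrom_length_bp chromosome length in bases
#' @param F_target Balding-Nichols differentiation parameter in `[0, 1)`
#' @param ancestral_freq_range range the ancestral frequency is drawn from
#' @param recomb_rate_cM_per_Mb uniform recombination rate
#' @param genic_fraction expected fraction of SNPs flagged genic
#' @param pops_per_group populations pooled into each group label
#' @param chrom chromosome label
#' @param seed integer seed; fully determines the output
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_pops = 4, haplotypes_per_pop = 100, n_snps = 1200,
                       chrom_length_bp = 4e7, F_target = 0.05,
                       ancestral_freq_range = c(0.05, 0.95),
                       recomb_rate_cM_per_Mb = 1, genic_fraction = 0.4,
                       pops_per_group = 1, chrom = "1", seed = 1) {
  if (F_target < 0 || F_target >= 1) stop("F_target must be in [0, 1)")
  if (haplotypes_per_pop %% 2 != 0) stop("haplotypes_per_pop must be even")
  r <- ancestral_freq_range
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] >= r[2])
    stop("degenerate ancestral_freq_range")
  if (n_pops %% pops_per_group != 0)
    stop("n_pops must be a multiple of pops_per_group")
  cfg <- list(n_pops = n_pops, haplotypes_per_pop = haplotypes_per_pop,
              n_snps = n_snps, chrom_length_bp = chrom_length_bp,
              F_target = F_target, ancestral_freq_range = r,
              recomb_rate_cM_per_Mb = recomb_rate_cM_per_Mb,
              genic_fraction = genic_fraction,
              pops_per_group = pops_per_group, chrom = chrom, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a structured phased panel
#'
#' Per SNP an ancestral frequency `p` is drawn uniformly from
#' `ancestral_freq_range`; each population's frequency is then drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` (equal to `p` when `F = 0`), so that the
#' per-population frequency has mean `p` and variance `F p (1-p)`. Alleles
#' are drawn independently per site and chromosome copy (linkage
#' equilibrium). Physical positions are uniform-random sorted; genetic
#' positions follow the constant recombination rate; the genic flag is
#' assigned in contiguous runs of SNPs.
#'
#' @param cfg a [sim_config()]
#' @return list with elements `panel` (a [haplotype_panel()]) and `map`
#'   (a [genetic_map()])
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    m <- cfg$n_snps
    p_anc <- stats::runif(m, cfg$ancestral_freq_range[1],
                          cfg$ancestral_freq_range[2])
    F <- cfg$F_target
    freqs <- matrix(0, cfg$n_pops, m)
    for (i in seq_len(cfg$n_pops)) {
      freqs[i, ] <- if (F == 0) p_anc else
        stats::rbeta(m, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    }
    nh <- cfg$haplotypes_per_pop
    alleles <- matrix(0L, cfg$n_pops * nh, m)
    for (i in seq_len(cfg$n_pops)) {
      rows <- (i - 1L) * nh + seq_len(nh)
      alleles[rows, ] <- matrix(
        stats::rbinom(nh * m, 1L, rep(freqs[i, ], each = nh)), nh, m)
    }
    pos_bp <- sort(sample.int(cfg$chrom_length_bp, m))
    pos_cM <- pos_bp / 1e6 * cfg$recomb_rate_cM_per_Mb
    genic <- logical(m)
    i <- 1L
    while (i <= m) {
      run <- 1L + stats::rgeom(1, 1 / 8)      # mean run of 8 SNPs
      j <- min(m, i + run - 1L)
      genic[i:j] <- stats::runif(1) < cfg$genic_fraction
      i <- j + 1L
    }
    pops <- paste0("pop", seq_len(cfg$n_pops))
    groups <- paste0("grp", ceiling(seq_len(cfg$n_pops) / cfg$pops_per_group))
    n_ind <- nh %/% 2L
    samples <- data.frame(
      sample_id = paste0(rep(pops, each = n_ind), "_ind",
                         rep(seq_len(n_ind), cfg$n_pops)),
      population = rep(pops, each = n_ind),
      group = rep(groups, each = n_ind),
      stringsAsFactors = FALSE)
    snps <- data.frame(
      snp_id = paste0("snp", seq_len(m)), chrom = cfg$chrom,
      pos_bp = pos_bp, pos_cM = pos_cM, genic = genic,
      stringsAsFactors = FALSE)
    map <- genetic_map(rep(cfg$chrom, 2), c(1, cfg$chrom_length_bp),
                       c(0, cfg$chrom_length_bp / 1e6 *
                           cfg$recomb_rate_cM_per_Mb))
    panel <- haplotype_panel(alleles, snps, samples)
    # ground truth for moment checks on the generator itself
    attr(panel, "sim_truth") <- list(p_anc = p_anc, pop_freqs = freqs)
    list(panel = panel, map = map)
  })
}

#' Specification of a spiked partial sweep
#'
#' @param focal_snp SNP id or column index of the swept site
#' @param target_pop population label(s) receiving the sweep
#' @param carrier_fraction fraction `f` in `(0, 1]` of the target
#'   population's chromosomes that receive the donor haplotype
#' @param decay_scale_cM mean one-sided extent (genetic distance) of the
#'   copied haplotype; per recipient and side the extent is
#'   `Exponential(mean = decay_scale_cM)`
#' @param allele allele (0/1) the donor must carry at the focal SNP; default
#'   is the minor allele in the target population
#' @param seed integer seed
#' @export
sweep_spec <- function(focal_snp, target_pop, carrier_fraction,
                       decay_scale_cM, allele = NULL, seed = 1) {
  if (carrier_fraction <= 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in (0, 1]")
  if (decay_scale_cM < 0) stop("decay_scale_cM must be >= 0")
  structure(list(focal_snp = focal_snp, target_pop = target_pop,
                 carrier_fraction = carrier_fraction,
                 decay_scale_cM = decay_scale_cM, allele = allele,
                 seed = seed),
            class = "sweep_spec")
}

#' Spike a partial-sweep haplotype into a panel
#'
#' One donor chromosome of the target population carrying the chosen allele
#' at the focal SNP is selected; a fraction `f` of the target population's
#' chromosomes have their alleles replaced by the donor's over
#' `[focal - d_left, focal + d_right]`, with each one-sided extent drawn
#' independently per recipient from an exponential with mean
#' `decay_scale_cM` (genetic distance). All other chromosomes are untouched.
#'
#' @param panel a `haplotype_panel`
#' @param spec a [sweep_spec()]
#' @return the modified panel
#' @export
spike_sweep <- function(panel, spec) {
  stopifnot(inherits(spec, "sweep_spec"))
  fi <- if (is.character(spec$focal_snp)) focal_index(panel, spec$focal_snp)
        else as.integer(spec$focal_snp)
  rows <- panel_rows(panel, spec$target_pop, by = "population")
  if (length(rows) == 0L) stop("target population absent: ", spec$target_pop)
  av <- panel$alleles[rows, fi]
  if (length(unique(av)) < 2L)
    stop("focal SNP monomorphic in target population")
  allele <- spec$allele
  if (is.null(allele))
    allele <- if (mean(av) <= 0.5) 1L else 0L
  with_seed(spec$seed, {
    donors <- rows[panel$alleles[rows, fi] == allele]
    donor <- if (length(donors) == 1L) donors else sample(donors, 1L)
    n_rec <- max(1L, round(spec$carrier_fraction * length(rows)))
    recip <- sample(setdiff(rows, donor), min(n_rec, length(rows) - 1L))
    on_chrom <- panel$snps$chrom == panel$snps$chrom[fi]
    cm <- panel$snps$pos_cM
    cm0 <- cm[fi]
    for (r in recip) {
      d_left <- stats::rexp(1, 1 / spec$decay_scale_cM)
      d_right <- stats::rexp(1, 1 / spec$decay_scale_cM)
      sel <- on_chrom & cm >= cm0 - d_left & cm <= cm0 + d_right
      panel$alleles[r, sel] <- panel$alleles[donor, sel]
    }
    attr(panel, "sweep_info") <- list(focal_index = fi, allele = allele,
                                      donor = donor, recipients = recip)
  })
  panel
}
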