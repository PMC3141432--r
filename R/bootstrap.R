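# Bootstrap test of differential window differentiation.
#
# T = (theta_X,A-B - theta_X,A-C) - (thetabar_bg,A-B - thetabar_bg,A-C):
# the focal-window F_ST difference between pairs (A,B) and (A,C) minus the
# same difference over the mean of the matched background windows. Under
# the null that the focal window behaves like the background, E(T) = 0.
# Individuals are resampled with replacement, stratified within population;
# the focal and background windows stay fixed across replicates.

#' T statistic from its four components
#'
#' @param theta_X_AB,theta_X_AC focal-window mean F_ST for pairs (A,B), (A,C)
#' @param bg_AB,bg_AC mean over the background windows (excluding the focal
#'   window) of the window mean F_ST for the same pairs
#' @return `T` in `[-2, 2]`
#' @export
compute_T <- function(theta_X_AB, theta_X_AC, bg_AB, bg_AC) {
  (theta_X_AB - theta_X_AC) - (bg_AB - bg_AC)
}

# window means for a fixed set of windows given a theta vector; windows is a
# list(i1 = , i2 = ) of index bounds into the chromosome SNP ordering
fixed_window_means <- function(theta, i1, i2) {
  def <- !is.na(theta)
  ct <- c(0, cumsum(ifelse(def, theta, 0)))
  cd <- c(0, cumsum(as.numeric(def)))
  nd <- cd[i2 + 1L] - cd[i1]
  s <- ct[i2 + 1L] - ct[i1]
  ifelse(nd > 0, s / nd, NA)
}

#' Bootstrap test that a focal window's differentiation difference exceeds
#' the chromosomal background
#'
#' Computes `T_obs` on the observed panel, then `B_reps` bootstrap
#' replicates in which individuals are resampled with replacement within
#' each population (sample sizes preserved); per replicate the same focal
#' and background (matched null) windows are re-evaluated and `T*` recorded.
#' `p_conservative = (1 + #\{|T* - mean(T*)| >= |T_obs|\}) / (B + 1)`;
#' `p_asymptotic` is the upper tail of chi-squared(1) at `(T_obs/sigma)^2`
#' with `sigma` the ordinary (n-1) sample standard deviation of the `T*`.
#'
#' @param panel a `haplotype_panel`
#' @param chrom chromosome label of the focal window
#' @param center,half_width focal window (bp)
#' @param A,B,C three distinct group labels; pairs tested are (A,B) vs (A,C)
#' @param by `"group"` or `"population"`
#' @param n_null matched background windows per pair
#' @param B_reps bootstrap replicates (paper default 1000)
#' @param tolerance genic-fraction matching tolerance for the nulls
#' @param seed integer seed
#' @return object of class `bootstrap_result`
#' @export
bootstrap_fst_test <- function(panel, chrom, center, half_width, A, B, C,
                               by = "group", n_null = 1000, B_reps = 1000,
                               tolerance = 0.10, seed = 1) {
  if (length(unique(c(A, B, C))) != 3) stop("A, B, C must be distinct")
  on_ch <- which(panel$snps$chrom == chrom)
  pos <- panel$snps$pos_bp[on_ch]

  # fixed null windows, matched per pair on the observed panel
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 3))
  nulls <- list()
  for (pr in list(c(A, B), c(A, C))) {
    key <- paste(pr, collapse = "-")
    nulls[[key]] <- sample_matched_windows(
      panel, chrom, center, half_width, pair = pr, by = by, n = n_null,
      tolerance = tolerance, seed = seeds[match(key, c(paste(A, B, sep = "-"),
                                                       paste(A, C, sep = "-")))])
  }

  # index bounds of focal + null windows into the chromosome SNP ordering
  win_idx <- function(centers) {
    lo <- centers - half_width; hi <- centers + half_width
    list(i1 = findInterval(lo, pos, left.open = TRUE) + 1L,
         i2 = findInterval(hi, pos))
  }
  wAB <- win_idx(nulls[[paste(A, B, sep = "-")]]$centers)
  wAC <- win_idx(nulls[[paste(A, C, sep = "-")]]$centers)
  wX <- win_idx(center)

  # per-individual allele sums on this chromosome, stratified by population
  # (resampling preserves each population's sample size even when the
  # compared units are pooled groups)
  units <- c(A, B, C)
  pops_of_unit <- lapply(units, function(u) {
    if (by == "population") return(u)
    unique(panel$samples$population[panel$samples$group == u])
  })
  names(pops_of_unit) <- units
  G <- list()          # population -> individuals x snps allele-sum matrix
  for (p in unlist(pops_of_unit)) {
    rows <- panel_rows(panel, p, by = "population")
    if (length(rows) < 2) stop("population '", p, "' has < 2 haplotypes")
    h <- panel$alleles[rows, on_ch, drop = FALSE]
    odd <- seq(1, nrow(h), by = 2)
    G[[p]] <- h[odd, , drop = FALSE] + h[odd + 1, , drop = FALSE]
  }
  sizes <- vapply(pops_of_unit, function(ps)
    2L * sum(vapply(G[ps], nrow, 0L)), 0L)

  theta_pair <- function(cnt1, cnt2, n1, n2)
    theta_from_counts(rbind(cnt1, cnt2), c(n1, n2))

  eval_T <- function(cAB_A, cAB_B, cAC_A, cAC_C) {
    thAB <- theta_pair(cAB_A, cAB_B, sizes[A], sizes[B])
    thAC <- theta_pair(cAC_A, cAC_C, sizes[A], sizes[C])
    xAB <- fixed_window_means(thAB, wX$i1, wX$i2)
    xAC <- fixed_window_means(thAC, wX$i1, wX$i2)
    bgAB <- mean(fixed_window_means(thAB, wAB$i1, wAB$i2), na.rm = TRUE)
    bgAC <- mean(fixed_window_means(thAC, wAC$i1, wAC$i2), na.rm = TRUE)
    c(xAB, xAC, bgAB, bgAC)
  }

  unit_count <- function(pop_counts, u)
    Reduce(`+`, pop_counts[pops_of_unit[[u]]])
  obs_pop <- lapply(G, colSums)
  comp <- eval_T(unit_count(obs_pop, A), unit_count(obs_pop, B),
                 unit_count(obs_pop, A), unit_count(obs_pop, C))
  if (anyNA(comp)) stop("undefined T component on the observed panel")
  T_obs <- compute_T(comp[1], comp[2], comp[3], comp[4])

  redraws <- 0L
  T_star <- with_seed(seeds[3], {
    vapply(seq_len(B_reps), function(b) {
      repeat {
        cnt <- lapply(G, function(g) {
          k <- nrow(g)
          colSums(g[sample.int(k, k, replace = TRUE), , drop = FALSE])
        })
        v <- eval_T(unit_count(cnt, A), unit_count(cnt, B),
                    unit_count(cnt, A), unit_count(cnt, C))
        if (!anyNA(v)) return(compute_T(v[1], v[2], v[3], v[4]))
        redraws <<- redraws + 1L
      }
    }, 0)
  })

  sigma <- stats::sd(T_star)
  p_cons <- (1 + sum(abs(T_star - mean(T_star)) >= abs(T_obs))) / (B_reps + 1)
  p_asym <- if (sigma == 0) {
    if (T_obs == 0) 1 else 0      # degenerate resampling distribution
  } else stats::pchisq((T_obs / sigma)^2, df = 1, lower.tail = FALSE)
  structure(list(T_obs = T_obs, T_star = T_star, sigma_hat = sigma,
                 p_conservative = p_cons, p_asymptotic = p_asym,
                 B = B_reps, seed = seed, redraws = redraws,
                 components = c(theta_X_AB = comp[1], theta_X_AC = comp[2],
                                bg_AB = comp[3], bg_AC = comp[4])),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "bootstrap_result: T_obs = %.5f, sigma_hat = %.5f\n  p_conservative = %.4g (B = %d), p_asymptotic = %.4g\n",
    x$T_obs, x$sigma_hat, x$p_conservative, x$B, x$p_asymptotic))
  invisible(x)
}
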