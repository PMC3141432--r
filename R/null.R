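# Empirical null distributions from random windows of the same chromosome,
# matched on genic SNP content. The focal window's statistic is ranked
# against N matched windows; ranks use the mid-rank tie convention.

# chromosome context with cumulative sums for O(1) window statistics
null_ctx <- function(panel, chrom, theta, unit = "bp") {
  on_ch <- panel$snps$chrom == chrom
  pos <- if (unit == "bp") panel$snps$pos_bp[on_ch] else panel$snps$pos_cM[on_ch]
  genic <- panel$snps$genic[on_ch]
  if (anyNA(genic))
    stop("genic annotation required for matched null windows")
  th <- theta[on_ch]
  def <- !is.na(th)
  th0 <- ifelse(def, th, 0)
  list(pos = pos, n = length(pos),
       cg = c(0, cumsum(as.numeric(genic))),
       cd = c(0, cumsum(as.numeric(def))),
       ct = c(0, cumsum(th0)))
}

# vectorised closed-window stats over [lo, hi]
ctx_window_stats <- function(ctx, lo, hi) {
  i1 <- findInterval(lo, ctx$pos, left.open = TRUE) + 1L
  i2 <- findInterval(hi, ctx$pos)
  n_snp <- pmax(i2 - i1 + 1L, 0L)
  i2 <- pmax(i2, i1 - 1L)
  genic_cnt <- ctx$cg[i2 + 1L] - ctx$cg[i1]
  def_cnt <- ctx$cd[i2 + 1L] - ctx$cd[i1]
  th_sum <- ctx$ct[i2 + 1L] - ctx$ct[i1]
  list(n_snp = n_snp, genic_frac = ifelse(n_snp > 0, genic_cnt / n_snp, NA),
       n_def = def_cnt, mean = ifelse(def_cnt > 0, th_sum / def_cnt, NA))
}

# rejection-sample n matched windows; deterministic under the current RNG
# state. Returns accepted centers and their window stats.
matched_windows <- function(ctx, center, half_width, n = 1000,
                            tolerance = 0.10, max_draws = 1e6) {
  focal <- ctx_window_stats(ctx, center - half_width, center + half_width)
  if (focal$n_snp == 0) stop("focal window holds no SNPs")
  lo_f <- focal$genic_frac - tolerance
  hi_f <- focal$genic_frac + tolerance
  rng <- range(ctx$pos)
  acc_c <- numeric(0); acc_m <- numeric(0); acc_g <- numeric(0)
  acc_n <- integer(0)
  drawn <- 0
  while (length(acc_c) < n && drawn < max_draws) {
    k <- min(max(4L * n, 1000L), max_draws - drawn)
    drawn <- drawn + k
    cand <- stats::runif(k, rng[1], rng[2])
    st <- ctx_window_stats(ctx, cand - half_width, cand + half_width)
    ok <- st$n_snp > 0 & st$n_def > 0 &
      st$genic_frac >= lo_f & st$genic_frac <= hi_f &
      abs(cand - center) > 2 * half_width       # exclude the focal window
    acc_c <- c(acc_c, cand[ok]); acc_m <- c(acc_m, st$mean[ok])
    acc_g <- c(acc_g, st$genic_frac[ok]); acc_n <- c(acc_n, st$n_snp[ok])
  }
  if (length(acc_c) < n)
    stop("only ", length(acc_c), " acceptable null windows after ",
         drawn, " draws (need ", n, ")")
  keep <- seq_len(n)
  list(centers = acc_c[keep], means = acc_m[keep],
       genic_frac = acc_g[keep], n_snps = acc_n[keep],
       focal = focal, n_draws = drawn)
}

#' Sample genic-content-matched random windows
#'
#' Rejection-samples uniformly positioned windows of the same (bp) size on
#' the same chromosome until `n` are accepted whose genic SNP fraction lies
#' within `tolerance` (absolute) of the focal window's; windows overlapping
#' the focal window or holding no SNP defined for the comparison are
#' rejected.
#'
#' @param panel a `haplotype_panel`
#' @param chrom chromosome label
#' @param center,half_width focal window center and half-width (bp)
#' @param pair,by comparison passed to [fst_snp()] (used to mark defined SNPs)
#' @param n number of null windows (paper default 1000)
#' @param tolerance absolute genic-fraction tolerance (default 0.10)
#' @param seed integer seed; same seed gives identical window centers
#' @param max_draws bound on candidate draws before giving up
#' @return list with `centers`, `means` (window mean F_ST), `genic_frac`,
#'   `n_snps`, `focal` (focal-window stats), `n_draws`, `seed`
#' @export
sample_matched_windows <- function(panel, chrom, center, half_width,
                                   pair = NULL, by = "group", n = 1000,
                                   tolerance = 0.10, seed = 1,
                                   max_draws = 1e6) {
  theta <- fst_snp(panel, pair, by = by)
  ctx <- null_ctx(panel, chrom, theta)
  out <- with_seed(seed,
    matched_windows(ctx, center, half_width, n, tolerance, max_draws))
  out$seed <- seed
  out
}

#' Mid-rank percentile of a value among null values
#'
#' `rank = 100 (#\{null < value\} + 0.5 #\{null = value\}) / N`.
#'
#' @param value focal statistic
#' @param nulls numeric vector of null statistics (NA dropped)
#' @return list with `value`, `percentile` in `[0, 100]`, `n`
#' @export
percentile_rank <- function(value, nulls) {
  nulls <- nulls[!is.na(nulls)]
  if (length(nulls) == 0) stop("empty null set")
  pr <- 100 * (sum(nulls < value) + 0.5 * sum(nulls == value)) / length(nulls)
  list(value = value, percentile = pr, n = length(nulls))
}

#' Percentile of a focal window's mean F_ST against matched nulls
#'
#' Convenience wrapper: computes the focal window mean for the pair, samples
#' the matched null set, and returns the percentile rank.
#'
#' @inheritParams sample_matched_windows
#' @return list with focal `mean`, `n_snps`, `percentile`, `null` (the
#'   matched-window set)
#' @export
window_percentile <- function(panel, chrom, center, half_width, pair = NULL,
                              by = "group", n = 1000, tolerance = 0.10,
                              seed = 1, max_draws = 1e6) {
  nw <- sample_matched_windows(panel, chrom, center, half_width, pair, by,
                               n, tolerance, seed, max_draws)
  if (is.na(nw$focal$mean)) stop("focal window has no defined SNP")
  pr <- percentile_rank(nw$focal$mean, nw$means)
  list(mean = nw$focal$mean, n_snps = nw$focal$n_snp,
       percentile = pr$percentile, null = nw)
}

#' Group-specific F_ST (GSF_ST)
#'
#' The arithmetic mean of the focal group's pairwise window-F_ST percentile
#' ranks against each of the other groups: with G groups, exactly G - 1
#' ranks enter.
#'
#' @param ranks numeric vector of the pairwise percentile ranks involving
#'   the group in question
#' @param n_groups total number of groups G
#' @return the mean rank
#' @export
gsfst <- function(ranks, n_groups) {
  if (length(ranks) != n_groups - 1)
    stop("GSF_ST needs exactly ", n_groups - 1, " pairwise ranks, got ",
         length(ranks))
  if (anyNA(ranks)) stop("missing pairwise rank")
  mean(ranks)
}

# window starts tiling [start, end]: every `step`, final window shifted to
# end exactly at `end` when the grid does not land there
sliding_starts <- function(start, end, window, step) {
  if (end - start <= window) return(start)
  s <- seq(start, end - window, by = step)
  if (s[length(s)] < end - window) s <- c(s, end - window)
  s
}

#' Sliding-window F_ST percentile scan
#'
#' Windows of fixed width tile the region with the given step (default
#' 400 kb windows, 200 kb step, i.e. half-overlapping); the final window is
#' shifted to end exactly at the region end. Each window is ranked against
#' its own matched null set.
#'
#' @inheritParams sample_matched_windows
#' @param start,end region bounds (bp)
#' @param window,step window width and step (bp)
#' @return data.frame: `center`, `start`, `end`, `mean_fst`, `n_snps`,
#'   `percentile`, `genic_frac`
#' @export
sliding_scan <- function(panel, chrom, start, end, pair = NULL, by = "group",
                         window = 4e5, step = 2e5, n = 1000,
                         tolerance = 0.10, seed = 1, max_draws = 1e6) {
  if (end <= start) stop("empty region")
  theta <- fst_snp(panel, pair, by = by)
  ctx <- null_ctx(panel, chrom, theta)
  starts <- sliding_starts(start, end, window, step)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(starts)))
  rows <- lapply(seq_along(starts), function(k) {
    ctr <- starts[k] + window / 2
    st <- ctx_window_stats(ctx, starts[k], starts[k] + window)
    if (st$n_def == 0)
      return(data.frame(center = ctr, start = starts[k],
                        end = starts[k] + window, mean_fst = NA,
                        n_snps = st$n_snp, percentile = NA, genic_frac = NA))
    nw <- with_seed(seeds[k],
      matched_windows(ctx, ctr, window / 2, n, tolerance, max_draws))
    data.frame(center = ctr, start = starts[k], end = starts[k] + window,
               mean_fst = st$mean, n_snps = st$n_snp,
               percentile = percentile_rank(st$mean, nw$means)$percentile,
               genic_frac = st$genic_frac)
  })
  do.call(rbind, rows)
}

#' Pairwise percentile matrix over all populations
#'
#' For every population pair, the focal window's mean F_ST is ranked against
#' that pair's own matched null windows; the result is a symmetric matrix of
#' percentile ranks with an undefined diagonal. Cells where the pair is
#' monomorphic across the window are `NA`.
#'
#' @inheritParams sample_matched_windows
#' @param n_null null windows per pair
#' @return numeric matrix with population labels on both dimensions
#' @export
pairwise_matrix <- function(panel, chrom, center, half_width,
                            n_null = 1000, tolerance = 0.10, seed = 1,
                            max_draws = 1e6) {
  pops <- unique(panel$samples$population)
  if (length(pops) < 2) stop("need at least 2 populations")
  M <- matrix(NA_real_, length(pops), length(pops),
              dimnames = list(pops, pops))
  pairs <- utils::combn(length(pops), 2)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, ncol(pairs)))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    theta <- fst_snp(panel, c(pops[i], pops[j]), by = "population")
    ctx <- null_ctx(panel, chrom, theta)
    st <- ctx_window_stats(ctx, center - half_width, center + half_width)
    if (st$n_def == 0) next                       # monomorphic pair: NA cell
    nw <- with_seed(seeds[k],
      matched_windows(ctx, center, half_width, n_null, tolerance, max_draws))
    M[i, j] <- M[j, i] <- percentile_rank(st$mean, nw$means)$percentile
  }
  M
}
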