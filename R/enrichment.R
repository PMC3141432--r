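# Enrichment of extreme REHH cores per group: threshold tallies, pairwise
# two-sided Fisher exact tests, and Q-Q diagnostics for empirical p-values.

#' Count extreme-REHH cores per group and threshold
#'
#' @param records data.frame with columns `group` and `p` (empirical REHH
#'   p-values for the cores examined in a region)
#' @param thresholds p-value cutoffs; defaults correspond to the 99.9th,
#'   99.5th, 99th and 95th percentiles of the empirical distribution
#' @return data.frame, one row per group: `n_cores` examined and one count
#'   column per threshold (`p < threshold`)
#' @export
count_extreme <- function(records,
                          thresholds = c(0.001, 0.005, 0.01, 0.05)) {
  stopifnot(all(c("group", "p") %in% names(records)))
  groups <- unique(records$group)
  out <- data.frame(group = groups,
                    n_cores = vapply(groups, function(g)
                      sum(records$group == g), 0L),
                    stringsAsFactors = FALSE)
  for (t in thresholds)
    out[[paste0("n_p_lt_", t)]] <- vapply(groups, function(g)
      sum(records$group == g & records$p < t, na.rm = TRUE), 0L)
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for excess of extreme cores
#'
#' Exact p by summing, over the hypergeometric distribution fixed at the
#' table margins, the probabilities of all outcomes no more likely than the
#' observed one (the standard two-sided convention, with a small relative
#' tolerance against floating-point ties).
#'
#' @param extremeA,totalA extreme and total core counts in group A
#' @param extremeB,totalB the same for group B
#' @return two-sided p-value in `(0, 1]`
#' @export
fisher_excess <- function(extremeA, totalA, extremeB, totalB) {
  if (totalA <= 0 || totalB <= 0) stop("zero totals")
  if (extremeA > totalA || extremeB > totalB || extremeA < 0 || extremeB < 0)
    stop("counts exceed totals")
  k <- extremeA + extremeB
  support <- max(0, k - totalB):min(k, totalA)
  pr <- stats::dhyper(support, totalA, totalB, k)
  obs <- stats::dhyper(extremeA, totalA, totalB, k)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Pairwise Fisher tests over an enrichment table
#'
#' @param counts output of [count_extreme()]
#' @param column which threshold column to test
#' @return symmetric matrix of two-sided p-values (diagonal `NA`)
#' @export
pairwise_fisher <- function(counts, column = "n_p_lt_0.01") {
  g <- counts$group
  M <- matrix(NA_real_, length(g), length(g), dimnames = list(g, g))
  for (i in seq_along(g)) for (j in seq_along(g)) {
    if (i >= j) next
    M[i, j] <- M[j, i] <- fisher_excess(
      counts[[column]][i], counts$n_cores[i],
      counts[[column]][j], counts$n_cores[j])
  }
  M
}

#' Observed vs expected -log10 p-values for a Q-Q plot
#'
#' @param p empirical p-values in `(0, 1]`
#' @return data.frame sorted from most significant: `observed` =
#'   `-log10(p)` descending, `expected` = `-log10((i - 0.5) / n)`
#' @export
qq_data <- function(p) {
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  n <- length(p)
  data.frame(observed = sort(-log10(p), decreasing = TRUE),
             expected = -log10((seq_len(n) - 0.5) / n))
}
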