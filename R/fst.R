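# Weir-Cockerham F_ST on haploid (chromosome-level) samples.
#
# Inputs are phased haplotypes, so the estimator is the haploid
# variance-component form: a one-way ANOVA of the 0/1 allele indicator on
# population, with no within-individual component. Per-SNP estimates are
# clamped at zero; sites monomorphic across the compared samples are
# undefined and skipped by window means.

#' Haploid Weir-Cockerham theta for one SNP
#'
#' @param n per-population haplotype sample sizes (length >= 2, each >= 2)
#' @param x per-population derived-allele counts
#' @return the clamped estimate in `[0, 1]`, or `NA` if the site is
#'   monomorphic across the populations compared
#' @examples
#' wc_theta(c(20, 20), c(20, 0))   # fixed difference -> 1
#' wc_theta(c(20, 20), c(10, 2))   # ~0.284
#' @export
wc_theta <- function(n, x) {
  if (length(n) < 2) stop("need at least 2 populations")
  if (any(n < 2)) stop("each population needs at least 2 haplotypes")
  if (length(x) != length(n) || any(x < 0) || any(x > n))
    stop("invalid allele counts")
  theta_from_counts(matrix(x, ncol = 1), n)[1]
}

# vectorised estimator: counts is an r x m matrix of derived-allele counts,
# sizes the length-r haplotype sample sizes (constant across SNPs)
theta_from_counts <- function(counts, sizes) {
  r <- length(sizes)
  N <- sum(sizes)
  pbar <- colSums(counts) / N
  p <- counts / sizes
  dev2 <- (p - rep(pbar, each = r))^2
  MSB <- colSums(sizes * dev2) / (r - 1)
  MSW <- colSums(sizes * p * (1 - p)) / (N - r)
  n_c <- (N - sum(sizes^2) / N) / (r - 1)
  den <- MSB + (n_c - 1) * MSW
  theta <- (MSB - MSW) / den
  theta[pbar <= 0 | pbar >= 1 | den == 0] <- NA_real_
  pmin(pmax(theta, 0), 1)
}

# per-unit haplotype counts: rows of `panel` partitioned by group or
# population label; returns sizes and an r x m count matrix
unit_counts <- function(panel, labels, by = c("group", "population"),
                        snps = NULL) {
  by <- match.arg(by)
  lab <- if (by == "group") row_group(panel) else row_population(panel)
  if (is.null(snps)) snps <- seq_len(ncol(panel$alleles))
  counts <- matrix(0L, length(labels), length(snps))
  sizes <- integer(length(labels))
  for (i in seq_along(labels)) {
    rows <- which(lab == labels[i])
    if (length(rows) < 2) stop("unit '", labels[i], "' has < 2 haplotypes")
    sizes[i] <- length(rows)
    counts[i, ] <- colSums(panel$alleles[rows, snps, drop = FALSE])
  }
  list(sizes = sizes, counts = counts)
}

#' Per-SNP F_ST across groups or populations
#'
#' With `pair = NULL` all units (all groups, or all populations) enter one
#' multi-sample estimate per SNP — the "global" F_ST. With a pair, the two
#' units are compared. Group-level comparisons pool all haplotypes of a
#' group's populations into one sample.
#'
#' @param panel a `haplotype_panel`
#' @param pair character vector of two unit labels, or `NULL` for all units
#' @param by `"group"` or `"population"`
#' @param snps optional SNP column indices to restrict to
#' @return numeric vector of clamped theta estimates (`NA` = undefined)
#' @export
fst_snp <- function(panel, pair = NULL, by = c("group", "population"),
                    snps = NULL) {
  by <- match.arg(by)
  lab <- if (by == "group") row_group(panel) else row_population(panel)
  units <- if (is.null(pair)) unique(lab) else as.character(pair)
  if (length(units) < 2) stop("need at least 2 units to compare")
  uc <- unit_counts(panel, units, by = by, snps = snps)
  theta_from_counts(uc$counts, uc$sizes)
}

# SNP indices inside the closed window [center - hw, center + hw]
window_snps <- function(panel, chrom, center, half_width,
                        unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  pos <- if (unit == "bp") panel$snps$pos_bp else panel$snps$pos_cM
  which(panel$snps$chrom == chrom & abs(pos - center) <= half_width)
}

#' Mean F_ST over a window
#'
#' Arithmetic mean of the per-SNP clamped estimates over the SNPs falling in
#' the closed interval `[center - half_width, center + half_width]`,
#' skipping undefined (monomorphic) sites. A window with no defined SNP is
#' flagged empty (`mean = NA`) and must be excluded from null sets.
#'
#' @inheritParams fst_snp
#' @param chrom chromosome label
#' @param center,half_width window center and half-width in `unit`
#' @param unit `"bp"` or `"cM"`
#' @param theta optional precomputed per-SNP theta vector (whole panel) to
#'   avoid recomputation across many windows
#' @return list with `mean`, `n_snps` (defined SNPs used), `empty`
#' @export
window_mean_fst <- function(panel, pair = NULL, chrom, center, half_width,
                            unit = c("bp", "cM"),
                            by = c("group", "population"), theta = NULL) {
  unit <- match.arg(unit)
  by <- match.arg(by)
  idx <- window_snps(panel, chrom, center, half_width, unit)
  if (is.null(theta)) {
    th <- if (length(idx)) fst_snp(panel, pair, by = by, snps = idx)
          else numeric(0)
  } else th <- theta[idx]
  th <- th[!is.na(th)]
  if (length(th) == 0L)
    return(list(mean = NA_real_, n_snps = 0L, empty = TRUE))
  list(mean = mean(th), n_snps = length(th), empty = FALSE)
}

#' Expanding-window F_ST scan around a focal SNP
#'
#' Window sizes default to the doubling series 50 kb to 1.6 Mb (total
#' widths), each centered on the focal SNP. A genetic-distance analogue is
#' obtained with `unit = "cM"` and sizes in cM.
#'
#' @inheritParams window_mean_fst
#' @param focal_snp SNP id or column index
#' @param sizes full window widths (bp, or cM when `unit = "cM"`)
#' @return data.frame with `size`, `mean_fst`, `n_snps`
#' @export
expanding_scan <- function(panel, pair = NULL, focal_snp,
                           sizes = c(50, 100, 200, 400, 800, 1600) * 1e3,
                           unit = c("bp", "cM"),
                           by = c("group", "population")) {
  unit <- match.arg(unit)
  by <- match.arg(by)
  fi <- if (is.character(focal_snp)) focal_index(panel, focal_snp)
        else as.integer(focal_snp)
  chrom <- panel$snps$chrom[fi]
  center <- if (unit == "bp") panel$snps$pos_bp[fi] else panel$snps$pos_cM[fi]
  theta <- fst_snp(panel, pair, by = by)
  res <- lapply(sizes, function(s)
    window_mean_fst(panel, pair, chrom, center, s / 2, unit, by,
                    theta = theta))
  data.frame(size = sizes,
             mean_fst = vapply(res, `[[`, 0, "mean"),
             n_snps = vapply(res, `[[`, 0L, "n_snps"))
}
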