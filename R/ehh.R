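# Haplotype-homozygosity scan: core haplotypes from LD blocks, extended
# haplotype homozygosity (EHH) and relative EHH (REHH), empirical p-values
# binned by core frequency.
#
# EHH of a core at distance d is the probability that two randomly chosen
# carrier chromosomes are identical over the interval from the core edge to
# the SNP nearest d (inclusive); REHH divides by the EHH of all other cores
# of the same block pooled, correcting for local recombination rate.

#' Two-locus LD statistics with a D' confidence interval
#'
#' D' and r^2 from phased haplotype counts; the 95% CI for |D'| is the set
#' of values whose multinomial profile log-likelihood (marginal allele
#' frequencies held at their MLEs) lies within 1.92 of the maximum.
#'
#' @param hap_a,hap_b 0/1 allele vectors over the same chromosomes
#' @return list with `d_prime`, `r2`, `ci_low`, `ci_high`
#' @export
ld_pair <- function(hap_a, hap_b) {
  pA <- mean(hap_a); pB <- mean(hap_b)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) stop("monomorphic site")
  n11 <- sum(hap_a == 1 & hap_b == 1)
  n10 <- sum(hap_a == 1 & hap_b == 0)
  n01 <- sum(hap_a == 0 & hap_b == 1)
  n00 <- sum(hap_a == 0 & hap_b == 0)
  D <- n11 / length(hap_a) - pA * pB
  s <- if (D >= 0) 1 else -1
  Dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  d_prime <- if (Dmax == 0) 0 else abs(D) / Dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  # profile log-likelihood over |D'| on a grid
  grid <- seq(0, 1, by = 0.001)
  Dg <- s * grid * Dmax
  h11 <- pmax(pA * pB + Dg, 1e-12)
  h10 <- pmax(pA * (1 - pB) - Dg, 1e-12)
  h01 <- pmax((1 - pA) * pB - Dg, 1e-12)
  h00 <- pmax((1 - pA) * (1 - pB) + Dg, 1e-12)
  ll <- n11 * log(h11) + n10 * log(h10) + n01 * log(h01) + n00 * log(h00)
  keep <- ll >= max(ll) - 1.92
  list(d_prime = d_prime, r2 = r2,
       ci_low = min(grid[keep]), ci_high = max(grid[keep]))
}

# classify a pair: 1 = strong LD, -1 = strong recombination, 0 = neither
classify_pair <- function(ci, thresholds) {
  if (ci$ci_low >= thresholds$ci_low && ci$ci_high >= thresholds$ci_high)
    return(1L)
  if (ci$ci_high < thresholds$recomb_high) return(-1L)
  0L
}

# fast equivalent of classify_pair(ld_pair(...)): the profile log-likelihood
# is concave in D', so the 1.92-drop set is an interval containing the
# observed D'; CI-bound comparisons against the three thresholds reduce to
# log-likelihood evaluations at those thresholds only.
classify_counts <- function(n11, n10, n01, n00, thresholds) {
  n <- n11 + n10 + n01 + n00
  pA <- (n11 + n10) / n; pB <- (n11 + n01) / n
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(0L)
  D <- n11 / n - pA * pB
  s <- if (D >= 0) 1 else -1
  Dmax <- if (s > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (Dmax == 0) return(0L)
  dhat <- abs(D) / Dmax
  ll_at <- function(dp) {
    Dg <- s * dp * Dmax
    n11 * log(max(pA * pB + Dg, 1e-12)) +
      n10 * log(max(pA * (1 - pB) - Dg, 1e-12)) +
      n01 * log(max((1 - pA) * pB - Dg, 1e-12)) +
      n00 * log(max((1 - pA) * (1 - pB) + Dg, 1e-12))
  }
  cut <- ll_at(dhat) - 1.92
  # CI bounds come from the 0.001 grid of ld_pair(): lo >= t iff no grid
  # point below t clears the cut; hi >= t iff dhat or ll(t) clears it
  lo_ge <- dhat >= thresholds$ci_low &&
    ll_at(max(thresholds$ci_low - 0.001, 0)) < cut
  hi_ge <- dhat >= thresholds$ci_high || ll_at(thresholds$ci_high) >= cut
  if (lo_ge && hi_ge) return(1L)
  hi_lt_rec <- dhat < thresholds$recomb_high &&
    ll_at(thresholds$recomb_high) < cut
  if (hi_lt_rec) return(-1L)
  0L
}

# fast per-row haplotype keys (column-wise paste0 beats row-wise apply)
hap_keys <- function(mat) {
  if (ncol(mat) == 0L) return(rep("", nrow(mat)))
  do.call(paste0, lapply(seq_len(ncol(mat)), function(j) mat[, j]))
}

#' Haplotype blocks by the D'-confidence-interval definition
#'
#' Markers with minor allele frequency below `maf_min` are ignored. A pair
#' is in strong LD when its D' CI is `[>= 0.70, >= 0.98]` and shows strong
#' recombination when the CI upper bound is `< 0.90`. Maximal
#' non-overlapping marker intervals in which at least 95% of informative
#' pairs are strong-LD become blocks; markers outside any block are
#' single-SNP cores. Pairs farther apart than `max_span_snps` markers are
#' not evaluated (treated as uninformative).
#'
#' @param panel a `haplotype_panel`
#' @param chrom chromosome label
#' @param rows haplotype row indices to use (default: all rows)
#' @param start,end optional bp bounds of the region scanned
#' @param maf_min marker minor-allele-frequency floor
#' @param max_span_snps maximum marker separation at which pairs are tested
#' @param thresholds list with `ci_low`, `ci_high`, `recomb_high`, `prop`
#' @return list of integer vectors of panel SNP column indices, ordered
#'   along the chromosome (length-1 vectors are singleton cores)
#' @export
gabriel_blocks <- function(panel, chrom, rows = NULL, start = NULL,
                           end = NULL, maf_min = 0.05, max_span_snps = 25,
                           thresholds = list(ci_low = 0.70, ci_high = 0.98,
                                             recomb_high = 0.90,
                                             prop = 0.95)) {
  if (is.null(rows)) rows <- seq_len(nrow(panel$alleles))
  sel <- panel$snps$chrom == chrom
  if (!is.null(start)) sel <- sel & panel$snps$pos_bp >= start
  if (!is.null(end)) sel <- sel & panel$snps$pos_bp <= end
  idx <- which(sel)
  if (length(idx) == 0L) stop("empty region")
  H <- panel$alleles[rows, idx, drop = FALSE]
  freq <- colMeans(H)
  markers <- which(pmin(freq, 1 - freq) >= maf_min)
  M <- length(markers)
  if (M == 0L) return(list())
  if (M == 1L) return(list(idx[markers]))
  # pairwise classes within the span limit; pair haplotype counts from one
  # cross-product of the marker matrix
  X <- H[, markers, drop = FALSE]
  storage.mode(X) <- "double"
  n_chr <- nrow(X)
  X11 <- crossprod(X)
  ones <- colSums(X)
  cls <- matrix(0L, M, M)
  for (a in seq_len(M - 1L)) {
    for (b in (a + 1L):min(M, a + max_span_snps)) {
      n11 <- X11[a, b]
      n10 <- ones[a] - n11
      n01 <- ones[b] - n11
      cls[a, b] <- classify_counts(n11, n10, n01,
                                   n_chr - n11 - n10 - n01, thresholds)
    }
  }
  # eligible intervals: >= prop of informative pairs strong-LD
  cand <- list()
  for (a in seq_len(M - 1L)) {
    n_ld <- 0L; n_rec <- 0L
    for (b in (a + 1L):min(M, a + max_span_snps)) {
      newc <- cls[a:(b - 1L), b]
      n_ld <- n_ld + sum(newc == 1L)
      n_rec <- n_rec + sum(newc == -1L)
      inf <- n_ld + n_rec
      if (inf > 0L && n_ld / inf >= thresholds$prop)
        cand[[length(cand) + 1L]] <- c(a, b)
    }
  }
  in_block <- rep(FALSE, M)
  blocks <- list()
  if (length(cand)) {
    cm <- do.call(rbind, cand)
    ord <- order(-(cm[, 2] - cm[, 1]), cm[, 1])   # longest first, leftmost
    for (k in ord) {
      a <- cm[k, 1]; b <- cm[k, 2]
      if (any(in_block[a:b])) next
      in_block[a:b] <- TRUE
      blocks[[length(blocks) + 1L]] <- idx[markers[a:b]]
    }
  }
  for (m in which(!in_block))
    blocks[[length(blocks) + 1L]] <- idx[markers[m]]
  blocks[order(vapply(blocks, min, 0L))]
}

#' Core haplotypes of a block
#'
#' The distinct allele strings over the block's SNPs partition the
#' chromosomes considered; each string with its carrier set and frequency
#' is one core.
#'
#' @param panel a `haplotype_panel`
#' @param block integer vector of SNP column indices
#' @param rows haplotype row indices considered (default: all)
#' @return data.frame `core`, `count`, `freq`, plus a list-column `carriers`
#'   of row indices
#' @export
core_haplotypes <- function(panel, block, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(nrow(panel$alleles))
  key <- hap_keys(panel$alleles[rows, block, drop = FALSE])
  tab <- sort(table(key), decreasing = TRUE)
  out <- data.frame(core = names(tab), count = as.integer(tab),
                    freq = as.integer(tab) / length(rows),
                    stringsAsFactors = FALSE)
  out$carriers <- lapply(out$core, function(cs) rows[key == cs])
  out
}

# columns extending from the block edge in `direction` out to the SNP whose
# distance from the edge is nearest `distance` (inclusive); empty when the
# target distance is 0 or no SNP lies in that direction
extension_cols <- function(panel, block, direction, distance,
                           unit = c("bp", "cM")) {
  unit <- match.arg(unit)
  chrom <- panel$snps$chrom[block[1]]
  pos <- if (unit == "bp") panel$snps$pos_bp else panel$snps$pos_cM
  on_ch <- which(panel$snps$chrom == chrom)
  if (direction == "upstream") {
    edge <- min(pos[block])
    cand <- on_ch[pos[on_ch] < edge]
    d <- edge - pos[cand]
  } else {
    edge <- max(pos[block])
    cand <- on_ch[pos[on_ch] > edge]
    d <- pos[cand] - edge
  }
  if (distance <= 0 || length(cand) == 0L) return(integer(0))
  o <- order(d)
  cand <- cand[o]; d <- d[o]
  horizon <- which.min(abs(d - distance))
  cand[seq_len(horizon)]
}

# pair-match homozygosity of a grouping: sum C(c_j, 2) / C(n, 2)
pair_homozygosity <- function(group_sizes, n) {
  if (n < 2) return(NA_real_)
  sum(choose(group_sizes, 2)) / choose(n, 2)
}

#' Extended haplotype homozygosity of a core
#'
#' @param panel a `haplotype_panel`
#' @param block SNP column indices of the core's block
#' @param carriers haplotype row indices carrying the core
#' @param direction `"upstream"` or `"downstream"`
#' @param distance target distance from the proximal block edge
#' @param unit `"bp"` (default) or `"cM"`
#' @return EHH in `[0, 1]`; 1 at distance 0
#' @export
ehh <- function(panel, block, carriers, direction = c("upstream",
                "downstream"), distance, unit = "bp") {
  direction <- match.arg(direction)
  if (length(carriers) < 2) stop("need >= 2 carrier chromosomes")
  ext <- extension_cols(panel, block, direction, distance, unit)
  if (length(ext) == 0L) return(1)
  key <- hap_keys(panel$alleles[carriers, ext, drop = FALSE])
  pair_homozygosity(as.integer(table(key)), length(carriers))
}

#' Relative EHH of a core against the pooled other cores of its block
#'
#' The pooled-others EHH groups the non-carrier chromosomes by identity of
#' their core-plus-extension haplotype (chromosomes with different cores
#' are never identical). `NA` when the denominator is zero.
#'
#' @inheritParams ehh
#' @param others haplotype row indices of the block's other chromosomes
#' @export
rehh <- function(panel, block, carriers, others, direction = c("upstream",
                 "downstream"), distance, unit = "bp") {
  direction <- match.arg(direction)
  if (length(others) < 2) stop("pooled others need >= 2 chromosomes")
  e_core <- ehh(panel, block, carriers, direction, distance, unit)
  ext <- extension_cols(panel, block, direction, distance, unit)
  cols <- c(block, ext)
  key <- hap_keys(panel$alleles[others, cols, drop = FALSE])
  e_other <- pair_homozygosity(as.integer(table(key)), length(others))
  if (is.na(e_other) || e_other == 0) return(NA_real_)
  e_core / e_other
}

#' REHH scan over a region within one population group
#'
#' Builds haplotype blocks among the chromosomes of `label`, forms core
#' haplotypes, and records EHH and REHH for each core with frequency above
#' `min_core_freq` in both directions at the given distance. With
#' `start`/`end` `NULL`, the whole chromosome is scanned — the usual way to
#' build the chromosome-wide empirical REHH distribution.
#'
#' @param panel a `haplotype_panel`
#' @param label group (or population) whose chromosomes are scanned
#' @param chrom chromosome label
#' @param by `"group"` or `"population"`
#' @param start,end optional region bounds (bp) for the cores
#' @param distance REHH test distance from the core edge (default 300 kb)
#' @param unit `"bp"` or `"cM"`
#' @param min_core_freq cores at or below this frequency are skipped
#' @param maf_min,max_span_snps,thresholds passed to [gabriel_blocks()]
#' @return data.frame, one row per core x direction: `block`, `block_start`,
#'   `block_end`, `core`, `freq`, `n_carriers`, `direction`, `distance`,
#'   `ehh`, `rehh`
#' @export
rehh_scan <- function(panel, label, chrom, by = "group", start = NULL,
                      end = NULL, distance = 3e5, unit = "bp",
                      min_core_freq = 0.05, maf_min = 0.05,
                      max_span_snps = 25,
                      thresholds = list(ci_low = 0.70, ci_high = 0.98,
                                        recomb_high = 0.90, prop = 0.95)) {
  rows <- panel_rows(panel, label, by = by)
  if (length(rows) < 4) stop("too few chromosomes in '", label, "'")
  blocks <- gabriel_blocks(panel, chrom, rows = rows, start = start,
                           end = end, maf_min = maf_min,
                           max_span_snps = max_span_snps,
                           thresholds = thresholds)
  o_block <- integer(0); o_bs <- numeric(0); o_be <- numeric(0)
  o_core <- character(0); o_freq <- numeric(0); o_nc <- integer(0)
  o_dir <- character(0); o_ehh <- numeric(0); o_rehh <- numeric(0)
  n_rows <- length(rows)
  for (bi in seq_along(blocks)) {
    blk <- blocks[[bi]]
    core_key <- hap_keys(panel$alleles[rows, blk, drop = FALSE])
    core_tab <- table(core_key)
    if (length(core_tab) < 2) next                # single-core block: no REHH
    use <- names(core_tab)[core_tab / n_rows > min_core_freq & core_tab >= 2]
    if (length(use) == 0L) next
    bs <- min(panel$snps$pos_bp[blk]); be <- max(panel$snps$pos_bp[blk])
    for (dir in c("upstream", "downstream")) {
      ext <- extension_cols(panel, blk, dir, distance, unit)
      full_key <- if (length(ext))
        paste0(core_key, hap_keys(panel$alleles[rows, ext, drop = FALSE]))
        else core_key
      # counts of each (core, full haplotype) combination
      grp <- table(full_key)
      grp_core <- substr(names(grp), 1, nchar(core_key[1]))
      for (cs in use) {
        n_car <- as.integer(core_tab[[cs]])
        own <- as.integer(grp[grp_core == cs])
        e_core <- pair_homozygosity(own, n_car)
        oth <- as.integer(grp[grp_core != cs])
        n_oth <- n_rows - n_car
        e_oth <- pair_homozygosity(oth, n_oth)
        rh <- if (is.na(e_oth) || e_oth == 0) NA_real_ else e_core / e_oth
        o_block <- c(o_block, bi); o_bs <- c(o_bs, bs); o_be <- c(o_be, be)
        o_core <- c(o_core, cs); o_freq <- c(o_freq, n_car / n_rows)
        o_nc <- c(o_nc, n_car); o_dir <- c(o_dir, dir)
        o_ehh <- c(o_ehh, e_core); o_rehh <- c(o_rehh, rh)
      }
    }
  }
  out <- data.frame(block = o_block, block_start = o_bs, block_end = o_be,
                    core = o_core, freq = o_freq, n_carriers = o_nc,
                    direction = o_dir, distance = if (length(o_block)) distance
                    else numeric(0), ehh = o_ehh, rehh = o_rehh,
                    stringsAsFactors = FALSE)
  attr(out, "blocks") <- blocks
  out
}

#' Scan records of the core carrying a given allele at a focal SNP
#'
#' Selects, from a [rehh_scan()] result, the records of the block containing
#' the focal SNP whose core string carries `allele` at that SNP — e.g. the
#' spiked core after [spike_sweep()], or a risk-allele core.
#'
#' @param records a [rehh_scan()] result (its `"blocks"` attribute intact)
#' @param focal_index panel SNP column index of the focal SNP
#' @param allele allele (0/1) the core must carry at the focal SNP
#' @return the matching record rows (possibly zero rows if the focal SNP is
#'   in no multi-core block)
#' @export
focal_core_records <- function(records, focal_index, allele) {
  blocks <- attr(records, "blocks")
  if (is.null(blocks)) stop("records lack the 'blocks' attribute")
  bi <- which(vapply(blocks, function(b) focal_index %in% b, logical(1)))
  if (length(bi) == 0L) return(records[0, , drop = FALSE])
  pos <- match(focal_index, blocks[[bi]])
  sel <- records$block == bi &
    substr(records$core, pos, pos) == as.character(allele)
  records[sel, , drop = FALSE]
}

# frequency bin index over (0.05, 1] in steps of bin_width
freq_bin <- function(freq, bin_width = 0.05) {
  b <- ceiling((freq - 0.05) / bin_width - 1e-9)
  pmax(b, 1L)
}

#' Frequency-binned empirical REHH p-values
#'
#' Each record's REHH is ranked within its core-frequency bin (width 0.05
#' over (0.05, 1]) of the chromosome-wide records:
#' `p = (1 + #\{bin REHH >= query\}) / (n_bin + 1)`, the query itself
#' excluded from its null set. Bins holding fewer than `min_bin` records
#' are widened symmetrically to adjacent bins and flagged.
#'
#' @param records chromosome-wide scan records ([rehh_scan()] output)
#' @param queries records to score (default: all of `records`); rows are
#'   matched to `records` by all of block, core, direction to decide
#'   self-exclusion
#' @param bin_width frequency bin width
#' @param min_bin minimum bin occupancy before widening
#' @return `queries` with added columns `bin`, `n_bin`, `widened`, `p`
#' @export
rehh_empirical_p <- function(records, queries = NULL, bin_width = 0.05,
                             min_bin = 20) {
  pool <- records[!is.na(records$rehh), , drop = FALSE]
  if (nrow(pool) == 0L) stop("no defined REHH records")
  pool$bin <- freq_bin(pool$freq, bin_width)
  self_id <- function(df) paste(df$block, df$core, df$direction, sep = "|")
  pool_id <- self_id(pool)
  if (is.null(queries)) queries <- records
  q <- queries[!is.na(queries$rehh), , drop = FALSE]
  q$bin <- freq_bin(q$freq, bin_width)
  q_id <- self_id(q)
  q$n_bin <- NA_integer_; q$widened <- FALSE; q$p <- NA_real_
  for (i in seq_len(nrow(q))) {
    w <- 0L
    repeat {
      inb <- abs(pool$bin - q$bin[i]) <= w & pool_id != q_id[i]
      if (sum(inb) >= min_bin || w >= 19L) break
      w <- w + 1L
    }
    nulls <- pool$rehh[inb]
    q$n_bin[i] <- length(nulls)
    q$widened[i] <- w > 0L
    if (length(nulls) > 0L)
      q$p[i] <- (1 + sum(nulls >= q$rehh[i])) / (length(nulls) + 1)
  }
  q
}
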