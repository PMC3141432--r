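#' Genetic map with piecewise-linear interpolation
#'
#' Anchors physical positions (bp) to genetic positions (cM) per chromosome.
#' Queries between anchors are linearly interpolated; queries outside the
#' anchor range clamp to the terminal anchor value (slope 0 beyond the map).
#'
#' @param chrom chromosome label per anchor
#' @param pos_bp anchor physical positions (1-based)
#' @param cM anchor genetic positions, non-decreasing in bp per chromosome
#' @return object of class `genetic_map`
#' @export
genetic_map <- function(chrom, pos_bp, cM) {
  df <- data.frame(chrom = as.character(chrom), pos_bp = pos_bp, cM = cM,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos_bp), ]
  for (ch in unique(df$chrom)) {
    v <- df$cM[df$chrom == ch]
    if (any(diff(v) < 0)) stop("cM decreasing in bp on chromosome ", ch)
  }
  class(df) <- c("genetic_map", "data.frame")
  df
}

#' Read a genetic map from TSV (columns chrom, pos_bp, cM, with header)
#' @param file path
#' @export
read_genetic_map <- function(file) {
  m <- utils::read.table(file, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  genetic_map(m[[1]], m[[2]], m[[3]])
}

#' Interpolate genetic position at physical positions
#'
#' @param map a `genetic_map`
#' @param chrom chromosome label (scalar)
#' @param pos_bp physical positions to query
#' @return cM values, monotone non-decreasing in `pos_bp`
#' @export
interpolate_cM <- function(map, chrom, pos_bp) {
  sub <- map[map$chrom == as.character(chrom), , drop = FALSE]
  if (nrow(sub) == 0L) stop("unknown chromosome in genetic map: ", chrom)
  if (nrow(sub) == 1L) return(rep(sub$cM, length(pos_bp)))
  stats::approx(sub$pos_bp, sub$cM, xout = pos_bp, rule = 2, ties = "ordered")$y
}

#' Fill a panel's cM positions from a genetic map
#' @param panel a `haplotype_panel`
#' @param map a `genetic_map`
#' @export
add_map_positions <- function(panel, map) {
  for (ch in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == ch)
    panel$snps$pos_cM[idx] <- interpolate_cM(map, ch, panel$snps$pos_bp[idx])
  }
  panel
}
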