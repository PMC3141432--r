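#' Phased haplotype panel
#'
#' The central container of the package: a phased biallelic 0/1 allele matrix
#' with one row per chromosome copy (two per diploid individual) and one
#' column per SNP, together with per-SNP physical (bp) and genetic (cM)
#' positions, an optional genic annotation, and a sample -> population ->
#' group hierarchy. All scan statistics operate on this object.
#'
#' @param alleles integer/numeric matrix of 0/1 calls, one row per chromosome
#'   copy, one column per SNP. Rows `2k - 1` and `2k` belong to individual `k`.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos_bp`, `pos_cM`
#'   and optionally `genic` (logical). Positions must be 1-based and strictly
#'   increasing in bp within each chromosome.
#' @param samples data.frame with columns `sample_id`, `population`, `group`,
#'   one row per diploid individual, in panel row order.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(alleles, snps, samples) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (!all(alleles %in% c(0L, 1L)))
    stop("allele matrix must contain only 0/1 (no missingness supported)")
  if (nrow(alleles) %% 2L != 0L)
    stop("odd haplotype row count: need two chromosome copies per individual")
  if (nrow(alleles) != 2L * nrow(samples))
    stop("row count must equal 2 x individual count")
  need <- c("snp_id", "chrom", "pos_bp", "pos_cM")
  if (!all(need %in% names(snps)))
    stop("snps must have columns ", paste(need, collapse = ", "))
  if (is.null(snps$genic)) snps$genic <- NA
  snps$genic <- as.logical(snps$genic)
  if (ncol(alleles) != nrow(snps))
    stop("one snps row per allele column required")
  for (ch in unique(snps$chrom)) {
    pb <- snps$pos_bp[snps$chrom == ch]
    if (any(diff(pb) <= 0))
      stop("pos_bp not strictly increasing on chromosome ", ch)
    pc <- snps$pos_cM[snps$chrom == ch]
    if (!anyNA(pc) && any(diff(pc) < 0))
      stop("pos_cM decreasing on chromosome ", ch)
  }
  if (anyDuplicated(samples$sample_id))
    stop("duplicated sample_id")
  pg <- unique(samples[, c("population", "group")])
  if (anyDuplicated(pg$population))
    stop("a population maps to more than one group")
  obj <- list(
    alleles = alleles,
    snps = as.data.frame(snps, stringsAsFactors = FALSE),
    samples = as.data.frame(samples, stringsAsFactors = FALSE)
  )
  class(obj) <- "haplotype_panel"
  obj
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "haplotype_panel: %d haplotypes (%d individuals), %d SNPs, %d populations in %d groups\n",
    nrow(x$alleles), nrow(x$samples), ncol(x$alleles),
    length(unique(x$samples$population)), length(unique(x$samples$group))))
  invisible(x)
}

#' @rdname haplotype_panel
#' @param panel a `haplotype_panel`
#' @export
n_haplotypes <- function(panel) nrow(panel$alleles)

#' @rdname haplotype_panel
#' @export
n_snps <- function(panel) ncol(panel$alleles)

# population / group label per haplotype row
row_population <- function(panel) {
  rep(panel$samples$population, each = 2L)
}
row_group <- function(panel) {
  rep(panel$samples$group, each = 2L)
}

#' Rows of the allele matrix belonging to a population or group
#'
#' @param panel a `haplotype_panel`
#' @param label population or group label (or vector of labels)
#' @param by `"group"` or `"population"`
#' @return integer vector of haplotype row indices
#' @export
panel_rows <- function(panel, label, by = c("group", "population")) {
  by <- match.arg(by)
  lab <- if (by == "group") row_group(panel) else row_population(panel)
  which(lab %in% label)
}

#' Subset a panel by individuals and/or SNPs
#'
#' @param panel a `haplotype_panel`
#' @param individuals indices into `panel$samples`
#' @param snps indices into SNP columns
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  if (is.null(individuals)) individuals <- seq_len(nrow(panel$samples))
  if (is.null(snps)) snps <- seq_len(ncol(panel$alleles))
  rows <- as.vector(rbind(2L * individuals - 1L, 2L * individuals))
  haplotype_panel(panel$alleles[rows, snps, drop = FALSE],
                  panel$snps[snps, , drop = FALSE],
                  panel$samples[individuals, , drop = FALSE])
}

#' Read a phased panel from the tabular haplotype dialect
#'
#' The dialect is plain TSV: metadata lines beginning with `#` give, in
#' order, `#snp_id`, `#chrom`, `#pos_bp`, `#pos_cM` and optionally `#genic`
#' (0/1); every following line is one chromosome copy: a sample id followed
#' by 0/1 calls. The two copies of an individual are consecutive lines.
#'
#' @param haplotype_file path to the haplotype table
#' @param sample_map_file path to a TSV with header
#'   `sample<TAB>population<TAB>group`
#' @return a `haplotype_panel`
#' @export
read_panel <- function(haplotype_file, sample_map_file) {
  lines <- readLines(haplotype_file)
  lines <- lines[nzchar(lines)]
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  parse_meta <- function(key) {
    row <- meta[startsWith(meta, paste0("#", key))]
    if (length(row) == 0L) return(NULL)
    strsplit(sub(paste0("^#", key, "\\s+"), "", row[1]), "\\s+")[[1]]
  }
  snp_id <- parse_meta("snp_id")
  if (is.null(snp_id)) stop("missing #snp_id metadata row")
  chrom <- parse_meta("chrom")
  pos_bp <- as.numeric(parse_meta("pos_bp"))
  pos_cM <- as.numeric(parse_meta("pos_cM"))
  genic <- parse_meta("genic")
  genic <- if (is.null(genic)) rep(NA, length(snp_id)) else genic == "1"
  fields <- strsplit(body, "\\s+")
  ids <- vapply(fields, `[[`, "", 1L)
  calls <- lapply(fields, function(f) {
    v <- suppressWarnings(as.integer(f[-1]))
    if (anyNA(v) || !all(v %in% 0:1)) stop("non-binary allele code in haplotype row")
    v
  })
  if (length(unique(lengths(calls))) != 1L ||
      lengths(calls)[1] != length(snp_id))
    stop("haplotype rows do not match SNP count")
  alleles <- do.call(rbind, calls)
  if (nrow(alleles) %% 2L != 0L) stop("odd haplotype row count")
  ind_ids <- ids[seq(1L, length(ids), by = 2L)]
  if (!all(ids[seq(2L, length(ids), by = 2L)] == ind_ids))
    stop("the two chromosome copies of an individual must be consecutive")
  smap <- utils::read.table(sample_map_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  names(smap)[1:3] <- c("sample_id", "population", "group")
  miss <- setdiff(ind_ids, smap$sample_id)
  if (length(miss))
    stop("unknown sample in haplotype file: ", paste(miss, collapse = ", "))
  samples <- smap[match(ind_ids, smap$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  haplotype_panel(
    alleles,
    data.frame(snp_id = snp_id, chrom = chrom, pos_bp = pos_bp,
               pos_cM = pos_cM, genic = genic, stringsAsFactors = FALSE),
    samples)
}

#' Write a panel in the tabular haplotype dialect
#'
#' Inverse of [read_panel()]; `read_panel(write_panel(p))` reproduces the
#' allele matrix and labels bit-exactly.
#'
#' @param panel a `haplotype_panel`
#' @param haplotype_file,sample_map_file output paths
#' @export
write_panel <- function(panel, haplotype_file, sample_map_file) {
  s <- panel$snps
  con <- file(haplotype_file, "w")
  on.exit(close(con))
  wl <- function(key, vals) writeLines(paste(c(key, vals), collapse = "\t"), con)
  wl("#snp_id", s$snp_id)
  wl("#chrom", s$chrom)
  wl("#pos_bp", format(s$pos_bp, scientific = FALSE, trim = TRUE))
  wl("#pos_cM", format(s$pos_cM, scientific = FALSE, trim = TRUE, digits = 12))
  if (!all(is.na(s$genic))) wl("#genic", as.integer(s$genic))
  ids <- rep(panel$samples$sample_id, each = 2L)
  for (i in seq_len(nrow(panel$alleles)))
    wl(ids[i], panel$alleles[i, ])
  utils::write.table(
    data.frame(sample = panel$samples$sample_id,
               population = panel$samples$population,
               group = panel$samples$group),
    sample_map_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(panel)
}

#' Read a phased panel from a VCF
#'
#' Requires phased genotypes (`|` separator); any unphased call is an error.
#' Uses VariantAnnotation for parsing. Genetic positions are initialised to
#' `NA` and can be filled from a [genetic_map()] via [add_map_positions()].
#'
#' @param vcf_file path to an (uncompressed or bgzipped) VCF
#' @param sample_map_file TSV sample -> population -> group
#' @return a `haplotype_panel`
#' @export
read_panel_vcf <- function(vcf_file, sample_map_file) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_panel_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(vcf_file)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype in VCF; only '|'-separated calls are supported")
  rr <- SummarizedExperiment::rowRanges(vcf)
  smap <- utils::read.table(sample_map_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  names(smap)[1:3] <- c("sample_id", "population", "group")
  samp <- colnames(gt)
  miss <- setdiff(samp, smap$sample_id)
  if (length(miss)) stop("unknown sample in VCF: ", paste(miss, collapse = ", "))
  # expand sample-major genotype strings into 2 haplotype rows per sample
  alleles <- matrix(0L, nrow = 2L * length(samp), ncol = nrow(gt))
  for (j in seq_along(samp)) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    a <- suppressWarnings(vapply(parts, function(p) as.integer(p), integer(2)))
    if (anyNA(a) || !all(a %in% 0:1))
      stop("non-biallelic or missing genotype in VCF")
    alleles[2L * j - 1L, ] <- a[1L, ]
    alleles[2L * j, ] <- a[2L, ]
  }
  snps <- data.frame(
    snp_id = names(rr),
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos_bp = GenomicRanges::start(rr),
    pos_cM = NA_real_,
    genic = NA,
    stringsAsFactors = FALSE)
  samples <- smap[match(samp, smap$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  haplotype_panel(alleles, snps, samples)
}

#' Attach a genic annotation from a BED file
#'
#' BED intervals are half-open zero-based `[start, end)`; a SNP at 1-based
#' position `p` is genic iff `start < p <= end` for some interval on its
#' chromosome.
#'
#' @param panel a `haplotype_panel`
#' @param bed_file path to a 3+ column BED file (no header)
#' @return the panel with `snps$genic` filled
#' @export
add_genic_track <- function(panel, bed_file) {
  bed <- utils::read.table(bed_file, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)[, 1:3]
  names(bed) <- c("chrom", "start", "end")
  g <- rep(FALSE, ncol(panel$alleles))
  for (ch in unique(panel$snps$chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    if (nrow(b) == 0L) next
    idx <- which(panel$snps$chrom == ch)
    p <- panel$snps$pos_bp[idx]
    hit <- vapply(p, function(x) any(b$start < x & x <= b$end), logical(1))
    g[idx] <- hit
  }
  panel$snps$genic <- g
  panel
}

#' Read a focal (risk) SNP list
#'
#' TSV with header `snp_id<TAB>chrom<TAB>pos_bp` and an optional `allele`
#' column carrying the protective/susceptibility allele code (0/1). Every
#' focal SNP must exist in the panel.
#'
#' @param file path
#' @param panel panel the SNPs must belong to
#' @export
read_focal_snps <- function(file, panel) {
  fs <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  miss <- setdiff(fs$snp_id, panel$snps$snp_id)
  if (length(miss))
    stop("focal SNP absent from panel: ", paste(miss, collapse = ", "))
  fs
}

# index of a focal SNP in the panel, with validation
focal_index <- function(panel, snp_id) {
  i <- match(snp_id, panel$snps$snp_id)
  if (is.na(i)) stop("focal SNP absent from panel: ", snp_id)
  i
}
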