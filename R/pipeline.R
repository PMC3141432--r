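# End-to-end orchestration: one configuration drives simulation/loading,
# the expanding and sliding F_ST percentile scans, the pairwise population
# matrix, GSF_ST summaries, the bootstrap test, the REHH scan with
# empirical p-values, and the enrichment tables. Every table carries the
# producing seed and a hash of the configuration.

# FNV-1a 32-bit hash of a string, as 8 hex digits. Kept in doubles; the
# xor touches only the low byte and the multiply is split into 16-bit
# halves so every intermediate stays exactly representable.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    h16 <- h %/% 65536
    l16 <- h %% 65536
    h <- (l16 * 16777619 + ((h16 * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run configuration for the full scan
#'
#' @param sim a [sim_config()] to simulate inputs, or `NULL` when reading
#'   files
#' @param haplotype_file,sample_map_file input paths (used when `sim` is
#'   `NULL`)
#' @param focal_snps character vector of focal SNP ids
#' @param expanding_sizes expanding-scan window widths (bp)
#' @param sliding_window,sliding_step,sliding_flank sliding-scan geometry:
#'   the region spans `sliding_flank` either side of the first focal SNP
#' @param n_null matched null windows per focal window
#' @param boot_groups length-3 character vector (A, B, C) for the bootstrap
#'   test; `NULL` skips it
#' @param boot_reps bootstrap replicates
#' @param rehh_distance REHH test distance (bp)
#' @param rehh_flank half-width of the REHH focal region around the focal SNP
#' @param thresholds enrichment p-value cutoffs
#' @param seed master seed
#' @param out_dir output directory for TSV/JSON artifacts
#' @export
run_config <- function(sim = NULL, haplotype_file = NULL,
                       sample_map_file = NULL, focal_snps,
                       expanding_sizes = c(50, 100, 200, 400, 800, 1600) * 1e3,
                       sliding_window = 4e5, sliding_step = 2e5,
                       sliding_flank = 1e6, n_null = 1000,
                       boot_groups = NULL, boot_reps = 1000,
                       rehh_distance = 3e5, rehh_flank = 2e5,
                       thresholds = c(0.001, 0.005, 0.01, 0.05),
                       seed = 1, out_dir = tempfile("sweepscan_run_")) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

write_tsv <- function(df, path, seed, cfg_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%d config=%s", seed, cfg_hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full selection scan
#'
#' Emits, under `config$out_dir`: `expanding_scan.tsv` (per focal SNP and
#' group pair), `sliding_scan.tsv`, `pairwise_matrix.tsv`, `gsfst.tsv`,
#' `bootstrap.json`, `rehh_records.tsv` (chromosome-wide, with empirical
#' p), `enrichment.tsv`, `fisher_pairs.tsv`, `qq.tsv` and `manifest.json`.
#' Re-running with the same config and seed reproduces the statistical
#' tables byte-identically.
#'
#' @param config a [run_config()]
#' @return (invisibly) a list with all result objects
#' @export
run_full_scan <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[["elapsed"]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_ser <- config
  cfg_ser$sim <- unclass(cfg_ser$sim)
  cfg_ser$out_dir <- NULL          # output location is not statistical state
  cfg_hash <- fnv1a(jsonlite::toJSON(unclass(cfg_ser), auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max, 6))

  panel <- stage("load", {
    if (!is.null(config$sim)) simulate_panel(config$sim)$panel
    else read_panel(config$haplotype_file, config$sample_map_file)
  })
  stage("validate", {
    miss <- setdiff(config$focal_snps, panel$snps$snp_id)
    if (length(miss))
      stop("focal SNP absent from panel: ", paste(miss, collapse = ", "))
  })
  groups <- unique(panel$samples$group)
  gpairs <- utils::combn(groups, 2)
  focal_idx <- match(config$focal_snps, panel$snps$snp_id)
  chrom <- panel$snps$chrom[focal_idx[1]]
  f_pos <- panel$snps$pos_bp[focal_idx[1]]

  res <- list(config_hash = cfg_hash)

  res$expanding <- stage("expanding_scan", {
    rows <- list()
    for (fi in seq_along(focal_idx)) for (k in seq_len(ncol(gpairs))) {
      es <- expanding_scan(panel, gpairs[, k], focal_idx[fi],
                           sizes = config$expanding_sizes)
      es$focal_snp <- config$focal_snps[fi]
      es$pair <- paste(gpairs[, k], collapse = "-")
      rows[[length(rows) + 1L]] <- es
    }
    do.call(rbind, rows)
  })
  write_tsv(res$expanding, file.path(config$out_dir, "expanding_scan.tsv"),
            config$seed, cfg_hash)

  res$sliding <- stage("sliding_scan", {
    rows <- list()
    sub_seeds <- with_seed(seeds[1],
                           sample.int(.Machine$integer.max, ncol(gpairs)))
    for (k in seq_len(ncol(gpairs))) {
      sl <- sliding_scan(panel, chrom, f_pos - config$sliding_flank,
                         f_pos + config$sliding_flank, gpairs[, k],
                         window = config$sliding_window,
                         step = config$sliding_step, n = config$n_null,
                         seed = sub_seeds[k])
      sl$pair <- paste(gpairs[, k], collapse = "-")
      rows[[length(rows) + 1L]] <- sl
    }
    do.call(rbind, rows)
  })
  write_tsv(res$sliding, file.path(config$out_dir, "sliding_scan.tsv"),
            config$seed, cfg_hash)

  res$matrix <- stage("pairwise_matrix", {
    pairwise_matrix(panel, chrom, f_pos, config$sliding_window / 2,
                    n_null = config$n_null, seed = seeds[2])
  })
  write_tsv(cbind(population = rownames(res$matrix),
                  as.data.frame(res$matrix)),
            file.path(config$out_dir, "pairwise_matrix.tsv"),
            config$seed, cfg_hash)

  res$gsfst <- stage("gsfst", {
    sub_seeds <- with_seed(seeds[3],
                           sample.int(.Machine$integer.max, ncol(gpairs)))
    pr <- vapply(seq_len(ncol(gpairs)), function(k)
      window_percentile(panel, chrom, f_pos, config$sliding_window / 2,
                        gpairs[, k], n = config$n_null,
                        seed = sub_seeds[k])$percentile, 0)
    data.frame(group = groups, gsfst = vapply(groups, function(g) {
      gsfst(pr[gpairs[1, ] == g | gpairs[2, ] == g], length(groups))
    }, 0))
  })
  write_tsv(res$gsfst, file.path(config$out_dir, "gsfst.tsv"),
            config$seed, cfg_hash)

  if (!is.null(config$boot_groups)) {
    res$bootstrap <- stage("bootstrap", {
      b <- bootstrap_fst_test(panel, chrom, f_pos,
                              config$sliding_window / 2,
                              config$boot_groups[1], config$boot_groups[2],
                              config$boot_groups[3], n_null = config$n_null,
                              B_reps = config$boot_reps, seed = seeds[4])
      b
    })
    jsonlite::write_json(
      list(T_obs = res$bootstrap$T_obs, sigma_hat = res$bootstrap$sigma_hat,
           p_conservative = res$bootstrap$p_conservative,
           p_asymptotic = res$bootstrap$p_asymptotic,
           B = res$bootstrap$B, seed = res$bootstrap$seed,
           redraws = res$bootstrap$redraws, config = cfg_hash),
      file.path(config$out_dir, "bootstrap.json"),
      auto_unbox = TRUE, digits = NA)
  }

  res$rehh <- stage("rehh_scan", {
    rows <- list()
    for (g in groups) {
      rec <- rehh_scan(panel, g, chrom, distance = config$rehh_distance)
      if (nrow(rec) == 0L) next
      rec <- rehh_empirical_p(rec)
      rec$group <- g
      rows[[length(rows) + 1L]] <- rec
    }
    do.call(rbind, rows)
  })
  write_tsv(res$rehh, file.path(config$out_dir, "rehh_records.tsv"),
            config$seed, cfg_hash)

  res$enrichment <- stage("enrichment", {
    reg <- res$rehh[res$rehh$block_start >= f_pos - config$rehh_flank &
                    res$rehh$block_end <= f_pos + config$rehh_flank, ,
                    drop = FALSE]
    count_extreme(reg, config$thresholds)
  })
  write_tsv(res$enrichment, file.path(config$out_dir, "enrichment.tsv"),
            config$seed, cfg_hash)
  res$fisher <- stage("fisher", {
    pairwise_fisher(res$enrichment)
  })
  write_tsv(cbind(group = rownames(res$fisher), as.data.frame(res$fisher)),
            file.path(config$out_dir, "fisher_pairs.tsv"),
            config$seed, cfg_hash)
  res$qq <- stage("qq", {
    do.call(rbind, lapply(groups, function(g) {
      p <- res$rehh$p[res$rehh$group == g & !is.na(res$rehh$p)]
      if (length(p) == 0L) return(NULL)
      cbind(group = g, qq_data(p))
    }))
  })
  write_tsv(res$qq, file.path(config$out_dir, "qq.tsv"),
            config$seed, cfg_hash)

  manifest <- list(
    package = "sweepscan",
    version = as.character(utils::packageVersion("sweepscan")),
    seed = config$seed, config_hash = cfg_hash,
    stage_seeds = seeds,
    n_haplotypes = n_haplotypes(panel), n_snps = n_snps(panel),
    groups = groups,
    runtime_s = round(proc.time()[["elapsed"]] - t0, 2))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
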