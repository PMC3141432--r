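Package: sweepscan
Title: Window-Based F_ST and Haplotype-Homozygosity Scans for Local Adaptation
Version: 0.1.0
Authors@R:
    person("HGDP", "Scan Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Selection-scan statistics for phased multi-population haplotype
    panels: per-SNP Weir-Cockerham F_ST on haploid (chromosome) samples,
    window means over physical- or genetic-distance windows, empirical
    percentile ranks against genic-content-matched random windows on the same
    chromosome, group-specific F_ST summaries, a bootstrap test of
    differential window differentiation between population pairs, extended
    haplotype homozygosity (EHH) and relative EHH (REHH) on LD-block core
    haplotypes with frequency-binned empirical p-values, and Fisher-exact
    enrichment of extreme REHH cores. Includes a Balding-Nichols synthetic
    panel generator with an optional spiked partial sweep so every stage can
    be exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
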