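---
title: "Window F_ST and haplotype-homozygosity selection scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Window F_ST and haplotype-homozygosity selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`sweepscan` asks, for a focal ("risk") SNP in a phased multi-population
haplotype panel, whether the surrounding genomic region shows unusual
population differentiation or unusually long shared haplotypes — the two
classic footprints of recent positive selection. Both statistics are judged
*empirically*: the focal window is ranked against random windows of the same
chromosome rather than against a parametric null, which absorbs genome-wide
demographic effects that equally shift every window.

The package provides five coupled analyses:

1. **Window F_ST percentiles.** Per-SNP Weir–Cockerham F_ST between two
   population groups, averaged over a window centered on the focal SNP, and
   ranked against 1000 random same-sized windows of the same chromosome
   matched on genic SNP content.
2. **GSF_ST.** For G groups, a group's window percentile ranks against each
   of the other G − 1 groups are averaged into one group-specific summary.
3. **A bootstrap test** of whether the focal window's F_ST *difference*
   between two pairs of groups exceeds the chromosomal background
   difference.
4. **EHH/REHH.** Core haplotypes defined by LD blocks; extended haplotype
   homozygosity measured at fixed distances; relative EHH ranked within
   core-frequency bins of the chromosome-wide empirical distribution.
5. **Enrichment.** Counts of extreme-REHH cores per group in a region, with
   pairwise two-sided Fisher exact tests and Q–Q diagnostics.

# Estimators and conventions

## Haploid Weir–Cockerham F_ST

Inputs are phased chromosomes, so the estimator is the haploid
variance-component form: a one-way ANOVA of the 0/1 allele indicator on
population. With r samples of sizes $n_i$, frequencies $\hat p_i$,
$N=\sum n_i$, $\bar p = \sum n_i \hat p_i / N$ and
$n_c = (N - \sum n_i^2/N)/(r-1)$:

$$\mathrm{MSB} = \frac{\sum_i n_i(\hat p_i - \bar p)^2}{r-1},\qquad
  \mathrm{MSW} = \frac{\sum_i n_i \hat p_i(1-\hat p_i)}{N-r},\qquad
  \hat\theta = \frac{\mathrm{MSB}-\mathrm{MSW}}
                    {\mathrm{MSB}+(n_c-1)\,\mathrm{MSW}}.$$

Negative estimates are clamped to zero **per SNP, before window
averaging** (biologically meaningless negatives are treated as zero at the
site level, and window means inherit the rule). Sites monomorphic across
the compared samples are undefined and skipped by window means; a window
with no defined site is flagged empty and excluded from null sets. A
fixed-difference site gives exactly 1. Group-level comparisons pool all
haplotypes of a group's populations into one sample; the all-populations
percentile matrix instead treats each of the populations as the unit.

An important property, verified against an independently coded
variance-component implementation and documented because it is easy to
mistake for a bug: the **mean of per-SNP $\hat\theta$ is not unbiased for
the generating F when only two populations are compared**. The
between-population mean square has a single degree of freedom, so the
per-SNP ratio is noisy and Jensen's inequality drags its mean below
$E[a]/(E[a]+E[b]) = F$, while the zero-clamp pushes upward near $F=0$. At
$F=0.2$ (100 haplotypes per population) the expectation is ≈ 0.149; at
$F=0.1$, ≈ 0.084; the multi-locus ratio-of-sums estimator is consistent,
but window averaging of per-SNP values is what the scan intends, so the
per-SNP form is kept.

## Windows and matched nulls

Positions are 1-based; a window is the closed interval
$[c - L/2,\, c + L/2]$ and a SNP belongs to it iff its position lies
inside. The expanding scan doubles the width over
$\{50, 100, 200, 400, 800, 1600\}$ kb (a cM analogue uses genetic
distance); the sliding scan tiles a region with 400 kb windows every
200 kb, shifting the final window back so it ends exactly at the region
end.

Null windows are drawn with uniform-random centers over the chromosome's
SNP extent and accepted iff (i) their genic SNP fraction is within ±0.10
— read as absolute percentage points, since a relative tolerance is
ill-defined at fraction 0 — of the focal window's, (ii) they contain at
least one SNP defined for the comparison, and (iii) they do not overlap
the focal window. Percentile ranks use the mid-rank tie convention
$100\,(\#\{x < v\} + \tfrac12\#\{x = v\})/N$, so a focal value tied with
every null sits at the 50th percentile. Null sets are drawn independently
per pair and per window from logged sub-seeds.

## The bootstrap test

For groups A, B, C, with $\theta_X$ the focal-window mean F_ST and
$\bar\theta_{bg}$ the mean over the matched background windows (focal
window excluded),

$$T = (\theta_{X,A\text{-}B} - \theta_{X,A\text{-}C})
    - (\bar\theta_{bg,A\text{-}B} - \bar\theta_{bg,A\text{-}C}),$$

and the null hypothesis is $E(T)=0$. Individuals (haplotype pairs, the
resampling unit) are resampled with replacement **stratified within
population**, preserving each population's sample size — unstratified
resampling would randomize population labels and destroy the estimand.
Windows stay fixed across replicates; only individuals are resampled. Two
p-values are reported: the conservative centered exceedance
$p = (1 + \#\{|T^*_i - \overline{T^*}| \ge |T_{obs}|\})/(B+1)$, whose
attainable minimum at $B=1000$ is $1/1001 < 0.001$, and the asymptotic
upper tail of $\chi^2_1$ at $(T_{obs}/\hat\sigma)^2$ with $\hat\sigma$
the ordinary (B−1) sample standard deviation of the $T^*$ — identical to
the two-sided normal tail of $|T_{obs}|/\hat\sigma$.

**Calibration caveat** (measured by the acceptance suite and left as an
honest failure there): this test is calibrated *conditionally on the
focal window*. When the generating model gives every window its own
realized mean differentiation (as any F > 0 world does), a randomly
chosen focal window carries a window-level random effect that individual
resampling cannot reproduce, and the test rejects a random null window at
≈ 0.15 instead of 0.05; at F = 0 the zero-clamp parks $\hat\theta$ on
the parameter-space boundary and the test becomes ultra-conservative.
The test is therefore best read as evidence about a *pre-specified*
window against a fixed background, not as a genome-wide scan statistic.

## Core haplotypes, EHH and REHH

Haplotype blocks use the D′-confidence-interval definition: markers with
minor allele frequency ≥ 0.05; a pair is "strong LD" when its 95% D′ CI
has lower bound ≥ 0.70 and upper bound ≥ 0.98, and "strong recombination"
when the upper bound is < 0.90; maximal non-overlapping marker intervals
in which ≥ 95% of informative pairs are strong-LD become blocks (chosen
greedily, longest first, ties leftmost); remaining markers are
single-SNP cores. The D′ CI comes from the multinomial profile
log-likelihood over |D′| on a 0.001 grid with marginal frequencies held
at their MLEs (phased data, so no EM); the interval is where the
log-likelihood is within 1.92 of its maximum. Because that profile is
concave, block building uses an exact four-point shortcut that evaluates
the likelihood only at the observed D′ and the three thresholds; a
property test keeps it pinned to the grid route. Pairs separated by more
than `max_span_snps` (default 25) markers are not evaluated — a runtime
bound in the spirit of the usual maximum-pair-distance settings.

The distinct allele strings over a block's markers partition its
chromosomes into **cores**; only cores with frequency > 5% are analyzed,
with rarer chromosomes still contributing to the pooled denominator.
EHH of a core at distance d (bp by default, from the proximal block
edge, separately upstream and downstream) groups the carriers by identity
of the haplotype from the edge out to the SNP *nearest* d (inclusive; no
interpolation between markers) and is $\sum_j \binom{c_j}{2} /
\binom{n}{2}$. REHH divides by the pooled EHH of all other cores of the
block, where chromosomes with different cores are never identical.
EHH(0) = 1 and curves are non-increasing by construction.

Empirical p-values rank a core's REHH within its **core-frequency bin**
(width 0.05 over (0.05, 1]) of the chromosome-wide records:
$p = (1 + \#\{\mathrm{REHH}_{bin} \ge \mathrm{REHH}_q\})/(n_{bin}+1)$,
the query excluded from its own null set. Bins holding fewer than 20
records are widened symmetrically to adjacent bins and flagged. Both
directions are scored separately and never combined. Rank-based p-values
make the raw-vs-log-REHH question moot.

## Enrichment

Extreme cores are counted per group at thresholds
$\{0.001, 0.005, 0.01, 0.05\}$ (the 99.9/99.5/99/95th percentiles of the
empirical distribution). Pairwise two-sided Fisher exact tests use
(extreme, non-extreme) counts with per-group totals, summing
hypergeometric outcomes no more likely than the observed table. No
multiple-testing correction is applied by default. Q–Q series pair sorted
observed $-\log_{10} p$ with expected $-\log_{10}((i-0.5)/n)$.

# The synthetic world

`sim_config()` defaults state the world all power and calibration tests
live in, chosen once for scientific realism and runtime and not
revisited:

* **4 populations × 100 haplotypes** (50 diploids) — the scale of the
  larger population groups in worldwide reference panels.
* **1200 SNPs over 40 Mb** (one per ~33 kb). Deliberately sparser than a
  genome-wide array: the generator draws sites in linkage equilibrium, so
  haplotype identity over a 300 kb horizon must rest on a handful of
  markers for the null EHH to stay informative (with array density the
  null EHH would be numerically zero for every core). This is the main
  realism concession and is flagged below.
* **F = 0.05** — classic human between-continental-group differentiation.
* **Ancestral frequencies uniform on (0.05, 0.95)** — a common-variant
  ascertainment spectrum; population frequencies follow the
  Balding–Nichols Beta with mean p and variance F·p(1−p) (checked against
  those moments in the tests).
* **1 cM/Mb** uniform recombination; genic flags in contiguous runs of
  mean 8 SNPs covering 40% of sites.

`spike_sweep()` plants the ground-truth signal: one donor chromosome
carrying a chosen allele (default: the target population's minor allele)
is copied onto a fraction f of the target population's chromosomes over
an interval whose one-sided genetic extents are independent exponentials
with mean `decay_scale_cM`. This mimics a partial sweep: elevated
pairwise F_ST around the focal SNP and a long, frequent shared haplotype
— while leaving other populations and distal sites untouched (asserted
exactly in the tests).

**What a green test does and does not establish.** The linkage
equilibrium baseline makes the null exchangeable, so percentile
uniformity and the empirical-p calibration are exact properties of the
machinery, and any haplotype signal is attributable to the spike. It does
not emulate background LD, demographic history, mutation-rate
heterogeneity or array ascertainment; absolute power numbers measured
here (for the default spike f = 0.3, decay 0.3 cM: REHH detection ≈ 0.7
per replicate, sliding-scan maximum ≈ 0.5–0.65, bootstrap ≈ 0.3–0.45) are
properties of this stated world, not forecasts for real panels.

# Numerical and design choices

* Alleles are abstract 0/1 with no reference/alternate semantics; every
  statistic is orientation-symmetric (asserted by an allele-flip test).
* Missing data are rejected at load; the estimators are exact on complete
  phased matrices. All chromosomes are treated as autosomal-diploid;
  male X haplotypes would need an explicit ploidy model (v1 limitation).
* The conservative bootstrap p uses the +1-corrected centered exceedance
  — the standard choice consistent with both the "conservative" label and
  a $1/(B+1)$ floor.
* $\hat\sigma$ uses the B−1 denominator ("ordinary sample standard
  deviation").
* All randomness flows from one run-level seed through logged integer
  sub-seeds (kept below 2^31), making every table byte-reproducible.
* Degenerate cases: monomorphic sites are undefined (never zero); empty
  windows are flagged and excluded; a σ̂ = 0 resampling distribution gives
  p = 1 at T = 0 and p = 0 otherwise; a zero REHH denominator is
  undefined rather than infinite.
* Genic matching requires a genic track; fraction is per-SNP (the
  annotation is per-SNP), not per-base.

# Known limitations

* No background LD in the baseline generator (a coalescent backend could
  replace it behind the same interface).
* The bootstrap test's unconditional anticonservatism under F > 0 worlds,
  discussed above.
* Gabriel-block building is quadratic in markers within the span bound;
  genome-scale scans should keep `max_span_snps` modest.
* X-chromosome male haplotypes, multi-allelic sites, imputation and
  phasing are out of scope.
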