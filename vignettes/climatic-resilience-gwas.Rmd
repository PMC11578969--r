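---
title: "Climatic-resilience indicators and mixed-model GWAS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Climatic-resilience indicators and mixed-model GWAS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crgwas)
```

## The problem

Heat stress degrades welfare and performance in lactating sows. Climatic
resilience (CR) — how little an animal is perturbed by thermal load and
how quickly it returns to euthermia — can be quantified from
high-frequency body-temperature records: a vaginally implanted logger
samples temperature (Tv) every 10 minutes over weeks, while barn ambient
conditions are logged every 5 minutes. `crgwas` derives twelve CR
indicators from such records, maps them with a mixed linear-model GWAS,
and annotates significant SNPs positionally. Because commercial sow data
are private, the package ships a calibrated generator that emulates the
study design so every stage is testable end to end.

## The twelve indicators

Six indicators summarize *deviations* between each observation and a
trailing moving window of six consecutive 10-minute observations (the
window includes the current point): the natural log of the sample
variance (`LnVar_Ave`, `LnVar_Med`), the lag-1 Pearson autocorrelation
(`Autocor_Ave`, `Autocor_Med`) and the moment skewness g1
(`Skew_Ave`, `Skew_Med`), computed against the window **ave**rage or
**med**ian. A stable, resilient animal has small, unstructured,
symmetric deviations; noisy, sticky (autocorrelated) or spiky (skewed)
deviations signal poor thermoregulation.

Four indicators use the ventilation-specific heat-stress (HS)
thresholds — 39.76 °C under mechanical and 39.78 °C under natural
ventilation, taken as known inputs from the prior estimation study:

* `HSD` — minutes per day in runs of consecutive above-threshold
  observations (aggregated over days; mean by default);
* `Max_Tv` — the daily maximum Tv (same aggregation);
* `HSU_A` = $\sum_{t:\,T_{v,t} > \tau}(T_{v,t}-\tau) \ge 0$ and
  `HSU_B` = $\sum_{t:\,T_{v,t} \le \tau}(T_{v,t}-\tau) \le 0$ over the
  whole recording period.

Two are population-level min–max products, e.g.
$\mathrm{Nor\_medvar}_i = \frac{\mathrm{Med}_i-\mathrm{Med}_{\min}}
{\mathrm{Med}_{\max}-\mathrm{Med}_{\min}} \times
\frac{\mathrm{varT_v}_i-\mathrm{varT_v}_{\min}}
{\mathrm{varT_v}_{\max}-\mathrm{varT_v}_{\min}}$, and `Nor_avevar`
analogously with the animal mean.

### Conventions where the indicator definitions are underdetermined

* **Window alignment.** Trailing windows of six observations ending at
  the current point; a centered window is impossible with even length,
  and trailing windows match the resilience-indicator literature
  (deviation of the newest observation from its recent expectation).
  Every time point with a complete window yields a deviation
  (overlapping windows), maximizing data use.
* **Gaps.** Sensor series have holes. Windows and lag-1 pairs must be
  contiguous on the nominal 10-minute grid within ±2 minutes; anything
  spanning a larger gap is discarded, never interpolated.
* **Estimators.** `LnVar` uses the natural log of the n−1 sample
  variance; skewness is $g_1 = m_3/m_2^{3/2}$ with denominator-n central
  moments; autocorrelation is the Pearson correlation over consecutive
  deviation pairs. Degenerate inputs (zero variance, too few
  deviations) yield `NA`, never −∞ or silent zeros.
* **Daily traits.** `Max_Tv` and `HSD` are daily quantities entering the
  GWAS as one value per animal; the aggregate is the mean over recorded
  days (median/max available by configuration, recorded in metadata).
  Days without records are omitted, not zero-filled.
* **`HSU_B` sign.** The below-threshold sum is kept as the raw signed
  (non-positive) sum; an absolute-value variant is a config flag.
* **"Consistently exceeded".** Any run of consecutive above-threshold
  observations counts towards `HSD` (minimum run length 1,
  configurable).

## The association model

For each indicator $y$ the null model is $y = Xb + u + e$ with
$u \sim N(0, G\sigma_g^2)$, $e \sim N(0, I\sigma_e^2)$, where $G$ is the
VanRaden genomic relationship matrix over standardized dosages
($z_{ij} = (x_{ij}-2p_j)/\sqrt{2p_j(1-p_j)}$, missing dosages imputed at
$2p_j$, $G = ZZ'/m$). Fixed effects default to intercept + parity class
+ ventilation class and are fully configurable. Variance components are
estimated by REML: $G$ is eigendecomposed once, the restricted
likelihood is profiled over the total variance, and the heritability
ratio is maximized by deterministic 1-D search on $[10^{-6},
1-10^{-6}]$ with tolerance $10^{-8}$ — no random restarts, identical
answers on reruns.

Each SNP is then tested by generalized least squares under the fitted
covariance structure with a 1-df Wald test. Two design choices matter:

* **Leave one chromosome out (LOCO).** The $G$ used when testing a SNP
  excludes that SNP's chromosome, so the tested marker never competes
  with itself through the polygenic term. Components are re-estimated
  once per left-out chromosome and held fixed for all SNPs on it
  (per-SNP REML would cost $O(m)$ fits for no practical gain).
* **Residual scale.** The GLS fit re-estimates the overall residual
  scale per SNP from whitened residuals. With $\sigma_g^2 = 0$ the scan
  is then *exactly* ordinary least squares, a limit the tests verify
  against `lm()`, and the explicit-inverse oracle equivalence holds at
  $10^{-8}$.

### Multiple testing

Three schemes, all inclusive at the boundary ($p \le$ threshold):

1. genome-wide Bonferroni $0.05/N$ and 2. suggestive $1/N$, with $N$ the
   SNP count after greedy sliding-window LD pruning (window 50, step 5,
   $r^2 > 0.1$; the lower-MAF member of an offending pair is removed,
   ties to the later map position — the reference tool's exact
   tie-break is unspecified, so ours is documented and logged);
3. chromosome-wise $0.05/M_e$ with $M_e = 2 N_e L/\log(N_e L)$,
   $N_e = 60$, $L$ the chromosome length in cM at 1 Mb ≡ 1 cM (taken
   from the spanned map extent). The log base is not stated where the
   formula is quoted; the natural log is assumed and flagged in output
   metadata.

Inflation is diagnosed by $\lambda$ = median observed $\chi^2_1$ /
null median, with a distribution-free order-statistic 95% CI for the
sample median mapped through the same ratio (the CI construction is a
package choice; the cited literature names a CI without specifying
one). Q-Q coordinates use $(i-0.5)/n$ uniform quantiles.

## Annotation

Genes (GFF3, via rtracklayer) and QTL intervals (Animal-QTLdb GFF
dialect or a 5-column TSV) within ±500 kb of each significant SNP are
reported, inclusive at exactly 500 kb. QTL-type composition uses
distinct intervals (key: chromosome, start, end, type, trait), and a
per-type upper-tail hypergeometric test compares hit composition to the
background table — a documented stand-in, since the database tooling
used in the motivating analysis does not state its enrichment test.
GO/KEGG enrichment requires external web databases and is out of scope.

## The synthetic-data generator

The generator emulates the study design: ~400–1,600 sows of parities
2–7 split between mechanical and natural ventilation, genotyped at
SNP-chip-like density (scaled down to 5 × 600 independent loci with MAF
uniform on [0.05, 0.45] under Hardy–Weinberg sampling), with Tv sampled
every 10 minutes over 14 days and ambient conditions every 5 minutes.
Two latent animal traits with configurable architecture (planted QTL +
polygenic background + environmental noise, empirically standardized so
realized variance fractions are exact) drive the phenotype:

* **thermal baseline** — a per-animal Tv offset (sd 0.25 °C);
* **heat sensitivity** — the gain on ambient heat load, defined as
  max(0, ambient − 25 °C), mean 0.08 and sd 0.04 °C per °C of load.

Tv is baseline + parity effect + circadian cycle + sensitivity × heat
load + stationary AR(1) sensor noise (ρ = 0.6, sd = 0.15 °C). The
latent sensitivity additionally modulates the noise sd, the AR
coefficient and the right-skew of the innovations (standardized-gamma
draws): low-resilience animals run noisier, stickier, spikier
residuals. That is not cosmetic — it is what makes the log-variance,
autocorrelation and skewness indicators *heritable*, which is the
empirical regime the package targets: with default calibration the
REML heritabilities of all twelve indicators fall in roughly
[0.05, 0.35], bracketing the 0.08–0.29 range reported for such
indicators in lactating sows. Heat waves are scheduled episodes
(25% of days, +6 °C) so replicate cohorts see comparable heat-stress
exposure. Records are dropped completely at random (2% default),
leaving real holes that exercise the gap policy; values are clipped to
a physiological band [37, 42.5] °C with a logged clip count.

What the generator does **not** emulate: linkage disequilibrium and
haplotype structure (loci are independent, so LD pruning retains nearly
everything), pedigree or selection, barn structure beyond the two
ventilation classes, informative missingness, and sensor artifacts
(drift, spikes from logger handling). Passing tests therefore
demonstrate correctness of the estimators and calibration under a
clean generative model — not robustness to every pathology of real
barn data.

## Numerical choices and problem sizes

* REML search bounds [1e−6, 1−1e−6], tolerance 1e−8; boundary fits are
  flagged. Eigendecompositions use `eigen(symmetric = TRUE)`.
* Zero-variance SNPs yield records with missing statistics; monomorphic
  SNPs are dropped from GRMs and pruning with a message. The MAF filter
  for tested SNPs defaults to 0.01 (quality control for the original
  data lives in a prior study, so the filter is configurable).
* Rolling window medians use vectorized order-statistic extraction
  rather than a per-window sort, keeping a 400-animal × 14-day cohort's
  phenotyping in seconds.
* Validation sizes were chosen so the full suite runs in minutes on one
  core: null calibration uses one cohort of 400 animals × 3,000 SNPs;
  planted-QTL recovery uses 50 replicates of 800 animals × 800 SNPs;
  generator calibration averages REML fits over replicate cohorts of
  1,200 animals because marker-based heritability estimates carry
  sampling error of order $\sqrt{2m}/n$.
* With marker counts deliberately small, chromosome-wise $M_e$
  thresholds can exceed the suggestive threshold; the threshold
  *ordering* reported alongside results always reflects the actual
  $N$ and $L$ of the data at hand.

## A worked example

```{r example, eval = FALSE}
library(crgwas)
cfg <- pipeline_config(
  sim = sim_config(n_animals = 200, n_chromosomes = 3,
                   snps_per_chromosome = 300, n_days = 7, seed = 42),
  indicators = c("LnVar_Ave", "HSU_B"))
res <- run_pipeline(cfg, "demo_run")
res$thresholds
res$lambda
head(res$assoc$HSU_B[order(res$assoc$HSU_B$p), ])
```

The run directory contains PLINK MAP/PED genotypes, tidy Tv and
covariate TSVs, the ground-truth record, the indicator table, one
association TSV per indicator with significance labels, threshold and
λ tables, Q-Q coordinates, and a JSON manifest whose config hash makes
reruns comparable.

## Known limitations

* Repeated-records models (daily `Max_Tv`/`HSD` as longitudinal
  responses) are not implemented; daily traits are collapsed per
  animal.
* The scan assumes one phenotype record per genotyped animal and
  complete fixed-effect covariates.
* The hypergeometric QTL enrichment treats intervals as exchangeable
  units and ignores interval length and overlap correlation.
* Heat-stress thresholds are inputs; estimating them from Tv and
  ambient data is a separate problem deliberately left out.
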