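---
title: "Methods: case-control methylation analysis with a chip-constrained randomization null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control methylation analysis with a chip-constrained randomization null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylwas)
```

# The analysis model

`methylwas` implements a case-control epigenome-wide association analysis for
Infinium-27K-style methylation arrays. The measured quantity at CpG site $j$
in subject $i$ is the methylation proportion (beta-value)

$$\beta_{ij} = \frac{M'_{ij}}{M'_{ij} + U'_{ij}},$$

where $M'$ and $U'$ are the methylated and unmethylated channel intensities
after subtracting the subject's mean negative-control intensity (negative
results clamped at zero; a zero denominator yields a missing value). Analysis
is done on the logit scale, $m_{ij} = \mathrm{logit}(\beta_{ij})$ (the
M-value), where effects are closer to additive and variances more comparable
across sites.

Each site is tested by ordinary least squares:

$$ m_{ij} = \alpha_j + \gamma_j \, \text{case}_i + \mathbf{x}_i^\top
\boldsymbol\delta_j + \varepsilon_{ij}, $$

with covariates $\mathbf{x}_i$ = experimental batch (factor), two
bisulfite-conversion efficiency channels, age, BMI, race (factor, reference
caucasian), and indicators of vitamin use, alcohol and smoking. The test
statistic is $t_j = \hat\gamma_j / \mathrm{SE}(\hat\gamma_j)$.

## The chip-constrained randomization null

BeadChips carry 12 arrays each and are processed in batches of up to four
chips; samples on one chip share technical variation. Instead of referring
$t_j$ to the theoretical $t$ distribution, significance is evaluated against
pseudo-datasets in which disease status is randomized **within the chip
structure**, in two stages per chip:

1. the observed case/control labels are uniformly permuted among the
   subjects of the chip;
2. with probability 1/2, every label on the chip is then swapped
   (case $\leftrightarrow$ control).

Each subject is therefore case with probability exactly 1/2 in every
pseudo-dataset (we verify this by exhaustive enumeration for small chips),
while each chip retains either its observed case/control composition or its
complement — the chip structure of the design, and with it any chip-driven
spurious association, is preserved under the null. All covariates stay
attached to their subjects; only the status column of the design matrix is
replaced, and the full regression is refit per draw.

The two-sided empirical p-value for site $j$ after $R$ draws uses the +1
correction and counts ties as extreme:

$$ p_j = \frac{1 + \#\{r : |t^*_{jr}| \ge |t_j|\}}{R + 1} \in
\left[\tfrac{1}{R+1},\, 1\right]. $$

By default each site is compared with its own null draws (per-probe null);
`pooled = TRUE` pools draws across sites. The per-probe null is the
assumption-light reading — it lets every site have its own null spread — and
is the package default. Note the p-value floor: detecting anything at
$p < 0.005$ requires $R \ge 200$; we use $R = 499$–$999$ in examples and
recommend $R = 10{,}000$ for production runs.

### What the randomization does and does not fix

A point that the package's own validation surfaced clearly: when cases and
controls are **randomly interleaved** onto chips (as in the emulated study
design and in the generator), the ordinary $t$ reference is already close to
valid on average, because random placement lets the chip effect inflate the
within-group variance estimate by almost exactly its contribution to the
group-difference variance. The randomization null still earns its keep in
two ways: its tails are heavier than the theoretical $t$ (we measure pooled
97.5% quantiles of $|t^*|$ around 2.1–2.3 against a $t$ quantile of 1.99
under chip noise), making inference conservative site by site and robust to
the non-Gaussian residuals produced near the beta boundaries; and it remains
valid *conditionally* on an unlucky, imbalanced placement, where the
theoretical reference can fail badly (with status-confounded placement we
measure naive-t type-I error near 0.47 at nominal 0.05). Batch-level
randomization schemes protect the average; the chip-constrained null
protects the realized design.

## Storey q-values

False discovery rates use Storey's estimator, written from its definition:
$\hat\pi_0(\lambda) = \#\{p_j > \lambda\} / (m(1-\lambda))$ on the grid
$\lambda = 0, 0.05, \ldots, 0.90$, smoothed by a cubic smoothing spline
(df = 3) and evaluated at $\lambda = 0.90$, clamped into $(0, 1]$; then
$q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)} / j$. With $\hat\pi_0 = 1$
this reproduces the Benjamini–Hochberg adjustment exactly (a tested
identity). On 10,000 uniform p-values $\hat\pi_0$ lands near 1 (typically
0.95–1.0).

## Candidates, enrichment, cohort table

Candidate sites are those with empirical $p$ strictly below 0.005, reported
with direction (+ = hypermethylated in cases, the sign of $\hat\gamma_j$).
CpG-island over-representation among candidates is a two-sided exact
binomial test against the array's island fraction (default 0.76). Gene-set
over-representation maps candidate probes to unique uppercased gene symbols
(best p per gene) and applies the one-sided hypergeometric test within the
universe of assayed genes — candidates can only arise from assayed genes, so
a whole-genome universe would overstate enrichment — with BH correction
across sets (set counts are small, so the BH step-up is appropriate there).
The cohort descriptive table uses Fisher's exact test (probability-mass
two-sided rule; exact network algorithm for r x c tables, Monte Carlo with
the $(1+\#)/(B+1)$ estimator as a fallback), with "Missing" rows reported
but excluded from testing and percentages computed on full group
denominators, as in the emulated study's published table.

# The synthetic data generator

The generator exists so the whole pipeline runs and is testable with no
external data. It emulates:

- **Cohort structure**: 180 cases / 187 controls by default; lifestyle
  covariates drawn from the study's published marginal frequencies per
  status (e.g. smoking 30.0% in cases vs 18.7% in controls), including the
  published missingness rates (BMI ~4.6%, income ~7%) so complete-case
  handling is exercised. Age and BMI are drawn uniformly within their
  reported bins. Two bisulfite-conversion channels are drawn from a
  correlated bivariate normal (r = 0.9).
- **Chip layout**: a global random shuffle fills chips of 12, grouped into
  batches of up to 4 chips — cases and controls randomly interleaved.
- **Baseline methylation**: a three-component Beta mixture,
  Beta(0.5, 8) with weight 0.62 (hypomethylated peak), Beta(8, 0.5) with
  weight 0.20 (hypermethylated peak), Beta(2, 2) with weight 0.18
  (intermediate), clamped into $[10^{-4}, 1-10^{-4}]$; this reproduces the
  characteristic bimodal sample-wise beta histogram.
- **Effects**: `n_true_sites` probes get an additive case shift of
  `effect_size_logit` on the logit scale. Spiked sites are drawn among
  probes with baseline beta in $[0.05, 0.95]$: an additive logit shift at a
  site massed at $10^{-3}$ is below the intensity noise floor of the assay
  model and is not a meaningful differential-methylation signal. The sign
  is + (hypermethylated in cases) with probability 0.892, mirroring the
  hyper/hypo split reported for the emulated study's candidates.
- **Chip effects**: independent $N(0, \texttt{chip\_effect\_sd})$ draws
  *per probe and chip*. Probe-specific batch effects are the standard model
  for array batch artifacts (this is what empirical-Bayes batch correctors
  estimate); a single scalar shared by all probes would also make every
  simulated test depend on one random draw, so error *rates* measured over
  a few hundred probes would not concentrate. The scalar-per-chip summary
  is recoverable as the column mean of the ground-truth effect matrix.
- **Signals**: methylated intensity $G\beta + \epsilon$, unmethylated
  $G(1-\beta) + \epsilon$ with gain $G = 5000$ and
  $\epsilon \sim |N(200, 50)|$; negative controls from the same
  half-normal. Entries selected for missingness (default rate 0.01) emit
  background-level light split randomly across the two channels, so the
  detection p-value fails there. The 0.01 default makes roughly 1% of
  probes hit the ">= 10 bad samples" drop rule at n = 367, the order of
  magnitude reported for the emulated platform.
- **Replicates**: optionally one technical replicate per batch (identical
  methylation profile, independent signal noise).

With background noise set to zero the intended beta matrix is recovered
exactly (a tested round trip), which pins the signal model to the beta
estimator.

**What the generator does not emulate**: dye bias, scanner drift, probe
 chemistry differences (the 27K platform has a single design),
 sequence-driven probe affinity, cell-type composition, or correlation
 between island status and methylation level (island flags are independent
 Bernoulli draws). Passing tests therefore validate the statistical
 machinery under an idealized intensity model, not the biology of any real
 cohort.

# Numerical choices and degenerate inputs

- **Detection p-value**: upper tail of $N(\mu_s, \sigma_s)$ fitted to the
  sample's negative controls, evaluated at $M + U$; the metric is named but
  not defined in the emulated study, and this matches vendor practice. A
  site is called when $p < 0.05$. Zero-variance controls are an error.
- **Sample QC**: call rate $\ge \lceil 0.95\, m \rceil$ sites; background
  strictly below 1000 units; "clear separation" of probe signal from
  background quantified as (mean signal − mean background)/pooled SD > 5.
  The separation criterion is an interpretation (the study reads it off a
  vendor dashboard); both thresholds are configurable.
- **Probe filter**: drop when missing in $\ge$ 10 samples, applied after
  sample QC; kept-probe order preserved.
- **Logit clamp**: $\beta$ clamped into $[\varepsilon, 1-\varepsilon]$,
  $\varepsilon = 10^{-6}$, so boundary betas stay finite. Consequence worth
  knowing: a recovered $\beta$ of exactly 0 or 1 (one channel below
  background) maps to $\mp 13.8$, which fattens residual tails at sites
  massed near the boundaries; simulation shows ±2 SE coverage of a spiked
  1.0-logit effect of ~0.97 for interior baselines but ~0.92 overall when
  spikes sit within 0.10 of the boundary. Larger $\varepsilon$ damps this
  at the cost of compressing genuine extreme methylation.
- **kNN imputation**: candidates are fully observed probes; distance is
  Euclidean over the target's observed samples; imputed value is the
  unweighted mean of the k = 10 nearest candidates at that sample. Observed
  entries are never altered. A probe with no observed entries is an error
  (precluded by the probe filter at realistic missingness).
- **PCA**: samples are observations, probes variables, centered not scaled
  (M-values share a scale); component signs fixed by making each
  component's largest-magnitude loading positive. The PC screen regresses
  each kept PC on each factor singly (linear for continuous, one-way ANOVA
  for categorical), complete-case per factor, no multiplicity correction —
  it is exploratory and informs covariate choice only.
- **Randomization reproducibility**: draw $r$ under seed $s$ uses a derived
  seed $(s + 48271\,r) \bmod (2^{31}-1)$, so any draw can be regenerated
  independently of the others.
- **Ties in the empirical p**: $|t^*| \ge |t|$ counts ties as extreme
  (conservative).
- **Factor handling**: single-level factors are dropped from the design
  with a warning; rank deficiency is an error naming the offending columns;
  samples missing any model covariate are dropped (complete-case), matching
  the emulated study's explicit missing-data accounting.

# Validation scale

The shipped checks run at deliberately chosen sizes: the null-validity
study uses 12 independent replicates of 200 null probes on 96 samples
across 8 chips with `chip_effect_sd = 0.5` and $R = 500$ (rates pooled over
2,400 tests); parameter recovery uses one full 2,000-probe, 367-sample run
at $R = 499$ plus 60 independent cohorts for ±2 SE coverage of the spiked
effect (1,200 coverage events). These sizes give rate estimates whose Monte
Carlo error is small against the bounds being checked while keeping the
default test suite fast.

# Known limitations

- The pipeline tests sites marginally; no spatial smoothing across
  neighbouring CpGs and no region-level inference.
- No between-array normalization (quantile or functional): the emulated
  platform is single-design and the emulated study applied none.
- The empirical null costs $R$ full refits of the site-wise regressions;
  this is linear in $R$ and in probes, and the matrix formulation keeps a
  2,000-probe, $R = 499$ run in the tens of seconds, but genome-scale runs
  at $R = 10{,}000$ are minutes-to-hours territory.
- The sub-phenotype (defect-class) stratified analysis is supported only in
  the sense that a custom design can swap the outcome term; no stratified
  driver is shipped.
- Storey's $\hat\pi_0$ is estimated on the empirical p-value grid, which is
  discrete with resolution $1/(R+1)$; at small $R$ the spline estimate of
  $\pi_0$ is correspondingly coarse.
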