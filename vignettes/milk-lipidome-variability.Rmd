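---
title: "Methods: variance components and biological variability of milk lipids"
author: "milkvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variance components and biological variability of milk lipids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milkvar)
```

# The problem

Targeted lipidomics of human milk asks two repeatability questions: how
stable are the differences between donors (is each mother's milk lipidome a
reproducible individual signature?), and how much does the lipidome move
within a donor between morning and evening collections?  Answering both
requires a post-processing chain that turns raw peak areas into relative
concentrations, discards analytically unreliable species, handles sporadic
left-censored dropouts, and then partitions each lipid's variance into
between- and within-participant components.

`milkvar` implements that chain for a within-subjects design with `n`
donors sampled at two counterbalanced times of day (morning 06:00–09:00,
evening 18:00–21:00), a 13-class panel spanning neutral lipids (TAG, DAG,
measured by direct infusion) and phospholipids/sphingolipids (measured by
reversed-phase MRM), and the usual QC layer of technical QCs, batch QCs,
blanks and a 40–160% dilution series.

# Quantification model

## Internal-standard normalization

Each class has one spiked internal standard (two deliberate cross-class
assignments: DAG species are normalized to the d5-labeled TAG 48:0
standard, dihexosylceramides to the glucosyl C8 ceramide standard).  For
lipid $l$ in sample $s$,

$$c_{ls} = \frac{A_{ls}}{A_{\mathrm{ISTD}(class(l)),s}}\cdot
\mathrm{spike}(class(l)),$$

a *relative* concentration in spike-amount units; no molar conversion is
attempted.  Because the standard is spiked before extraction, any
per-sample extraction-efficiency factor multiplies numerator and
denominator alike and cancels: normalization is exactly scale-equivariant,
which the tests assert.

## Isotopologue overlap correction

In positive-mode MRM the M+3 isotopologue of SM X:Y is isobaric with PC
(X−4):(Y−1).  The correction subtracts $r_3(\mathrm{SM})\cdot
A_{\mathrm{SM}}$ from the overlapped PC area (floored at zero), where the
M+3 fraction comes from a carbon-only binomial model:

$$r_k(n_C) = \frac{\binom{n_C}{k} p^k (1-p)^{n_C-k}}{(1-p)^{n_C}},
\qquad p = 0.0107.$$

Contributions of ²H, ¹⁵N and ¹⁸O are ignored — the three-heavy-carbon term
dominates M+3 and is fully determined by the carbon count, which the
species name carries.  The SM→PC pairing is derived structurally from the
parsed names rather than from a hard-coded list, so synthetic panels pair
correctly.  The same arithmetic corrects the endogenous GM3 d18:1/18:0
M+3 overlap on its d3-labeled internal standard.  Whether an instrument's
effective factor is exactly the theoretical one is unknowable from names
alone, so `r3` is exposed as an override.  The correction is single-pass:
it is only idempotent when interferent areas are zero.

## QC filtering

Per lipid the package computes the technical-QC and batch-QC replicate CVs
($100\,\mathrm{sd}/\mathrm{mean}$, on normalized concentrations so that
extraction noise cancels), dilution-series linearity (OLS of response on
volume fraction, duplicates entering as individual points), and a
signal-to-noise ratio.  The inclusion rule is deliberately literal, with
strict inequalities so boundary values are excluded: keep a lipid iff

* TQC CV **and** BQC CV < 20%,
* S/N > 10,
* linearity $R^2$ > 0.85.

S/N has no universal definition for integrated MRM peaks; the package uses
$\mathrm{mean(analyte\ in\ BQC)}/(\mathrm{mean(blank)} +
3\,\mathrm{sd(blank)})$ with a floored denominator, and the estimator is
pluggable.  Filtering is monotone: relaxing any threshold can only grow
the kept set (tested by enumeration against the raw predicate on a
380-lipid planted panel).

# Left-censored imputation (QRILC)

Missing values in such panels are sporadic and concentrated at low signal,
so they are treated as left-censored.  Per lipid, the underlying Normal
$(\mu,\sigma)$ is estimated by quantile regression: the observed order
statistics are regressed on standard-normal quantiles at plotting
positions $(r + m - 0.5)/n$ shifted by the $m$ censored points, using only
positions above 0.25 (default) for robustness against lower-tail
irregularity; the slope estimates $\sigma$, the intercept $\mu$.  Each
missing entry is then drawn from $N(\mu, \tau\sigma)$ truncated above at
the lipid's minimum observed value and below at 0 ($\tau$ = 1 by default),
via inverse-CDF sampling from a seeded RNG, so completed tables are
bit-reproducible and observed entries are never touched.  Columns with
fewer than five observed values are refused rather than imputed.
Imputation runs after QC filtering and before model fitting.  Tuning
defaults (`min_quantile = 0.25`, `tune_sigma = 1`) are the package's own
choices, documented rather than asserted as canonical.

# The variance-components model

For each lipid (or class total, summed per sample before fitting):

$$y_{it} = \beta_0 + \beta_1\,\mathrm{evening}_t +
\beta_2\,\mathrm{order}_i + b_i + e_{it},\qquad
b_i \sim N(0,\sigma^2_{BS}),\quad e_{it} \sim N(0,\sigma^2_{WS}),$$

fitted by restricted maximum likelihood on the concentration scale (the
ICC, %CV and fold-change summaries are all defined on concentrations; a
log-scale switch exists for robustness checks).

## Profiled REML

The fitter is written in the package and validated against independent
implementations.  With $\lambda = \sigma^2_{BS}/\sigma^2_{WS}$,
$V^* = I + \lambda ZZ'$ is block diagonal over subjects, so
$V^{*-1}_i = I - \frac{\lambda}{1+\lambda n_i}J$ reduces every quantity to
per-subject sums.  For a candidate $\lambda$ the fixed effects solve GLS
and $\sigma^2_{WS}$ profiles in closed form; the restricted criterion

$$(n-p)\log\mathrm{RSS}(\lambda) + \sum_i \log(1+\lambda n_i) +
\log\bigl|X'V^{*-1}X\bigr|$$

is minimized over $\log\lambda \in [-12, 12]$ by `optimize()` (tolerance
1e-10) and then polished by root-finding on its analytic derivative
(tolerance 1e-13), with the boundary $\lambda = 0$ evaluated explicitly;
negative between-subject variance is truncated at that boundary and
flagged.  On balanced intercept-only designs the interior optimum equals
the method-of-moments ANOVA estimators
$\hat\sigma^2_{WS} = \mathrm{MSW}$,
$\hat\sigma^2_{BS} = (\mathrm{MSB}-\mathrm{MSW})/k$, which the acceptance
suite verifies to 1e-8 over 100 simulated datasets; on unbalanced designs
with fixed effects the suite checks agreement with `lme4::lmer` (variances,
coefficients, their standard errors and the REML log-likelihood).

The standard error of $\hat\sigma^2_{BS}$ comes from the observed
information: the 2×2 Hessian of the restricted log-likelihood in
$(\sigma^2_{BS}, \sigma^2_{WS})$ by central differences (relative step
1e-4) at the optimum.  On the boundary the information is singular and the
standard error is reported as undefined.

## Tests and their conventions

* **Wald Z for the ICC**: $Z = \hat\sigma^2_{BS}/\mathrm{se}$, with a
  **one-sided** upper Normal tail.  A variance component is one-sided by
  nature, and the shipped reference table of class-level results is
  internally consistent with the one-sided tail at every row (the
  acceptance suite recomputes all 13 pairs, allowing for the rounding of
  both printed numbers); a two-sided convention reproduces none of the
  sub-0.05 rows.  Boundary fits report p = 1.
* **Fixed-effect F**: $F = (\hat\beta/\mathrm{se})^2$ on 1 numerator df,
  with denominator df by containment — for within-subject terms
  $n_{obs} - n_{subjects} - (q_w + 1)$, for between-subject terms
  $n_{subjects} - (q_b + 1)$; both give 18 in the full 20×2 design with
  time + order, and F(1,18) reproduces the reference table's printed
  time-of-day p-values at printed rounding, which is how the convention
  was selected.  (Two of the thirteen order-column pairs disagree with any
  plausible df in the last printed digit and are treated as source
  rounding; the property test bounds them at 0.01.)  A naive
  `df_method = "residual"` alternative is provided; Satterthwaite
  approximation is out of scope.
* **ICC labels**: half-open benchmark ranges — below 0.4 *below-moderate*,
  [0.4, 0.6) *moderate*, [0.6, 0.8) *substantial*, [0.8, 1] *almost
  perfect*.

## Summaries

Biological %CV is $100\,\mathrm{sd}/\mathrm{mean}$ across subjects at one
time point, never pooled across time points (a pooled variant exists but
is kept separate).  Fold changes are the median of per-subject
evening/morning ratios by default, which respects the within-subject
pairing; the cohort-median-ratio alternative is a flag, because the two
only coincide asymptotically.  Rankings of most/least variable lipids
break ties lexicographically so output is reproducible.

# The synthetic study generator

The generator is first-class, tested code: it draws complete study-shaped
datasets (areas, internal-standard areas, metadata, QC injections) with a
stored ground truth, so every downstream stage has a recoverable target.

Per lipid $j$, subject $i$, time $t$:

$$y_{ijt} = \mu_j + (\mathrm{fold}_j - 1)\,\mu_j\,[t=\mathrm{evening}] +
b_{ij} + e_{ijt}$$

additively on the concentration scale — matching the model the pipeline
fits and the scale on which ICC and %CV are defined — with a truncation
floor at $10^{-9}\mu_j$ to keep concentrations positive (configurable);
`lognormal_biology = TRUE` switches to a multiplicative model with the
same per-lipid CVs for robustness checks.  The evening effect is
multiplicative before noise, so configured fold changes are recovered by
the paired-median estimator.  Class defaults place the 13 classes at the
operating points characteristic of the emulated 20-donor study: mean
concentrations spanning the neutral/polar abundance gap (TAG ≫ DAG ≫
phospholipids/sphingolipids), class ICCs between 0.35 and 0.74, technical
CVs between 5 and 21%, evening folds up to 1.5 (PE, TAG highest), and
biological CVs around 0.8–1.0 for neutral versus ~0.3–0.4 for polar
classes.  Within a class, lipid means fan out geometrically (×2.5 down to
×0.3) and each lipid inherits its class's true ICC by splitting total
biological variance, so class totals also carry that ICC exactly.

Raw areas follow the response model
$A = c \cdot A_{\mathrm{ISTD}}/\mathrm{spike}$ (unit response factor),
multiplied by unit-mean lognormal technical noise at the class CV.  A
per-sample extraction factor multiplies endogenous and standard areas
alike, and TQCs share one extract while BQCs are independently extracted
with inflated noise (`bqc_cv_ratio` ≥ 1), reproducing the TQC ≤ BQC CV
ordering.  Dilution-series response is proportional to volume fraction,
with an optional saturation knob; blanks sit near zero.  SM→PC M+3
interference can be injected (the exact inverse of the correction, which
round-trips to 1e-9).

**Censoring.**  The emulated study exhibits very sparse left-censored
missingness (~4 values in a 237 × 40 table).  A fixed quantile threshold
on the *concentration* scale cannot reproduce that under the
additive-Normal choice: for high-CV classes the threshold is negative and
never fires.  The generator therefore censors on the latent biological
Gaussian score (the combined subject + residual standard deviate), which
removes exactly the lowest `censor_quantile` of every lipid's distribution
and makes the expected missing count `n_lipids × n_samples × q`; the
default `q = 4.2e-4` gives ≈ 4.  This is the package's own design choice.

**All randomness flows from one seed** (`studyConfig(seed=)`); the QC
series uses a deterministic offset of it.  Identical config and seed give
byte-identical artifacts, which the pipeline test asserts.

## What the generator does not emulate

No chromatograms, spectra or retention times; no drift or batch structure
(so the pipeline has no drift correction to exercise); no diet/feeding
covariates; biological effects are independent across lipids (no
correlation structure within a class beyond the shared parameters), so
tests passing here say nothing about correlated-panel behavior on real
data; and the additive-Normal default puts a small probability mass at the
positivity floor for the high-CV neutral classes, where the configured
variances are moments of the *untruncated* law — generator-convergence
tests therefore use moderate-CV settings, and real right-skewed data are
better served by the lognormal switch.

# Numerical and test-design choices

* REML: search bounds $\log\lambda \in [-12,12]$, `optimize()` tolerance
  1e-10, derivative root polish 1e-13, explicit boundary evaluation;
  degenerate (constant) responses return both variances 0 with a flag
  rather than failing.
* A lipid with fewer than 4 usable records is skipped with a log entry;
  a column with fewer than 5 observed values refuses imputation.
* ICC estimates from two records per subject have sampling sd of roughly
  $(1-\rho^2)\sqrt{2/n}$ — about 0.15 at $n = 20$.  Recovery tests
  therefore choose their problem sizes for the property under test: the
  operating-point recovery runs 500 replicate 20 × 2 studies and checks
  the *mean* estimate (within 0.03 of truth; the small shortfall of the
  mean is the boundary-truncation bias of REML ICCs at this design size),
  while the end-to-end rank-recovery test uses 700 subjects at zero
  technical CV, because technical variance attenuates measured ICCs below
  the configured biological values (most for small classes) and
  single-study estimates at $n=20$ cannot order 13 classes whose true
  ICCs sit within a 0.02–0.1 band of each other.
* The acceptance script simulates 500 replicates per operating point with
  all draws from the single `--seed`.

# Known limitations

Random slopes, crossed random effects and multiple-testing adjustment are
out of scope (p-values are reported raw, as in the emulated study design).
Absolute quantification, adduct handling and in-source fragmentation are
not modeled.  The isotope model is carbon-only and name-derived; species
whose names hide their formula (e.g. oxidized lipids) would need explicit
carbon counts.  The S/N estimator is a proxy for vendor peak-level S/N.
The deposited-study reproduction checks require the external tables,
converted to the package's CSV layout, and are driven by the
`MILKVAR_DEPOSITED_DIR` environment variable.
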