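---
title: "Deriving sex-specific height exponents for relative-weight indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving sex-specific height exponents for relative-weight indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bennscan)
```

## The problem

Body mass index, weight (kg) / height (m)^2, is the standard relative-weight
measure, but the exponent 2 is a historical convention derived largely from
male data. A Benn-type index chooses the exponent *p* in weight/height^*p*
empirically, so that the index is uncorrelated with height in the study
population (*height independency*) while remaining strongly correlated with
body fatness (*fatness dependency*). Because fat accumulation and
distribution differ between the sexes, the optimal *p* is plausibly
sex-specific.

`bennscan` implements this derivation as a reusable pipeline:

1. scan a grid of exponents, computing at each grid point the age-adjusted
   partial Pearson correlation of the index with height and with seven
   fatness / central-adiposity measures (BF%, weight, fat mass, fat-free
   mass, waist circumference, waist:hip ratio, waist:height ratio);
2. select criterion-optimal exponents — the zero crossing of the height
   curve, or the maximum of each fatness curve;
3. evaluate the selected ("new") formula against the conventional one
   (p = 2) as a screen for excessive body fat (AUC, Youden-optimal cutoffs,
   relative-sitting-height strata, category reclassification) and as an
   all-cause-mortality predictor (Cox models on index fifths, AIC).

Population anthropometric data with linked mortality is access-controlled,
so the package ships a seeded synthetic cohort generator with a *known*
ground-truth scaling exponent; every stage of the pipeline is exercised and
validated against it.

## The exponent scan

At every exponent *p* on the grid the index is formed in log space,
`exp(log w - p log h)`, which survives |p| up to 50 without overflowing
double precision (height in meters, so `log h` is order 0.5). The grid is
stored as integer multiples of the step: the default exhaustive grid runs
from −50 to 50 in steps of 0.01 (10,001 points, both endpoints included),
matching two-decimal reporting of exponents. `benn_fit()` defaults to the
restricted grid −5..5, which comfortably brackets human weight–height
allometry; the exhaustive grid is available by passing
`power_grid(-50, 50, 0.01)`.

The age-adjusted partial correlation between index and measure is the
Pearson correlation of the residuals of each after least-squares regression
on an intercept and age. Internally the scan uses the algebraically
identical recursion

r<sub>xy·z</sub> = (r<sub>xy</sub> − r<sub>xz</sub> r<sub>yz</sub>) /
√((1 − r<sub>xz</sub>²)(1 − r<sub>yz</sub>²)),

so that only the correlations involving the index need recomputation at
each grid point; the test suite verifies the equivalence of the two routes
to 10^−10. Confidence intervals use the Fisher z transform,
tanh(atanh r ± 1.96/√(n − g − 3)) with g = 1 control variable; the
literature is not unanimous on whether the degrees of freedom should be
n − 3 or n − g − 3, and this package uses n − g − 3. Age is the sole
adjustment variable.

**Criterion optima.** The height-independency optimum is the grid point
minimizing |r| with height — reported at grid (two-decimal) resolution, not
interpolated, with ties broken toward the smaller exponent; the scan also
checks that a sign change brackets the optimum, which anthropometric-like
data crosses exactly once. Fatness-dependency optima maximize the *signed*
correlation; a plateau wider than 10 grid points triggers a warning. Note
that the weight criterion is structurally forced: at p = 0 the index *is*
weight, so its maximal correlation is exactly 1 at p = 0.

**Degenerate input.** On a noise-free cohort (weight an exact power law of
height) the index at the true exponent is constant. A constant's
correlation is mathematically undefined, but under the generative model the
correlation tends to 0 as the weight residual SD tends to 0, so the scan
defines it as 0; this makes noise-free recovery of the ground-truth
exponent exact. The standalone `partial_corr()` (the user-facing
operation) instead rejects zero residual variance as an undefined
correlation rather than silently returning 0.

## The synthetic cohort generator

`cohort_params()` encodes, per sex, marginal targets typical of a large
middle-aged UK population cohort: females with height 162 (6.3) cm, weight
71.4 (14.0) kg, body fat 36.6 (6.9)%; males 176 (6.8) cm, 86.0 (14.2) kg,
25.3 (5.7)%. The generative model is:

* height ~ truncated normal on (1.2, 2.2) m; age ~ truncated normal on
  [40, 70] y (mean 56.3/56.7, SD 8.0/8.2 for females/males); sampling is by
  rejection, so all downstream formulas stay defined;
* log weight = log a + p_true · log height + b · (age − ā) + ε, with
  ε ~ N(0, σ_w²) independent of height. Defaults: p_true = 1.4 (F) and
  1.8 (M) — near the height-independent exponents expected for each sex —
  and b = 0.002/y;
* BF% = mean + 0.1 · (age − ā) + 5 · (ε/σ_w) + noise, truncated to
  (3, 75)%; fat mass = BF% · weight/100, fat-free mass the complement, so
  the composition identity holds exactly;
* waist and hip circumference linear in fat mass plus noise, floored at
  40 cm; relative sitting height ~ truncated normal (0.528 (0.014) F,
  0.522 (0.012) M) on (0.40, 0.65), chosen so the 2.5%/97.5% quantiles land
  near the 0.50/0.55 stratum boundaries typical of adult populations;
* categorical covariates (ethnicity, education, smoking, alcohol, each with
  an explicit Unknown level) drawn from configured population frequencies —
  they influence nothing biologically and exist to exercise
  covariate-adjustment plumbing;
* mortality: exponential event times with hazard
  λ₀ · exp(0.085 · (age − ā) + 0.08 · z), z the standardized conventional
  index, administratively censored at 12 y. λ₀ defaults to 0.0057/y (F) and
  0.010/y (M), giving roughly 7% and 11% 12-year mortality. The constant
  baseline permits closed-form checks, and the Cox stage is semiparametric
  regardless.

**Calibration.** The weight scale a and residual SD σ_w are not free knobs:
they are derived in closed form by lognormal moment matching so the
marginal weight mean and SD hit their targets —
σ_w² = log(1 + (s/m)²) − p_true² · Var(log h) − (b · sd_age)², and
log a = log m − ½ log(1 + (s/m)²) − p_true · E[log h], with the height
log-moments from the delta method. The BF% residual SD is likewise derived
from the marginal BF% SD target after removing the age-trend and
weight-residual contributions. Age trends are centered at the mean of the
*truncated* age distribution (computed analytically), not the nominal
mean — truncation at [40, 70] shifts the realized mean age by about half a
year, which would otherwise bias the weight and BF% marginals. With these
choices the generated means and SDs of height, weight and BF% sit within
Monte-Carlo error (3 SE at n = 100,000) of their targets; the test suite
asserts this.

**What the generator does not emulate.** Only marginals and one covariance
channel (weight residual → BF%) are calibrated; the full
weight–height–fatness covariance structure of real populations is not
reproduced. Consequently numeric correlation values from real cohorts are
not recoverable by design — the pipeline's correctness is established by
ground-truth recovery, structural identities and independent oracles, not
by matching any particular population's correlation table. Ethnicity has
no body-composition model; BIA/DXA measurement differences are out of
scope.

## Screening evaluation

Excessive body fat is labelled by the standard clinical rule BF% > 35%
(females) / > 25% (males), strict inequality. AUC is computed rank-based
(Mann–Whitney with ties counted ½); for a single continuous predictor this
equals the ROC area of a logistic regression of the label on the score,
because the fitted probability is a monotone transform of the score — the
suite verifies the identity against an O(n²) pair-counting oracle exactly
and against an independent logistic-ROC computation to 10^−6.

Youden-optimal cutoffs maximize sensitivity + specificity over midpoints
between consecutive distinct scores plus ±∞, under the explicit convention
*score ≥ cutoff predicts high* (the convention must be fixed for
sensitivity/specificity to be reproducible); ties break toward the smallest
cutoff. Cutoffs are learned on the training partition and frozen before
test-set evaluation. The selection rule is the pure Youden maximum — no
sensitivity weighting.

Relative sitting height (sitting/standing height) strata use the 2.5% and
97.5% empirical quantiles (linear interpolation, type 7) per sex on the
evaluation cohort: lower third below q(0.025), upper third at or above
q(0.975).

**Category mapping.** The conventional categories use the standard
18.5/25/30 thresholds with half-open, left-closed bins (a value on a
threshold goes up). To classify subjects under a new exponent, the old
thresholds are mapped to the new index scale by training-set quantile
matching: each new threshold is the empirical quantile of the new index at
the fraction of training subjects below the corresponding old threshold.
Applied back to the training set this preserves category frequencies to
within 1/n. Quantile matching is this package's documented choice for
deriving new-scale category boundaries; reclassification percentages are
then computed on the test set, split by ordinal direction.

## Survival evaluation

Each index is categorized into fifths at interpolated 20/40/60/80
percentiles (values on a cutpoint go to the lower fifth; heavy ties leaving
a fifth empty are rejected), with the lowest fifth as the reference. The
Cox model of all-cause mortality on the fifth indicators plus adjustment
covariates (age, Townsend deprivation — both linear and untransformed —
education, smoking, alcohol, ethnicity) is fitted by the package's own
Newton iteration on the Efron-tie-corrected log partial likelihood, with
step-halving. This is implemented directly — not delegated to a survival
library — so that the analytic score vector can be checked against finite
differences and the Efron/Breslow identity without ties can be asserted; an
established independent Cox fitter is used as a cross-check *oracle* in the
test suite only. Separate models are fitted per sex.

Numerical conventions: convergence is declared when the gradient max-norm
falls below 10^−8 scaled by max(1, |log-likelihood|) — the score components
grow with the number of subjects, so an absolute criterion is not
meaningful in double precision at cohort scale; in addition, when the
expected quadratic gain of a Newton step falls below the double-precision
resolution of the likelihood, one final step is taken (squaring the
remaining coefficient error) and iteration stops. Non-convergence within 50
iterations and separation (|coefficient| > 20) are errors, not silent
results. Wald 95% intervals, exp(β ± 1.96 SE), are reported; AIC is exactly
−2·loglik + 2·(#coefficients), lower better, and formula comparison reports
AIC(new) − AIC(old). Categorical covariate levels containing no events are
collapsed into the reference level (with a message): such levels produce a
monotone partial likelihood whose coefficient diverges, which would
otherwise trip the separation guard on any modest cohort.

## The full pipeline

`run_full_analysis()` reproduces the study flow per sex: generate (or read)
a cohort, fill mortality, split 80%/20% stratified by sex (per-sex test
share within one subject of the target; exact partition), fit the scan on
the training set, select the new formula by height independency, then
evaluate screening and survival on the test set. Formulas, cutoffs and
category thresholds are functions of the training partition only — the
evaluation functions accept them as frozen inputs, so test-set leakage is
excluded by interface. A single top-level seed deterministically spawns
per-stage seeds; two runs with the same configuration produce byte-identical
report bundles (the JSON manifest records seeds, grid and package version,
and deliberately no timestamps).

```{r example, eval = FALSE}
cfg <- run_config("synthetic", seed = 42, n_per_sex = 10000,
                  grid = power_grid(-5, 5, 0.01))
report <- run_full_analysis(cfg)
report$F$new_power
write_report(report, "report_dir")
```

## Validation strategy and problem sizes

The test suite validates each operation against an independent oracle
computed by a different route: two-stage OLS residual regression for the
partial-correlation recursion; O(n²) pair counting and logistic-model ROC
for AUC; exhaustive candidate scans for Youden cutoffs; hand-computed
risk-set products, finite-difference score checks and an independent Cox
implementation for the survival fitter; and sort-and-count quantile
computations for category mapping and strata.

Ground-truth recovery of the scaling exponent is checked at two levels:
noise-free cohorts recover p_true exactly at grid resolution, and for
p_true ∈ {1.0, 1.5, 2.0, 2.5} the estimator on cohorts of n = 50,000 over
20 seeds shows |bias| ≤ 0.05 and SD ≤ 0.05 against the population optimum
computed by a million-subject brute-force scan. These problem sizes — 50,000
subjects for estimator studies, 100,000 for marginal calibration, 20,000
per replicate for survival coverage — were chosen as the smallest scales at
which Monte-Carlo error is well below the tolerances being asserted.

## Known limitations

* The generator calibrates marginals, not the full dependence structure;
  correlation magnitudes from any real cohort are not reproduced, only the
  structural behavior of the curves.
* The mortality process has a constant baseline hazard and log-linear
  age/index effects; no frailty, no competing risks, no time-varying
  effects.
* Reclassification depends on the documented quantile-matching convention
  for new-scale category thresholds; other conventions (e.g., refitting
  prevalence-matched cutoffs) would give different percentages.
* The height-independency optimum is reported at grid resolution (0.01);
  no sub-grid interpolation is attempted.
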