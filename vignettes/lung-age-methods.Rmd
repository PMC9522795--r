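---
title: "Lung age from spirometry: models, normal limits, and the synthetic cohort generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lung age from spirometry: models, normal limits, and the synthetic cohort generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The lung-age idea

Spirometry reports many numbers (FEV1, FVC, mid-expiratory flows) that are
hard for patients to interpret. *Lung age* compresses them into one: the
chronological age at which an individual's spirometric values would be
average for a healthy never-smoker. The package estimates lung age by
*backward age regression*: in a healthy reference cohort, chronological age
is the response and spirometric indices plus height are the predictors,

\[
\widehat{\mathrm{age}} \;=\; \beta_0 + f(\mathrm{FEV}_1) +
\beta_h\,\mathrm{height} + \beta_{50}\,\mathrm{FEF}_{50\%} +
\beta_{75}\,\mathrm{FEF}_{75\%} \;(+\dots),
\]

fitted separately by sex. The difference between lung age and
chronological age, `delta = lung_age - age`, is the clinically used
quantity: positive values mean lung function below the healthy average
for that age.

Three families encode the FEV1 effect `f`:

* **mlr** — a single linear coefficient;
* **piecewise** — one continuous breakpoint, chosen by minimum residual
  sum of squares over a grid of FEV1 quantiles (5th–95th percentile,
  step 1 percentile by default). The breakpoint enters through a hinge
  term, so continuity holds by construction;
* **spline** — a natural cubic spline, default 3 interior knots at the
  quartiles of the fitting sample's FEV1 and boundary knots at its
  5th/95th percentiles.

`lung_age_select()` fits every candidate (predictor subset × family ×
sex) and keeps the model with the highest adjusted R². Exact ties break
towards fewer parameters, then the fixed family order mlr, piecewise,
spline, so selection is deterministic. `bootstrap_validate()` refits the
chosen recipe on subject-level resamples (default B = 1000) with spline
knots held fixed at the primary model's knots so replicate coefficients
are comparable.

### The spline basis

`natural_spline_basis()` builds the natural cubic spline design from
cubic B-splines (Cox–de Boor recursion, written here with derivative
support) with the two second-derivative constraints at the boundary
knots projected out by a QR step; evaluation outside the boundary knots
extrapolates linearly, which is the defining property of the natural
spline. This matters clinically: severe patients have FEV1 far below the
healthy 5th-percentile boundary knot (down to ~0.6 L), and the model is
*meant* to extrapolate there — predictions are never clamped, only
flagged with a warning. `truncated_power_basis()` spans the same function
space via truncated power functions and exists purely as an independent
test oracle; the suite requires OLS fits on the two bases to agree within
1e-8. The number and location of the published equation's knots live in
supplementary material of the source publication and are not bundled, so
`published_lung_age_model()` refuses to predict unless the user supplies
both the knots and the spline coefficients — a silently wrong clinical
number is worse than an error.

## Normal limits of delta lung age

Because healthy delta lung age drifts with age, a constant cut-off is
not ideal. `uln_fit()` regresses delta on age in healthy subjects (sexes
pooled — the source analysis found no sex difference in delta) and sets

\[
\mathrm{ULN}(\mathrm{age}) = \hat\alpha + \hat\beta\,\mathrm{age} +
z \cdot \mathrm{RSE}, \qquad z = 1.645 \text{ (one-sided 95\%) by default.}
\]

The published rule of this form is `12.243 - 0.323*age + 1.645*7.037`;
it crosses zero near age 74 and negative ULN values are reported as-is,
because suppressing them would change the published rule. The symmetric
lower limit (`fit - z*RSE`) is available but off by default: the
clinical interest is in lung ages *older* than the chronological age.
`derive_constant_uln()` gives the alternative constant rule — the 95th
percentile of healthy deltas by interpolated order statistics.

`classify_delta()` applies the three-way interpretation: `consistent`
(delta ≤ 0), `older_within_uln` (0 < delta ≤ ULN; the lung age rather
than the chronological age should then be quoted, so the subject knows
their function is below average), and `above_uln`. A delta exactly at
the limit counts as within. `gold_stage()` stages airflow limitation on
FEV1 percent predicted with half-open bands [80, ∞), [50, 80), [30, 50),
(0, 30); the stage-IV band is *below* 30%, the staging convention, which
also matches the printed stage-IV cohort mean of ~24%.

## Cohort handling

`healthy_inclusion_filter()` applies the healthy-cohort entry rules (age
18–80, BMI ≤ 30 kg/m², never-smoker, FEV1/FVC/ratio/MMEF within normal
limits). The normal-limit judgement depends on external reference
equations, so it is consumed as precomputed boolean flags and never
computed internally. `propensity_match()` balances patient and healthy
groups on age, height and sex: logistic propensity model,
nearest-neighbour matching on the logit without replacement, greedy in a
seeded random case order, caliper 0.2 SD of the logit. These specifics
are our choices — the matching method is named but not specified in the
source — and all are configurable.

## What the synthetic generator emulates

`builtin_profiles()` carries twelve profiles transcribed from the
printed cohort summaries: healthy modelling (n = 2931) and validation
(n = 478) groups, the two matched healthy comparison groups, and
COPD/asthma stages I–IV. Records are drawn as follows.

* Age is truncated-normal on [18, 80] ([40, 80] for COPD), with the
  underlying parameters solved so the *truncated* mean and SD equal the
  printed ones.
* Height is a two-component normal mixture (sex gap 8 cm) whose pooled
  mean and SD equal the printed ones; weight is BMI × height², with a
  truncated-normal BMI solved to reproduce the printed weight mean and
  SD while keeping healthy BMI ≤ 30 by construction.
* A latent lung-function level `L` combines a *youth score* (the
  quadratic age severity `(age - 25)^2`, i.e. a peak in the mid-20s,
  passed through its own probability transform so `L` is exactly
  standard normal), within-sex height, and idiosyncratic noise, with
  weights 0.82 / 0.25 / 0.51. Each spirometric index couples to `L`
  through a Gaussian copula (loadings: FVC and FEV1 0.85, FEF50 and
  MMEF 0.80, percent predicted 0.20) and keeps an exactly calibrated
  marginal: normal for volumes and percent predicted, gamma for the
  flows (printed SDs can exceed printed means in severe asthma, which a
  positive gamma marginal absorbs gracefully).
* FEF75 is FEF50 times an independent truncated-normal factor in
  (0.02, 0.95), which enforces FEF50 > FEF75 on every record and makes
  the FEF75 mean exact.
* The FEV1/FVC ratio is *derived* per record (so the record-level
  consistency invariant holds exactly); a solved latent FEV1–FVC
  correlation brings the cohort ratio mean as close to the printed value
  as the printed component means permit. For several patient groups the
  printed triple (FEV1, FVC, ratio means) is mutually inconsistent —
  e.g. stage I COPD prints 2.46/3.87 = 0.636 against a ratio of 0.63 —
  and the generator prioritizes the FEV1 and FVC means.
* Patient percent predicted is truncated-normal *inside* the stage band
  with parameters solved for the printed stage mean/SD, so band
  membership is guaranteed. The printed stage-III SDs (6.31 and 5.86 on
  a band of width 20) exceed what any truncated normal on that band can
  reach (the uniform limit, 5.77); the solver then matches the mean
  exactly and records the SD shortfall on the profile.

The rank-gaussianized youth score replaces a literal polynomial mean
function: it keeps the nonlinear, peak-then-decline age signal that
makes the spline family genuinely better than a straight line, while
letting every calibrated cohort mean be exact under the copula. What the
generator does **not** emulate: longitudinal decline, smoking exposure,
between-index correlations beyond the single latent level, per-sex
spirometry offsets beyond height, and any dependence between a patient's
stored percent-predicted value and an actual external reference
equation (percent predicted is an input column throughout the package,
never recomputed). Passing tests therefore show that the *pipeline* is
correct under a realistic data-generating law, not that the fitted
synthetic coefficients equal the published ones — the real cohorts are
not distributed, and the published real-data statistics (adjusted R²
0.660/0.689, RSE 8.693/8.544, constant ULN 12.5 y, the exceedance
table counts) are treated as reference documentation only.

## Numerical choices and problem sizes

Quantiles are always type-7 (linear interpolation between order
statistics): knot placement, breakpoint grids, constant ULN, bootstrap
summaries. Coefficient intervals are t-based 95%. Degenerate inputs
fail loudly: indistinct knots, rank-deficient designs (naming the
collinear columns), constant ages in the ULN regression, non-positive
percent predicted in staging, numeric sex codes in record files.
Truncated-normal calibrations are solved by bounded quasi-Newton
optimization on closed-form moments; the FEV1–FVC latent correlation by
25-node Gauss–Hermite quadrature. Model files are JSON at 17 significant
digits, which round-trips doubles bit-exactly (write → read → write is
byte-identical).

The test-suite and acceptance-script problem sizes are chosen to make
the statistical checks sharp but quick: oracle equivalence on 50 random
instances of n = 200; ULN parameter recovery at n = 1e5 (within 3
standard errors of the generating values); ULN coverage at n = 3000
(5% ± 1.5%); the spline-vs-linear method comparison on 100 replicates of
train n = 2000 / held-out n = 600 from the same generating law (the
validation *profile* emulates a different population, where transfer
error dominates the family difference); stage-pattern checks on a
healthy cohort of n = 2931 with staged cohorts of n = 300; generator
calibration at n = 1e4 against 3·SD/√n.

## Known limitations

* The published equation cannot be evaluated without its supplementary
  spline specification; the package hosts it but will not guess it.
* Selection between the piecewise and spline families on synthetic
  quadratic-age data is genuinely close (the inverse age-on-FEV1 curve
  is near a hinge); the package's selection contest therefore
  demonstrates nonlinear-vs-linear superiority, mirroring the source's
  qualitative claim, rather than spline-vs-piecewise dominance.
* Bootstrap validation holds spline knots fixed across replicates;
  knot-placement variability is not propagated.
* Propensity matching is greedy nearest-neighbour; optimal matching and
  weighting are out of scope.
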