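---
title: "Volume-dependent agreement limits for multi-observer tumor volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volume-dependent agreement limits for multi-observer tumor volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volagree)
```

## The problem

Vestibular schwannomas under wait-and-scan management are followed with serial
MRI, and treatment is triggered when the tumor "grows". A widely used
volumetric growth criterion is a 20% increase. Whether a 20% change is real,
however, depends on how much two annotations of the *same* tumor differ
between observers — and that disagreement is not a single number: small tumors
are annotated with much larger relative error than large ones. `volagree`
quantifies this volume dependence and turns it into per-tumor growth cutoffs.

## The model

For subject $i = 1, \dots, n$ annotated by observer $j = 1, \dots, m$ the
observed volume is modelled as

$$ Y_{ij} = \mu + a_i + b_j + e_{ij}, $$

with subject effects $a_i$, systematic observer offsets
$b_j \sim N(0, \sigma_O^2)$ (rater bias), and residual annotation error
$e_{ij} \sim N(0, \sigma_R^2)$. The balanced two-way ANOVA without
interaction gives mean squares for subjects, observers and residuals
(`anova_mean_squares()`), from which the method-of-moments components are

$$ \hat\sigma_R^2 = MS_R, \qquad
   \hat\sigma_O^2 = \max\!\left(0, \frac{MS_O - MS_R}{n}\right). $$

A negative raw observer component — expected when the true value is near zero
and $m$ is small — is truncated to zero and flagged
(`observer_truncated`); the raw value is retained for diagnostics.

### Limits of agreement with the mean

The LOAM asks: how far may a single observer's measurement deviate from the
mean of all $m$ observers' measurements of the same subject? Under the model,

$$ \operatorname{Var}(Y_{ij} - \bar Y_{i\cdot}) =
   \frac{m-1}{m}\left(\sigma_O^2 + \sigma_R^2\right), $$

so the half-width is
$\mathrm{LOAM} = z \sqrt{\tfrac{m-1}{m}(\hat\sigma_O^2 + \hat\sigma_R^2)}$
with $z = \Phi^{-1}(0.975) = 1.959964$ by default (the exact quantile rather
than a rounded 1.96, so that CI mappings stay consistent; the difference is
invisible at reporting precision). The exact finite-$m$ factor $(m-1)/m$ is
applied by default and can be disabled (`finite_correction = FALSE`) for
sensitivity analysis against the infinite-observer convention. LOAM% is the
half-width as a percentage of the group mean volume.

### Confidence intervals

Three interval constructions are used, each chosen to be closed-form where a
good closed form exists and validated by simulation where it does not:

* **LOAM.** $\psi = \sigma_O^2 + \sigma_R^2 = \tfrac{1}{n} MS_O +
  \tfrac{n-1}{n} MS_R$ is a positive linear combination of independent mean
  squares, so its modified large-sample (Graybill–Wang) interval applies
  directly and is mapped through $z\sqrt{\tfrac{m-1}{m}\,\psi}$. The interval
  is asymmetric about the point estimate. Empirical coverage over 1000
  simulated 26×5 cohorts at known components is checked in the test suite and
  sits within 0.93–0.97.
* **Component SDs.** No convenient closed form covers the truncated
  $\hat\sigma_O$; a seeded parametric bootstrap (default 10,000 resamples)
  redraws both mean squares as scaled $\chi^2$ variables from the fitted
  model and takes percentile intervals on the SD scale. Truncation propagates
  into zero lower bounds, matching how near-zero observer variance presents
  in practice. Bootstrap coverage for $\hat\sigma_R$ is simulation-checked as
  well.
* **ICC.** The intraclass correlation is the two-way random, absolute
  agreement, single measure form
  $\mathrm{ICC} = (MS_S - MS_R)/(MS_S + (m-1)MS_R + \tfrac{m}{n}(MS_O - MS_R))$,
  with the standard F-based interval using Satterthwaite denominator degrees
  of freedom.

## Stratification and the sliding window

Subjects are stratified into quartiles I–IV of *average observed* volume using
contiguous rank blocks (`stratify_quartiles()`), which guarantees exact
25/25/25/25 splits at $n = 100$; remainders go to the lowest strata first and
ties keep input order. The cyst-exclusion sensitivity analysis
(`stratum_report(exclude_cysts = TRUE)`) drops cyst-flagged subjects *within*
their full-cohort stratum rather than re-stratifying, so excluded rows remain
comparable to their inclusive counterparts.

The sliding window (`window_curve()`, default width 26 — deliberately the
reliability sample size, so every window is itself adequately powered) moves
one subject at a time through the volume-ordered cohort and produces a
continuous LOAM%-versus-volume curve. Two operations sit on top:

* `threshold_crossing()` finds where the curve falls to a threshold (20% by
  default). The default *persistent* rule requires all larger-volume windows
  to satisfy the threshold too, because the raw curve is noisy and a single
  transient dip should not define a clinical cutoff; first-touch is available
  as an option. The crossing is interpolated linearly in log-volume.
* `loam_lookup()` is the per-tumor calculator: piecewise-linear interpolation
  of LOAM% and its CI bounds against log volume, clamped (and flagged) outside
  the curve's range. Log-volume interpolation is the least surprising monotone
  choice for a quantity spanning two orders of magnitude.

## Covariate regression

`covariate_regression()` regresses the per-subject relative volume SD
(SD$_{V\%}$ = 100·SD/mean over the $m$ annotations, sample SD with the
$m - 1$ denominator, the default of mainstream statistical software) on each
imaging parameter and tumor characteristic singly, then jointly on those with
univariable $p < 0.05$. Complete cases are used per model; laterality is
coded L = 0 / R = 1, cysts no = 0 / yes = 1, field strength is numeric in
tesla, and acquisition dates become decimal years. No multiplicity
correction is applied, matching common practice for this kind of exploratory
covariate screen.

## Sample size by the CI lower-limit procedure

`required_sample_size()` returns the smallest $n$ such that the one-sided
$(1-\alpha)$ lower confidence limit of the one-way random-effects ICC exceeds
the minimum acceptable value $\rho_0$ with probability `power`, when the true
ICC is $\rho$. With $\theta = \rho/(1-\rho)$ the assurance is exact:

$$ P\left( F_{n-1,\,n(m-1)} >
   \frac{1 + m\theta_0}{1 + m\theta} F_{1-\alpha;\,n-1,\,n(m-1)} \right). $$

The one-way model with a one-sided limit is the combination under which the
conventional design ($\rho = 0.9$, $\rho_0 = 0.8$, power 0.8, $\alpha = 0.05$,
$m = 5$) requires exactly 26 subjects; the package documents this choice
explicitly since "CI lower-limit procedure" is used loosely in the reliability
literature. The exact F form was preferred over a normal approximation
because it is deterministic and directly checkable by simulation (the test
suite confirms the analytic assurance against 10,000 simulated one-way ICC
experiments).

## The synthetic cohort generator

Because multi-observer annotation datasets are rarely shareable, every stage
is exercised against `generate_cohort()`, whose defaults *are* the study
conditions the package targets:

* True volumes $V_i$ are log-normal with median 903 mm³ and log-SD 2.06
  (chosen so the quartile ratio matches an IQR of 193–3101 mm³), redrawn into
  20–40,000 mm³. The truncation reflects anatomy — vestibular schwannomas do
  not reach liter scale — and keeps the extreme tail from dominating
  leverage in the volume regression; the sample median stays within ~5% of
  903 mm³.
* Measurements are $Y_{ij} = V_i + (b_j + e_{ij})\,V_i^{\gamma}$ with
  $b_j \sim N(0, \tau_O^2)$, $e_{ij} \sim N(0, \tau_R^2)$,
  $\tau_O = 0.225$, $\tau_R = 0.674$, $\gamma = 2/3$. The additive error
  scaled by $V^{\gamma}$ — rather than multiplicative log-normal error —
  reproduces the central empirical phenomenon (relative limits fall with
  volume) with one interpretable exponent; $\gamma = 2/3$ is surface-area
  scaling, appropriate when annotation error accrues on the tumor boundary.
  Under this model LOAM% has the closed form
  `analytic_loam_percent()` $= 100\,z\sqrt{\tfrac{m-1}{m}(\tau_O^2+\tau_R^2)}\,
  V^{\gamma-1} \approx 124.6\,V^{-1/3}$: 26.8% at 100 mm³, crossing 20% at
  241.6 mm³. The constants were calibrated once against that quartile-I-scale
  behaviour and are defaults, not truth claims.
* A fraction (default 12%) of top-volume-half subjects carry a peritumoral
  cyst that doubles their residual SD. The cyst-effect magnitude is a free
  parameter — no quantitative model for it exists — and the closed-form curve
  deliberately excludes it, which is why oracle comparisons of stratum
  estimates against `analytic_loam_percent()` are run through the package's
  cyst-exclusion path.
* Imaging covariates are volume-linked only through the confounding map:
  3.0 T assignment is logistic in log-volume (slope 1.2 around 3000 mm³),
  and echo time, slice thickness and slice spacing follow field strength
  with independent noise; everything else is noise. Covariates therefore
  influence SD$_{V\%}$ *only through volume*, so the qualitative regression
  signature — imaging parameters significant univariably, only volume (with
  a negative slope) surviving adjustment — is a structural property of the
  generator, not of a particular seed. The test suite checks it as aggregate
  fractions over 24 seeds rather than seed-by-seed, since with $n = 100$ any
  single seed can produce a borderline p-value.

What the generator does **not** emulate: image-level segmentation behaviour,
intra-observer repeat measurements, longitudinal growth, non-Gaussian error
(e.g. occasional gross mis-annotations), and correlation between observer
bias and tumor volume. Passing tests therefore demonstrate that the
statistical machinery is correct and well calibrated under the stated model,
not that real annotation error follows a $V^{2/3}$ power law.

## Numerical choices and edge cases

* Problem sizes in the test suite were chosen as the smallest that make the
  Monte-Carlo assertions stable: 1000 replicates for CI coverage, 24 seeds
  for the regression signature, $n = 1000$ cohorts for curve-vs-closed-form
  comparisons.
* Degenerate inputs: a fully constant grid has undefined ICC (explicit
  error); zero error scales give LOAM = 0, ICC = 1, and a null CI; strata
  emptied below two subjects by cyst exclusion are skipped with a warning;
  missing volume cells are a hard error naming the cell, while missing
  metadata is preserved and handled complete-case in regression.
* All randomness (generator, bootstrap) is seeded explicitly; RNG state is
  restored via `withr`, so library calls never perturb a user's stream.

## Worked example

```{r example}
cfg <- synthetic_config(seed = 1)
cohort <- generate_cohort(cfg)
stratum_report(cohort, n_boot = 2000, seed = 1)[
  , c("stratum", "mean_volume", "loam_pct", "loam_pct_lo", "loam_pct_hi", "icc")]

curve <- window_curve(cohort, width = 26)
threshold_crossing(curve, 20, bound = "point")
loam_lookup(curve, c(150, 1500))
```

## Limitations

The LOAM machinery assumes a complete balanced grid (every observer annotates
every subject); incomplete designs need mixed-model extensions that are out
of scope. The MLS interval treats mean squares as independent scaled
chi-squares, exact under normal errors only. The sliding-window curve is an
estimator, not a smoother: neighbouring windows share $w - 1$ subjects, so
its pointwise CIs are strongly dependent along the volume axis.
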