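# volagree

Inter-observer agreement analysis for tumor volumetry with several
observers, built around vestibular schwannoma (VS) follow-up: when the same
tumor is volumetrically annotated by different people, how large a volume
change can be trusted as real growth — and how does that answer depend on
tumor size?

The package is for imaging researchers and biostatisticians who have (or
simulate) a complete grid of volumes, one measurement per subject and
observer, and want agreement limits, their drivers, and per-tumor growth
cutoffs.

## The statistics

For subject *i* and observer *j* the model is
`Y_ij = mu + a_i + b_j + e_ij`, with systematic observer offsets
`b_j ~ N(0, sigma_O^2)` and residual annotation error
`e_ij ~ N(0, sigma_R^2)`. From the balanced two-way ANOVA the package
computes:

- **LOAM**, the limits of agreement with the mean (multi-observer
  generalization of Bland–Altman limits):
  `LOAM = z * sqrt((m-1)/m * (sigma_O^2 + sigma_R^2))`, absolute (mm³) and
  as a percentage of the group mean, with modified large-sample
  (Graybill–Wang) confidence intervals;
- the **variance decomposition** `sigma_O` vs `sigma_R` with parametric
  bootstrap CIs (negative observer components truncated to zero and
  flagged);
- the **ICC** (two-way random, absolute agreement, single measure) with
  F-based CIs;
- **volume-quartile reports** with a peritumoral-cyst exclusion
  sensitivity analysis;
- a **sliding-window LOAM curve** over the volume-ordered cohort, the
  volume at which it crosses the conventional 20% growth criterion, and a
  per-tumor `loam_lookup()` calculator;
- **covariate regression** of the relative volume SD (SD_V%) on imaging
  parameters and tumor characteristics, univariable and adjusted;
- the **reliability sample size** by the ICC confidence-interval
  lower-limit (assurance) procedure — 26 subjects at the conventional
  design (rho 0.9 vs rho0 0.8, power 0.8, alpha 0.05, 5 observers);
- a calibrated **synthetic cohort generator** whose closed-form agreement
  curve (`~124.6 * V^(-1/3)` % at the defaults) serves as an oracle for
  validation.

## Worked example

```r
library(volagree)

cfg <- synthetic_config(seed = 1)        # 100 subjects x 5 observers
cohort <- generate_cohort(cfg)

loam_result(cohort, n_boot = 2000, seed = 1)
#> <loam_result> n = 100 subjects, m = 5 observers
#>   mean volume : 3080 mm^3
#>   LOAM        : +/- 333.3 mm^3 (312-370); 10.8% (10.1-12) of mean
#>   sigma_O     : 22.4 mm^3 (0-44.3)
#>   sigma_R     : 189 mm^3 (175-202)
#>   ICC(A,1)    : 0.999 (0.998-0.999)
```

A single observer's annotation of an average tumor in this cohort may
deviate up to ±10.8% from the all-observer mean; almost all of that error
is residual (`sigma_R`) rather than systematic rater bias (`sigma_O`).
Stratifying by volume quartile shows the strong size dependence:

```r
stratum_report(cohort, n_boot = 2000, seed = 1)[
  , c("stratum", "mean_volume", "loam_pct", "loam_pct_lo", "loam_pct_hi", "icc")]
#>   stratum mean_volume loam_pct loam_pct_lo loam_pct_hi    icc
#> 1       I       167.6   22.460      19.699      26.672 0.9452
#> 2      II       658.2   14.305      12.449      16.642 0.9425
#> 3     III      2061.6   12.391      10.769      14.372 0.9552
#> 4      IV      9431.4    6.452       5.702       8.419 0.9973
```

Small tumors (quartile I) carry ~22% agreement limits — larger than the
conventional 20% growth cutoff — while the largest quartile is near 6%.
The sliding-window curve makes that continuous and invertible:

```r
curve <- window_curve(cohort, width = 26)
threshold_crossing(curve, 20, bound = "point")
#> [1] 385.5757           # mm^3 where the estimated LOAM% falls below 20%
loam_lookup(curve, c(150, 1500))
#>   volume loam_pct ci_low ci_high extrapolated
#> 1    150     23.4   20.7    28.6 TRUE
#> 2   1500     13.3   11.7    15.8 FALSE
```

So for a 1500 mm³ tumor of this cohort, growth beyond ~13% already exceeds
inter-observer disagreement, whereas a 150 mm³ tumor needs ~23%.
`run_full_analysis(cfg, "out/")` writes all tables, figures and a
provenance log in one call; `inst/cli/volagree` exposes `simulate`,
`analyze`, `loam-calc` and `samplesize` subcommands for shell use.

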