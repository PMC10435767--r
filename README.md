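# glycanclock

Analysis pipeline for IgG N-glycan biological-ageing ("glycan clock")
studies in case-control cohorts, with a synthetic-cohort generator that
gives every stage a testable ground truth.

## The problem

IgG N-glycosylation changes with age in a strikingly reproducible way:
agalactosylated glycans (G0) rise, digalactosylated (G2) and sialylated (S)
glycans fall. In a case-control design — the motivating application is
adults with Down syndrome (DS, trisomy 21) versus age/sex-matched euploid
controls across three European cohorts — two quantities matter:

* the **standardized group effect** per derived trait, pooled across
  cohorts by fixed-effects meta-analysis of rank-inverse-normal
  transformed values;
* the **glycan-age shift**: with linear per-group age trends
  `y = a·age + b`, the horizontal offset

  ```
  Δ(x) = (a_DS·x + b_DS − b_ctrl) / a_ctrl − x
  ```

  is the number of years by which cases' glycomes look older than
  same-aged controls. A group×age interaction test checks whether the
  *rate* of glycan ageing differs (parallel slopes say it does not).

The package covers the full path from raw UHPLC peak tables (GP1–GP24,
% of total chromatogram area) to these estimates: total-area
normalization, log transform, empirical-Bayes (ComBat-model) plate
correction, GP20/GP21 exclusion, derived traits (G0/G1/G2/S/F/B),
rank-INT, per-cohort GLMs and sibling-paired mixed models, fixed-effects
pooling with Benjamini–Hochberg control, per-group trend fits, the age
shift with bootstrap CIs, and PCA placement of singleton samples
(nearest-centroid in PC1–PC3).

`simulate_cohort()` / `simulate_children()` / `simulate_study()` generate
cohorts with the study's structure (sizes, age ranges, plates, sibling
pairs, compositional closure) and known ground truth; `run_pipeline()`
chains everything end to end.

## Worked example

```r
library(glycanclock)

run <- run_pipeline(seed = 1)
run$summary
#> # A tibble: 1 × 5
#>    seed n_samples combined_shift_G0 combined_shift_G2 singleton_assigned
#>   <dbl>     <int>             <dbl>             <dbl> <chr>
#> 1     1       482              19.2              14.1 DS

run$association$meta
#> # A tibble: 6 × 7
#>   trait   beta     se     z        p     k        q
#>   <chr>  <dbl>  <dbl> <dbl>    <dbl> <int>    <dbl>
#> 1 G0     0.787 0.0579 13.6  5.19e-42     3 3.11e-41
#> 2 G1    -0.231 0.0977 -2.36 1.80e- 2     3 2.71e- 2
#> 3 G2    -0.594 0.0743 -8.00 1.28e-15     3 3.83e-15
#> 4 S     -0.221 0.0972 -2.28 2.29e- 2     3 2.75e- 2
#> 5 F     -0.124 0.0992 -1.25 2.12e- 1     3 2.12e- 1
#> 6 B     -0.346 0.0894 -3.87 1.10e- 4     3 2.20e- 4

run$clock$G0$report[, c("cohort", "slope_control", "slope_ds",
                        "interaction_p", "shift_mean")]
#> # A tibble: 3 × 5
#>   cohort slope_control slope_ds interaction_p shift_mean
#>   <chr>          <dbl>    <dbl>         <dbl>      <dbl>
#> 1 FRA            0.420    0.428        0.875        12.1
#> 2 ITA            0.277    0.365        0.148        17.5
#> 3 UK             0.275    0.390        0.0389       27.9
```

Reading this: 482 simulated adults (three cohorts, default parameters)
show a pooled G0 elevation of 0.79 rank-INT SD units in the case group;
per-cohort G0 trends are near-parallel between groups (no consistent
interaction), and mapping the case lines onto the control lines puts the
case glycome 12–28 years "older" depending on cohort, 19.2 years on
average here. The simulated segmental-duplication child projects into the
DS cluster of the children's PCA. Plots: `plot_trend_curves(data, "G0")`,
`autoplot(run$clock$G0$shifts$FRA)`, `autoplot(pca, groups = ...)`.

Single stages compose with the pipe:

```r
sim <- simulate_study(seed = 1)
traits <- sim$peaks |>
  normalize_total_area() |>
  log_transform_peaks() |>
  batch_correct(sim$meta) |>
  exclude_peaks() |>
  derived_traits()
associate_cohorts(traits, sim$meta)$meta
```

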