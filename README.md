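# biotraj

Long-term trajectories of biofluid biomarkers in Parkinson's disease,
estimated from short longitudinal follow-up by integrating the relation
between a marker's level and its annual change rate.

## The problem and the method

Cohorts such as PPMI follow each patient for 5–7 years, but CSF
amyloid-beta 1-42, alpha-synuclein, total and phosphorylated tau and
serum neurofilament light chain (NfL) evolve over decades. `biotraj`
implements the trajectory-estimation approach in which the short
per-subject windows are treated as local samples of a single population
dynamic:

1. each subject-marker series is fitted by OLS (disease duration as
   predictor), giving an annual change rate and an extrapolated level
   at motor onset;
2. the rates are modelled as a **restricted cubic spline** function of
   baseline level — 4 knots at the 5/35/65/95th percentiles (3 knots at
   5/50/95 when a cell has under 100 subjects) — yielding the
   right-hand side *f* of the autonomous ODE *dX/dt = f(X)*;
3. the ODE is integrated with the **modified Euler (Heun) method** from
   the group's mean onset level, backward to −5 and forward to +30
   years from motor onset;
4. control trajectories are anchored in age space at the median control
   baseline age and re-indexed by *duration = age − median PD age at
   onset*; z-scores use the control baseline mean and SD.

The package also provides the cohort rules (≥ 2 measurements per
series; hemoglobin < 200 ng/mL for CSF alpha-synuclein samples; 3×IQR
baseline-outlier and mean ± 4 SD cognitive-outlier exclusion; PDCU/PDCI
split at MoCA > 25; high/low amyloid split at 683.45 pg/mL), a
synthetic PPMI-like cohort generator with known ground-truth dynamics,
and a deterministic pipeline with TSV/JSON outputs. See the vignette
`vignettes/trajectory-estimation.Rmd` for the full model description.

## Worked example

```r
library(biotraj)

res <- run_pipeline("synthetic", pipeline_config(),
                    cohort_config(seed = 20210720L),
                    out_dir = "biotraj_output")

res$summary$abeta$pd$percent_change_0_30
#> [1] -6.991915
res$summary$abeta$pd$rate_roots
#>      level stability
#> 1 798.1818    stable
res$summary$nfl$pd$percent_change_0_30
#> [1] 153.962
```

This generates the default synthetic cohort (396 PD, 182 controls,
6-monthly visits to 72 months, dropout, planted blood-contaminated
alpha-synuclein samples), applies the filter chain, and estimates
trajectories for every marker and stratum. Here the estimated CSF
amyloid-beta 1-42 level in PD declines by about 7% over the 30 years
after motor onset and its annual change crosses zero at ~798 pg/mL — a
stable plateau, recovering the generator's configured truth (plateau
800 pg/mL); serum NfL rises by ~154% (configured sigmoid truth +160%).
Outputs under `biotraj_output/` include the exclusion report
(`filter_report.tsv`), per-subject kinetics, fitted rate curves and
models, trajectories with z-scores, and a JSON summary with percent
changes, rate-curve roots and crossing times. Identical configuration
and seed reproduce every file byte for byte.

A thin CLI over the same functions is installed at
`system.file("cli", "biotraj.R", package = "biotraj")`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/biotraj.R", package="biotraj"))')" \
  all --seed 7 --out run1
```

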