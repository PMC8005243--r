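# grayzonePET

Dual-cutoff quantification of early amyloid-beta deposition on amyloid PET.

## What this is for

Single SUVR thresholds for amyloid PET are tuned to separate AD dementia
from elderly controls and miss the earliest phase of amyloid accumulation.
`grayzonePET` implements, for analysts working with regional florbetaben
SUVR tables, a two-cutoff framework that names that phase explicitly:

* **early cutoff** `SUVR_early = mean(yHC) + 2·SD(yHC)` per region, from
  young (20–40 y) cognitively normal controls;
* **established cutoff** `SUVR_estab` per region from ROC analysis
  (maximum Youden index `J = sensitivity + specificity − 1`, ties broken
  toward higher specificity) of visually negative elderly controls versus
  visually positive AD dementia;
* the **gray zone** `SUVR_early ≤ SUVR ≤ SUVR_estab`, read as emerging
  amyloid pathology.

Around this classification the package provides: centiloid calibration
(`CL = 153.4·SUVR − 154.9`) with transfer validation; ΔSUVR topographic
staging against the half-capacity point of a logistic accumulation
trajectory (`ΔSUVR = SUVR − (SUVR_yHC + SUVR_AD)/2`); per-subject
accumulation rates (`SUVR = α·t + β`, percent rate `100·α/SUVR_B`) with
category-level tests; progression and tau-association summaries; visual-
versus-quantitative concordance sweeps; a whole-population two-component
Gaussian-mixture confirmation of the cutoffs; and a seeded synthetic-cohort
generator emulating the five-dataset structure such studies use (no
subject-level data from the motivating studies is public). See the methods
vignette (`vignettes/grayzone-methods.Rmd`) for models, assumptions and
design choices.

## Worked example

Derive both cutoffs from simulated calibration cohorts, classify subjects,
and fit an accumulation rate:

```r
library(grayzonePET)
scen <- default_scenario()

# dataset 1: young controls -> early cutoffs
yhc <- generate_cross_sectional(list(
  group_spec("yHC", 65, scen$yhc$means, scen$yhc$sds,
             cl_mean = 2.82, cl_sd = 5.36)), seed = 1)
derive_early_cutoffs(yhc, regions = c("lateral_temporal", "composite"))
#>             region scale  n mean     sd early_cutoff normality_p
#> 1 lateral_temporal  suvr 65 1.09 0.0281         1.15       0.230
#> 2        composite  suvr 65 1.17 0.0436         1.26       0.749

# dataset 2: elderly controls vs AD dementia -> established cutoff
ds2 <- generate_cross_sectional(list(
  group_spec("eHC", 66, scen$ehc$means, scen$ehc$sds),
  group_spec("AD", 73, scen$ad$means, scen$ad$sds)), seed = 2)
roc <- derive_established_cutoff(
  ds2$suvr_composite[ds2$group_label == "eHC"],
  ds2$suvr_composite[ds2$group_label == "AD"])
roc
#> ROC cutoff 1.377: sensitivity 94.5%, specificity 100.0%, J 0.945, AUC 0.990

# three-category continuum
classify_amyloid(c(1.20, 1.30, 1.45), early = 1.26, estab = roc$cutoff)
#> [1] negative    gray_zone   established

# a subject scanned at baseline (SUVR 1.30) and 2 years (1.36)
fit_subject_slope(c(0, 2), c(1.30, 1.36))
#>   alpha beta value_b abeta_dep n_visits
#> 1  0.03  1.3     1.3    2.3077        2
```

The early cutoff lands at the young-control 97.7th percentile (here 1.26
composite; the published pair is 1.25/1.38); the ROC cutoff separates the
two calibration groups at near-perfect specificity; and the longitudinal
subject accumulates 0.03 SUVR/year, i.e. 2.31 %/year of its baseline —
a rate typical of the gray zone.

The whole pipeline — simulation, calibration check, cutoffs, classification,
topography, accumulation, tau, concordance, JSON report — runs as one call:

```r
report <- run_pipeline(pipeline_config(default_scenario(), seed = 1,
                                       outdir = "grayzone_out"))
```

or from a shell via the thin CLI (`inst/cli/grayzonePET.R`):

```sh
Rscript inst/cli/grayzonePET.R all --seed 1 --out grayzone_out
Rscript inst/cli/grayzonePET.R classify --early 13.5 --estab 35.7 --scale cl --out gz_cl
```

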