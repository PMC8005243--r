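---
title: "Dual-cutoff quantification of early amyloid deposition: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-cutoff quantification of early amyloid deposition: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grayzonePET)
```

## The problem

Amyloid PET is usually dichotomized: a scan is amyloid-positive or it is
not, either by expert visual reading or by a single SUVR threshold tuned to
separate AD dementia from elderly controls. Both conventions are blind to
the earliest phase of amyloid accumulation, when cortical retention has
risen above the young-adult norm but has not yet reached the burden typical
of established pathology. `grayzonePET` implements a two-cutoff framework
for this regime on regional florbetaben SUVR tables:

* an **early cutoff** per region — two standard deviations above the mean
  SUVR of young (20–40 y) cognitively normal controls, a classical
  reference-limit construction;
* an **established cutoff** per region — the ROC-optimal threshold (maximum
  Youden index) separating visually negative elderly controls from visually
  positive AD dementia patients;
* the interval between them, the **gray zone**, read as emerging amyloid
  pathology.

Everything downstream — centiloid calibration, ΔSUVR topography,
longitudinal accumulation rates, progression and tau summaries, and
visual-vs-quantitative concordance — is organized around this three-category
continuum. The pipeline starts at subject-level regional SUVR tables; all
image-domain processing (reconstruction, registration, ROI extraction) is
out of scope.

## Cutoff derivation

**Early.** For each region the cutoff is `mean + 2 * sd` over the
young-control sample, with the SD using the `n - 1` denominator (the
convention for reference limits; with n = 65 the choice of denominator moves
the cutoff only in the third decimal). A Shapiro–Wilk test is recorded per
region; departure from normality (p < 0.05) produces a warning, not a
failure, because the construction is still defined — just harder to
interpret as a 97.7th percentile.

**Established.** Candidate thresholds are the midpoints between adjacent
sorted unique pooled values, plus one candidate below the minimum and one
above the maximum. A subject is test-positive iff its value is strictly
greater than the threshold. The candidate maximizing J = sensitivity +
specificity − 1 wins; ties go to the higher specificity, remaining ties to
the larger threshold. The strict ">" convention was chosen so that a value
exactly at the established cutoff classifies as gray zone, consistent with
defining established pathology as values strictly above the cutoff. AUC is
the Mann–Whitney estimate with ties counted one half; a closed-form
binormal AUC (`auc_binormal()`) is provided as a consistency oracle when
only class moments are available.

**Classification.** `classify_amyloid()` maps a value to `negative`
(`value < early`), `gray_zone` (`early <= value <= estab`, both boundaries
inclusive) or `established` (`value > estab`). The map is total and monotone
in the value.

**Mixture confirmation.** As a reading-independent check, a two-component
univariate Gaussian mixture can be fitted to the whole-population centiloid
distribution (`fit_mixture_confirmation()`): own EM implementation with 10
seeded random restarts, a 500-iteration cap, and a collapse guard (component
means closer than 1 CL raise an error). Two cutoffs are derived from the
fit: lower-component mean + 2 SD (the early analogue) and the
posterior-equality crossing between the component means (the established
analogue). The extraction rules are explicit package conventions — mixture
literature offers several — and both numbers are reported so either can be
compared against reading-based cutoffs.

## Centiloid calibration

Cortical SUVR converts to centiloids by the published florbetaben map
`CL = 153.4 * SUVR − 154.9` (whole cerebellum reference). CL values are
never rounded internally; tables round to one decimal. A calibration
transfer is validated by OLS against a reference pair set per scale, passing
iff |slope − 1| ≤ 0.02, |intercept| ≤ 2 CL (or 0.02 SUVR) and R² ≥ 0.98.
These numeric thresholds are this package's operationalization of the
standard transfer criteria; they are configurable, and they were chosen so
that a transfer of the canonical published quality (slope 1.01, intercept
−0.01, R² 0.998) passes.

## ΔSUVR topography

Regional SUVRs cannot be compared directly across regions — non-specific
binding and dynamic range differ. The package assumes regional amyloid
accumulation follows a logistic trajectory
`SUVR(t) = NS + K / (1 + exp(-r (t − T50)))` and anchors its two free
asymptotic parameters cross-sectionally: NS at the visually negative
young-control regional mean and NS + K at the visually positive AD regional
mean. The half-capacity point is then the midpoint of the two anchors, and
`ΔSUVR = SUVR − (SUVR_yHC + SUVR_AD) / 2` is comparable across regions:
a region whose ΔSUVR turns non-negative at a lower position on the composite
continuum accumulates earlier. Growth rate `r` and onset time `T50` are
deliberately *not* fitted — individual positions in accumulation time are
unobservable in cross-sectional data.

The onset ranking needs a numeric estimator of "where a region first
crosses zero", which heat-map inspection does not provide. The package's
convention: among the subjects with non-negative regional ΔSUVR, take the
lowest decile by composite SUVR and report their median composite as the
crossing position; regions that never cross rank last and are flagged. The
estimator is deliberately rank-based and resistant to single outliers; it is
configurable in the sense that the ΔSUVR matrix is exposed and any other
estimator can be applied to it. Amygdala, thalamus and striatum are excluded
from interpretation (limited dynamic range). Ties keep the canonical region
order (stable sort).

## Longitudinal accumulation

Per subject, `value = α t + β` by OLS over that subject's visits (with two
visits this is the difference quotient). The percent deposition rate is
`100 α / SUVR_B` with `SUVR_B` the *observed* baseline value, not the fitted
intercept — the definition follows the baseline-scan reading of the rate; a
switch to the fitted intercept is a one-line change in `fit_subject_slope()`
callers since both are returned. Group summaries per amyloid category report
mean ± SD, a one-sample one-sided t-test of mean rate > 0, and a Welch
unequal-variance one-sided test against the negative category (Welch because
category variances differ visibly in the published tables and nothing in the
source fixes the test variant). Categories under `min_n = 3` subjects are
suppressed as not-available. No multiple-testing correction is applied —
none is described for the original analyses — and the p-values should be
read accordingly.

Progression summaries count 4-year progression labels per baseline category
and report exact and integer-rounded percentages.

## Tau association

Spearman rank correlation (average ranks) links amyloid burden (composite
SUVR and CL) to regional flortaucipir SUVR. Category comparisons report tau
mean ± SD per amyloid category and a contrast against the negative
category. The source material is internally inconsistent about this
contrast's test (t-test in one place, ANOVA in another); the package
defaults to the one-sided Welch t-test and offers `test = "anova"`, and this
divergence is surfaced here rather than silently resolved.

## Visual concordance

Consensus is the majority of an odd panel of independent binary reads.
Sweeping a cutoff over the observed value range (default 100 evenly spaced
points) and dichotomizing with the same strict ">" convention yields
sensitivity, specificity and agreement against the consensus read, all
recomputable from the emitted confusion counts. Along any sweep sensitivity
is non-increasing and specificity non-decreasing by construction; on
cohorts whose reads are generated from the category-anchored read model the
agreement maximum falls in the upper gray zone, mirroring the qualitative
finding that visual reading turns positive only late in the gray zone.

## The synthetic cohort generator

No subject-level data from the motivating studies is public, so the
generator is a first-class module that emulates their *statistical*
structure — it defines the package's study conditions and is not tuned per
analysis:

* **Cross-sectional groups** (`generate_cross_sectional()`): regional SUVRs
  are Gaussian at the published group moments. Regions share a subject-level
  latent factor with equicorrelation `rho = 0.8` — amyloid PET signal is
  strongly correlated across cortical regions, but no inter-regional
  covariance is published, so 0.8 is a documented convention, configurable
  per scenario. The composite is recomputed from the six composite regions
  whenever they are present (tolerance 1e-9 is asserted, not assumed).
* **Longitudinal visits** (`generate_longitudinal()`): each subject's
  category (from its baseline value and a cutoff set) selects a rate
  distribution; percent-rate specifications convert to absolute slopes
  through the subject's own baseline (`α = pct · SUVR_B / 100`), i.e. the
  percent-rate definition run in reverse. Measurement noise is added to
  follow-up visits only, so the baseline row is the observed baseline — this
  matches the generator's role as the inverse of the per-subject regression
  and keeps the noiseless case exactly linear.
* **Tau** (`generate_tau()`): tau SUVRs are Gaussian per amyloid category
  with a rank-based coupling to the centiloid value. The blending weight is
  `λ = 2 sin(π ρ_s / 6)`, the Gaussian-copula loading whose population
  Spearman correlation is the requested `rank_coupling`. Blending happens
  *within* each category: pooled blending would let the category strata
  (which occupy truncated slices of the pooled rank distribution) drag the
  per-category means away from their specification. The pooled amyloid–tau
  correlation therefore combines within-category coupling with the
  between-category mean gradient; at coupling 0.5 and the default category
  mix it centres near 0.55 (pre-registered Monte-Carlo envelope 0.39–0.71).
  Exact pooled comonotonicity at coupling 1 holds when the category
  distributions are themselves ordered and non-overlapping.
* **Reads** (`generate_visual_reads()`): independent Bernoulli reads per
  reader with category-dependent positivity (defaults 0 / 0.214 / 0.93,
  the reported per-category visual positivity levels). Reader-specific bias
  and learning are not modelled.
* **Progression** (`generate_progression()`): Bernoulli per category with
  defaults 0 / 0 / 21⁄23.
* **Staggered logistic cohorts** (`generate_logistic_cohort()`): subjects
  at latent uniform accumulation times, regional values on logistic
  trajectories with T50 staggered in the reported onset order
  (cingulate/precuneus before frontal/lateral temporal before
  parietal/occipital), used to verify that the onset-ranking estimator
  recovers a known ordering.

Seeding: one master seed; every stage derives a deterministic child seed
(`child_seed()`) so stages are independently reproducible and an
identical configuration gives byte-identical outputs.

What the generator does **not** emulate: empirical (non-Gaussian) tails of
real SUVR distributions, scanner/site effects, reader correlation,
longitudinal attrition, and any image-domain artefact. Consequently,
passing tests show that the *methods* behave as specified under the stated
statistical structure — they do not certify performance on real scans, and
quantities that live in the empirical tails (the exact 1.38/35.7
established cutoffs, 93 %/100 % operating points, 21.4 %/19.6 % gray-zone
visual positivity, the 14/32 CL mixture cutoffs) are checked qualitatively,
never numerically.

## Scenario defaults and problem sizes

The default scenario reproduces the five-dataset structure: young controls
n = 65; elderly controls n = 66 + AD n = 73 for the ROC; SCD n = 168 with a
second scan at 2 years; MCI n = 44 with scans at 0/1/2 years and 4-year
progression labels; and a 270-subject amyloid+tau subset. Baseline mixtures
for the SCD/MCI/tau samples (fractions and component locations) are fixed
conventions chosen to give plausible category splits (e.g. roughly a third
of the tau subset with established pathology); only their qualitative shape
is reported in the source material. The test suite runs the full pipeline
on a down-scaled scenario (tens of subjects per dataset) and the
simulation-recovery checks at n = 200–300 with 20–200 seeds; these sizes
were chosen as the smallest at which the sampling-error bounds used in the
assertions (3 sd/√n style) are meaningfully tight.

## Numerical choices and degenerate inputs

* Zero-variance young-control samples: warning, early cutoff equals the
  mean. Fewer than 3 observations: error.
* ROC with a single class or all-identical values: error. Exact ties in the
  ROC data are handled by the average-rank AUC and by the explicit
  tie-break chain.
* EM: collapse guard at 1 CL mean separation; non-convergence after 500
  iterations is an error, not a silent result. The posterior-equality
  crossing is solved to 1e-10.
* Affine exactness: the centiloid map, ΔSUVR shifts, and slope/scale
  commutation (`α_CL = 153.4 α_SUVR`) are asserted to 1e-9 or better in the
  suite.
* Missing data are `NA` cells end to end; no sentinel numbers.

## Known limitations

* The onset-ranking estimator is one defensible operationalization of
  "crosses earlier"; rankings from heat-map inspection may differ in
  regions with nearly simultaneous onsets, and with a common T50 across
  regions the ranking is pure noise by design.
* Gray-zone category boundaries interact with cutoff uncertainty: subjects
  near a cutoff can flip categories between the generating and the derived
  cutoffs, which slightly mixes adjacent categories' rate distributions in
  full-pipeline runs.
* The centiloid validation operates on user-supplied pair tables; the
  reference dataset itself is not downloaded or redistributed, and the
  bundled pairs are synthetic.
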