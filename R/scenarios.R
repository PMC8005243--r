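# Published group moments used to parameterize the default scenario. These
# are the study conditions the simulator emulates: regional SUVR means/SDs of
# young controls, elderly controls and AD dementia, centiloid moments,
# category-specific accumulation-rate distributions, tau SUVR distributions
# per amyloid category, visual-read positivity per category, and the
# published dual cutoffs.

yhc_moments <- function() {
  data.frame(
    region = c(cortical_regions(), "composite"),
    mean = c(1.09, 1.09, 1.18, 1.12, 1.23, 1.28, 1.12, 1.16),
    sd   = c(0.04, 0.03, 0.04, 0.04, 0.07, 0.09, 0.04, 0.04))
}

ehc_moments <- function() {
  data.frame(
    region = c(cortical_regions(), "composite"),
    mean = c(1.15, 1.15, 1.20, 1.13, 1.28, 1.33, 1.15, 1.21),
    sd   = c(0.07, 0.05, 0.06, 0.08, 0.09, 0.09, 0.08, 0.06))
}

ad_moments <- function() {
  data.frame(
    region = c(cortical_regions(), "composite"),
    mean = c(1.57, 1.51, 1.43, 1.51, 1.70, 1.77, 1.60, 1.58),
    sd   = c(0.19, 0.17, 0.16, 0.16, 0.22, 0.21, 0.19, 0.17))
}

moment_vec <- function(m, what) stats::setNames(m[[what]], m$region)

#' Published reference values used by the default scenario
#'
#' Centiloid group moments (yHC 2.82 +/- 5.36 CL; eHC 6.8 +/- 8.8 CL; AD
#' 81.0 +/- 33.2 CL), the published dual cutoffs (composite SUVR 1.25/1.38;
#' 13.5/35.7 CL), category accumulation-rate distributions for the SCD and
#' MCI longitudinal samples, and tau SUVR distributions (standard-CL-scale
#' categories) per amyloid category.
#'
#' @return A nested list of reference constants.
#' @export
reference_values <- function() {
  list(
    cl_moments = list(yhc = c(mean = 2.82, sd = 5.36),
                      ehc = c(mean = 6.8, sd = 8.8),
                      ad = c(mean = 81.0, sd = 33.2)),
    cutoffs = list(suvr = c(early = 1.25, estab = 1.38),
                   cl = c(early = 13.5, estab = 35.7)),
    # composite-row class moments of the ROC calibration cohort (eHC vs AD)
    roc_moments = list(
      suvr = c(mean_neg = 1.21, sd_neg = 0.06, mean_pos = 1.58,
               sd_pos = 0.17, n_neg = 66, n_pos = 73),
      cl = c(mean_neg = 6.8, sd_neg = 8.8, mean_pos = 81.0,
             sd_pos = 33.2, n_neg = 66, n_pos = 73)),
    # percent composite-SUVR deposition per year by category; CL/year rates
    scd_rates = list(
      suvr = list(negative = c(0.24, 1.24), gray_zone = c(1.66, 1.86),
                  established = c(2.40, 2.37)),
      cl = list(negative = c(0.00, 0.89), gray_zone = c(1.81, 1.86),
                established = c(2.38, 1.82))),
    mci_rates = list(
      suvr = list(negative = c(-0.29, 1.68), gray_zone = c(1.51, 1.38),
                  established = c(1.23, 1.90)),
      cl = list(negative = c(0.08, 1.62), gray_zone = c(2.62, 1.47),
                established = c(1.41, 1.82))),
    tau = list(
      means = list(
        mesial_temporal = c(negative = 1.16, gray_zone = 1.18,
                            established = 1.33),
        fusiform = c(negative = 1.15, gray_zone = 1.16, established = 1.35),
        inferior_temporal = c(negative = 1.15, gray_zone = 1.18,
                              established = 1.38),
        parietal_tau = c(negative = 1.03, gray_zone = 1.06,
                         established = 1.16)),
      sds = list(
        mesial_temporal = c(negative = 0.09, gray_zone = 0.11,
                            established = 0.15),
        fusiform = c(negative = 0.08, gray_zone = 0.09, established = 0.24),
        inferior_temporal = c(negative = 0.05, gray_zone = 0.11,
                              established = 0.28),
        parietal_tau = c(negative = 0.06, gray_zone = 0.09,
                         established = 0.24))),
    reads = c(negative = 0, gray_zone = 0.214, established = 0.93),
    progression = c(negative = 0, gray_zone = 0, established = 21 / 23))
}

#' Published dual cutoffs as cutoff sets
#'
#' @param scale `"suvr"` (composite 1.25 / 1.38) or `"cl"` (13.5 / 35.7 CL).
#' @return A [cutoff_set()].
#' @export
published_cutoffs <- function(scale = c("suvr", "cl")) {
  scale <- match.arg(scale)
  v <- reference_values()$cutoffs[[scale]]
  cutoff_set(v[["early"]], v[["estab"]], scale = scale,
             region = if (scale == "suvr") "composite" else "cortex",
             provenance = list(method = "published"))
}

#' Default paper-parameterized simulation scenario
#'
#' The five-dataset structure the package's analyses assume:
#' dataset #1, young healthy controls (n = 65, regional Gaussians at the
#' young-control moments); dataset #2, elderly controls (n = 66) and AD
#' dementia (n = 73) for the ROC cutoff; dataset #3, SCD (n = 168) with a
#' second scan at 2 years; dataset #4, MCI (n = 44) with scans at 0, 1 and
#' 2 years plus 4-year progression labels; dataset #5, an amyloid + tau
#' subset (n = 270). The SCD and MCI baseline composite distributions are
#' mixtures (a young-control-like mode plus gray-zone and established
#' components) since only their qualitative shape is reported; mixture
#' fractions are fixed conventions of the scenario. The amyloid + tau subset
#' draws centiloid from a three-component mixture giving roughly a third of
#' subjects established pathology.
#'
#' @param n Optional named overrides of the dataset sizes
#'   (`yhc`, `ehc`, `ad`, `scd`, `mci`, `tau`).
#' @return A nested scenario list consumed by [run_pipeline()].
#' @export
default_scenario <- function(n = NULL) {
  sizes <- list(yhc = 65, ehc = 66, ad = 73, scd = 168, mci = 44, tau = 270)
  if (!is.null(n)) sizes[names(n)] <- n
  rv <- reference_values()
  list(
    rho = 0.8,
    sizes = sizes,
    yhc = list(means = moment_vec(yhc_moments()[1:7, ], "mean"),
               sds = moment_vec(yhc_moments()[1:7, ], "sd"),
               cl = rv$cl_moments$yhc),
    ehc = list(means = moment_vec(ehc_moments()[1:7, ], "mean"),
               sds = moment_vec(ehc_moments()[1:7, ], "sd"),
               cl = rv$cl_moments$ehc),
    ad = list(means = moment_vec(ad_moments()[1:7, ], "mean"),
              sds = moment_vec(ad_moments()[1:7, ], "sd"),
              cl = rv$cl_moments$ad),
    # baseline composite mixtures: fraction, composite mean/sd, CL mean/sd
    scd_mixture = data.frame(
      fraction = c(0.72, 0.16, 0.12),
      comp_mean = c(1.17, 1.31, 1.50), comp_sd = c(0.045, 0.035, 0.09),
      cl_mean = c(3, 24, 62), cl_sd = c(6, 6, 20)),
    mci_mixture = data.frame(
      fraction = c(0.40, 0.08, 0.52),
      comp_mean = c(1.18, 1.31, 1.55), comp_sd = c(0.05, 0.035, 0.12),
      cl_mean = c(4, 25, 75), cl_sd = c(6, 6, 25)),
    tau_cl_mixture = data.frame(
      fraction = c(0.48, 0.15, 0.37),
      cl_mean = c(0, 24, 75), cl_sd = c(7, 6, 30)),
    visits = list(scd = c(0, 2), mci = c(0, 1, 2)),
    noise_sd = list(suvr = 0.01, cl = 1.5),
    scd_rates = rv$scd_rates,
    mci_rates = rv$mci_rates,
    tau = rv$tau,
    tau_coupling = 0.5,
    reads = rv$reads,
    n_readers = 3,
    progression = rv$progression,
    trajectories = default_trajectories())
}

#' Default staggered logistic trajectories
#'
#' Per-region logistic parameters with NS at the young-control mean, K the
#' young-control-to-AD dynamic range, a common growth rate, and T50 staggered
#' in the reported onset order (cingulate cortices and precuneus earliest,
#' then frontal and lateral temporal, then parietal and occipital).
#'
#' @param r Common growth rate (1/year).
#' @return Named list of [logistic_params()].
#' @export
default_trajectories <- function(r = 0.35) {
  ns <- moment_vec(yhc_moments()[1:7, ], "mean")
  k <- moment_vec(ad_moments()[1:7, ], "mean") - ns
  t50 <- c(frontal = 15, lateral_temporal = 16, occipital = 19, parietal = 18,
           anterior_cingulate = 12, posterior_cingulate = 12.5,
           precuneus = 13)
  stats::setNames(lapply(names(ns), function(rg) {
    logistic_params(rg, ns = ns[[rg]], k = k[[rg]], r = r, t50 = t50[[rg]])
  }), names(ns))
}

#' Draw a baseline cohort from a labelled Gaussian mixture
#'
#' Baseline composite SUVR and centiloid values follow a mixture of Gaussian
#' components (e.g. a young-control-like mode plus gray-zone and established
#' components). One shared latent deviate per subject drives both scales so
#' they agree in rank, as the two quantification routes do in practice.
#'
#' @param mix Data frame with columns `fraction`, `cl_mean`, `cl_sd` and
#'   (unless `cl_only`) `comp_mean`, `comp_sd`.
#' @param n Number of subjects.
#' @param dataset_id,group_label Row labels.
#' @param seed Integer seed.
#' @param cl_only Draw only the centiloid column.
#' @return A cohort table of baseline rows.
#' @export
simulate_mixture_baseline <- function(mix, n, dataset_id = "mix",
                                      group_label = "simulated", seed = 1,
                                      cl_only = FALSE) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  comp_idx <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$fraction)
  z <- stats::rnorm(n)
  df <- data.frame(subject_id = sprintf("%s_%04d", dataset_id, seq_len(n)),
                   dataset_id = dataset_id, group_label = group_label,
                   visit_time = 0)
  if (!cl_only) {
    df$suvr_composite <- mix$comp_mean[comp_idx] + mix$comp_sd[comp_idx] * z
  }
  df$cl_cortex <- mix$cl_mean[comp_idx] + mix$cl_sd[comp_idx] * z
  as_cohort_table(df)
}

#' Simulate 4-year progression labels per amyloid category
#'
#' Bernoulli progression-to-dementia labels with a category-specific
#' probability, the category assigned from the baseline value with the
#' supplied cutoffs.
#'
#' @param cohort Cohort table.
#' @param p_progress Named vector over [amyloid_levels()] of progression
#'   probabilities.
#' @param cutoffs A [cutoff_set()].
#' @param seed Integer seed.
#' @return The cohort with `progression_4yr` filled at baseline rows.
#' @export
generate_progression <- function(cohort, p_progress, cutoffs, seed) {
  stopifnot(inherits(cutoffs, "cutoff_set"),
            all(amyloid_levels() %in% names(p_progress)))
  value_col <- if (cutoffs$scale == "suvr") "suvr_composite" else "cl_cortex"
  set.seed(as.integer(seed %% .Machine$integer.max))
  ib <- which(cohort$visit_time == 0)
  status <- as.character(classify_amyloid(cohort[[value_col]][ib],
                                          cutoffs$early, cutoffs$estab))
  if (!"progression_4yr" %in% names(cohort)) {
    cohort$progression_4yr <- NA_real_
  }
  cohort$progression_4yr[ib] <- stats::rbinom(length(ib), 1,
                                              p_progress[status])
  cohort
}
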