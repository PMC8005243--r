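#' Deterministic child seeds for pipeline stages
#'
#' One master seed drives the whole pipeline; each stage draws from its own
#' child seed so stages are independently reproducible. The derivation is a
#' fixed affine-modular map of the master seed and a stage index (stage names
#' are hashed by character codes), kept below 2^31 - 1.
#'
#' @param master Non-negative integer master seed.
#' @param stage Stage name (character) or integer index.
#' @return Integer child seed.
#' @export
child_seed <- function(master, stage) {
  stopifnot(length(master) == 1, is.finite(master), master >= 0)
  idx <- if (is.character(stage)) {
    sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  } else {
    as.numeric(stage)
  }
  as.integer((as.numeric(master) * 48271 + idx * 16807 + 1) %% 2147483629)
}

#' Specification of one diagnostic group's cross-sectional distribution
#'
#' @param group_label One of yHC, eHC, SCD, MCI, AD (free-form labels are
#'   allowed).
#' @param n Number of subjects (>= 1).
#' @param means,sds Named numeric vectors of per-region SUVR means and SDs
#'   (same names, SDs >= 0, means > 0). May include the pseudo-region
#'   `"composite"` when only a composite distribution is specified.
#' @param cl_mean,cl_sd Optional centiloid mean/SD for the standard cortical
#'   ROI (drawn jointly with the regional latent factor).
#' @param dataset_id Scenario tag stored in the cohort rows.
#' @return A `group_spec` object.
#' @export
group_spec <- function(group_label, n, means, sds, cl_mean = NULL,
                       cl_sd = NULL, dataset_id = group_label) {
  stopifnot(length(n) == 1, n >= 1, is.numeric(means), is.numeric(sds),
            length(means) == length(sds),
            identical(names(means), names(sds)))
  if (is.null(names(means))) stop("means/sds must be named by region")
  if (any(sds < 0)) stop("SDs must be >= 0")
  if (any(means <= 0)) stop("SUVR means must be > 0 (SUVR is a positive ratio)")
  if (!is.null(cl_mean)) stopifnot(is.numeric(cl_mean), is.numeric(cl_sd),
                                   cl_sd >= 0)
  structure(list(group_label = group_label, n = as.integer(n), means = means,
                 sds = sds, cl_mean = cl_mean, cl_sd = cl_sd,
                 dataset_id = dataset_id),
            class = "group_spec")
}

#' Logistic amyloid accumulation trajectory
#'
#' Regional amyloid accumulation is modelled as logistic growth in time:
#' `SUVR(t) = NS + K / (1 + exp(-r * (t - T50)))`, with NS the tracer
#' non-specific binding (lower asymptote), K the carrying capacity (dynamic
#' range), r the uninhibited growth rate (1/year) and T50 the time of
#' half-maximal carrying capacity. The trajectory is strictly increasing and
#' bounded in (NS, NS + K); at t = T50 it equals NS + K/2.
#'
#' @param region Region name.
#' @param ns Non-specific binding (SUVR, > 0).
#' @param k Carrying capacity (SUVR, > 0).
#' @param r Growth rate (1/year, > 0).
#' @param t50 Time of half-maximal capacity (years).
#' @return A `logistic_params` object.
#' @export
logistic_params <- function(region, ns, k, r, t50) {
  stopifnot(is.numeric(ns), is.numeric(k), is.numeric(r), is.numeric(t50))
  if (ns <= 0 || k <= 0 || r <= 0) stop("NS, K and r must all be positive")
  structure(list(region = region, ns = ns, k = k, r = r, t50 = t50),
            class = "logistic_params")
}

#' @param t Time through the accumulation process (years); vectorized.
#' @param params A [logistic_params()] object.
#' @rdname logistic_params
#' @return `logistic_suvr()`: SUVR values at `t`.
#' @export
logistic_suvr <- function(t, params) {
  stopifnot(inherits(params, "logistic_params"))
  if (any(!is.finite(t))) stop("t must be finite")
  params$ns + params$k / (1 + exp(-params$r * (t - params$t50)))
}

#' Generate a cross-sectional cohort from group specifications
#'
#' Per group, regional SUVRs are Gaussian with the spec's moments. Regions
#' share a subject-level latent factor with equicorrelation `rho` (amyloid
#' PET signal is strongly correlated across cortical regions):
#' `x_r = mean_r + sd_r * (sqrt(rho) * z_subject + sqrt(1 - rho) * z_r)`.
#' The centiloid value, when specified, loads on the same latent factor. The
#' composite is recomputed from the six composite regions when they are all
#' present, otherwise taken from a `"composite"` pseudo-region.
#'
#' @param specs List of [group_spec()] objects sharing one region set.
#' @param seed Integer seed; identical seed and specs give identical output.
#' @param rho Inter-regional equicorrelation in `[0, 1)` (default 0.8).
#' @return A [as_cohort_table()] cohort with baseline rows only.
#' @export
generate_cross_sectional <- function(specs, seed, rho = 0.8) {
  if (inherits(specs, "group_spec")) specs <- list(specs)
  if (length(specs) == 0) stop("empty specification list")
  stopifnot(all(vapply(specs, inherits, logical(1), "group_spec")),
            rho >= 0, rho < 1)
  region_sets <- lapply(specs, function(s) names(s$means))
  if (length(unique(vapply(region_sets, paste, "", collapse = ","))) != 1) {
    stop("all group specs in one scenario must share the same region set")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  offsets <- c(0, cumsum(vapply(specs, `[[`, integer(1), "n")))
  tabs <- lapply(seq_along(specs), function(si) {
    s <- specs[[si]]
    regions <- names(s$means)
    z_sub <- stats::rnorm(s$n)
    draw <- function(mean, sd) {
      mean + sd * (sqrt(rho) * z_sub + sqrt(1 - rho) * stats::rnorm(s$n))
    }
    vals <- mapply(draw, s$means, s$sds)
    vals <- matrix(vals, nrow = s$n,
                   dimnames = list(NULL, suvr_col(regions)))
    df <- data.frame(
      subject_id = sprintf("%s_%04d", s$dataset_id, offsets[si] + seq_len(s$n)),
      dataset_id = s$dataset_id, group_label = s$group_label,
      visit_time = 0)
    df <- cbind(df, as.data.frame(vals))
    if (all(suvr_col(composite_regions()) %in% names(df))) {
      df$suvr_composite <- compute_composite(df)
    } else if ("suvr_composite" %in% names(df)) {
      # pseudo-region "composite" produced column suvr_composite directly
    }
    if (!is.null(s$cl_mean)) {
      df$cl_cortex <- s$cl_mean + s$cl_sd *
        (sqrt(rho) * z_sub + sqrt(1 - rho) * stats::rnorm(s$n))
    }
    df
  })
  all_names <- unique(unlist(lapply(tabs, names)))
  tabs <- lapply(tabs, function(d) {
    d[setdiff(all_names, names(d))] <- NA_real_
    d[all_names]
  })
  as_cohort_table(do.call(rbind, tabs))
}

#' Generate longitudinal follow-up visits with category-specific slopes
#'
#' Each subject's amyloid category is assigned from its baseline value with
#' the supplied cutoffs, a latent true slope is drawn from that category's
#' slope distribution, and follow-up values are baseline + slope * t plus
#' Gaussian measurement noise (follow-up visits only; the baseline row is
#' the observed baseline). On the SUVR scale the slope specification is in
#' percent deposition per year and is converted per subject through its
#' baseline (`alpha = pct * baseline / 100`), mirroring the percent-rate
#' definition in reverse; on the CL scale slopes are absolute CL/year.
#'
#' @param base Cohort table with baseline rows (visit_time 0) for every
#'   subject and the value column for `scale`.
#' @param visit_times Numeric vector of visit times including 0.
#' @param slope_spec Named list `negative`, `gray_zone`, `established`, each
#'   `c(mean, sd)` of the category's rate distribution (percent/yr for
#'   `"suvr"`, CL/yr for `"cl"`).
#' @param noise_sd Measurement noise SD (same units as the value column).
#' @param cutoffs A [cutoff_set()] on the matching scale.
#' @param seed Integer seed.
#' @param scale `"suvr"` (uses `suvr_composite`) or `"cl"` (uses `cl_cortex`).
#' @return Cohort table with baseline plus follow-up rows (follow-up rows
#'   carry only the value column); attribute `true_slopes` holds the latent
#'   per-subject slopes and assigned categories.
#' @export
generate_longitudinal <- function(base, visit_times, slope_spec, noise_sd,
                                  cutoffs, seed, scale = c("suvr", "cl")) {
  scale <- match.arg(scale)
  stopifnot(inherits(cutoffs, "cutoff_set"), noise_sd >= 0,
            all(c("negative", "gray_zone", "established") %in% names(slope_spec)))
  if (!any(visit_times == 0)) stop("visit_times must include the baseline 0")
  value_col <- if (scale == "suvr") "suvr_composite" else "cl_cortex"
  b <- baseline_rows(base)
  if (nrow(b) == 0) stop("no baseline rows in the input cohort")
  if (!value_col %in% names(b) || any(is.na(b[[value_col]]))) {
    stop("baseline column ", value_col, " missing or incomplete")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  status <- classify_amyloid(b[[value_col]], cutoffs$early, cutoffs$estab)
  rate <- vapply(as.character(status), function(s) {
    sp <- slope_spec[[s]]
    stats::rnorm(1, sp[1], sp[2])
  }, numeric(1))
  alpha <- if (scale == "suvr") rate * b[[value_col]] / 100 else rate
  follow <- lapply(setdiff(visit_times, 0), function(t) {
    d <- b[, c("subject_id", "dataset_id", "group_label")]
    d$visit_time <- t
    d[[value_col]] <- b[[value_col]] + alpha * t +
      stats::rnorm(nrow(b), 0, noise_sd)
    d
  })
  follow <- do.call(rbind, follow)
  base_keep <- b[, intersect(names(b), c("subject_id", "dataset_id",
                                         "group_label", "visit_time",
                                         value_col))]
  out <- rbind(base_keep, follow[names(base_keep)])
  out <- out[order(out$subject_id, out$visit_time), ]
  rownames(out) <- NULL
  out <- as_cohort_table(out)
  attr(out, "true_slopes") <- data.frame(subject_id = b$subject_id,
                                         status = status, rate = rate,
                                         alpha = alpha)
  out
}

#' Tau-region specification for the amyloid + tau subset
#'
#' @param means,sds Lists (or matrices) keyed by tau region, each a named
#'   numeric vector over [amyloid_levels()] of tau SUVR means / SDs.
#' @param rank_coupling Target monotone association strength (0-1) between
#'   amyloid burden (CL) and tau SUVR within each amyloid category.
#' @return A `tau_spec` object.
#' @export
tau_spec <- function(means, sds, rank_coupling = 0.5) {
  stopifnot(identical(names(means), names(sds)),
            rank_coupling >= 0, rank_coupling <= 1)
  for (rg in names(means)) {
    stopifnot(all(amyloid_levels() %in% names(means[[rg]])),
              all(amyloid_levels() %in% names(sds[[rg]])),
              all(sds[[rg]] >= 0))
  }
  structure(list(means = means, sds = sds, rank_coupling = rank_coupling),
            class = "tau_spec")
}

#' Attach synthetic tau SUVRs coupled to amyloid burden
#'
#' Tau SUVRs are drawn per amyloid category from the spec's Gaussians. A
#' monotone coupling with the centiloid value is imposed by rank-based
#' blending within each category: the category-standardized tau deviate is
#' `lambda * z_rank(CL) + sqrt(1 - lambda^2) * noise`, with
#' `lambda = 2 * sin(pi * rank_coupling / 6)` (the Gaussian-copula value
#' whose population Spearman correlation equals `rank_coupling`). Blending
#' within categories preserves the per-category marginal moments exactly in
#' expectation; the pooled amyloid-tau correlation then combines the
#' within-category coupling with the between-category mean gradient.
#'
#' @param cohort Cohort table with `cl_cortex` at baseline.
#' @param spec A [tau_spec()].
#' @param cutoffs CL-scale [cutoff_set()] used to assign categories.
#' @param seed Integer seed.
#' @return The cohort with `tau_<region>` columns filled at baseline rows.
#' @export
generate_tau <- function(cohort, spec, cutoffs, seed) {
  stopifnot(inherits(spec, "tau_spec"), inherits(cutoffs, "cutoff_set"))
  if (!"cl_cortex" %in% names(cohort)) stop("cohort lacks cl_cortex")
  set.seed(as.integer(seed %% .Machine$integer.max))
  ib <- which(cohort$visit_time == 0)
  cl <- cohort$cl_cortex[ib]
  if (any(is.na(cl))) stop("cl_cortex missing at baseline rows")
  status <- as.character(classify_amyloid(cl, cutoffs$early, cutoffs$estab))
  lambda <- 2 * sin(pi * spec$rank_coupling / 6)
  for (rg in names(spec$means)) {
    v <- numeric(length(ib))
    for (s in amyloid_levels()) {
      i <- which(status == s)
      if (length(i) == 0) next
      z_cl <- stats::qnorm(rank(cl[i], ties.method = "average") /
                             (length(i) + 1))
      z <- lambda * z_cl + sqrt(1 - lambda^2) * stats::rnorm(length(i))
      v[i] <- spec$means[[rg]][[s]] + spec$sds[[rg]][[s]] * z
    }
    col <- tau_col(rg)
    if (!col %in% names(cohort)) cohort[[col]] <- NA_real_
    cohort[[col]][ib] <- v
  }
  cohort
}

#' Visual-read specification
#'
#' @param n_readers Odd number of independent blinded readers (default 3).
#' @param p_positive Named numeric vector over [amyloid_levels()]: the
#'   probability that a single read of a subject in that category is
#'   positive.
#' @return A `read_spec` object.
#' @export
read_spec <- function(n_readers = 3,
                      p_positive = c(negative = 0, gray_zone = 0.214,
                                     established = 0.93)) {
  stopifnot(n_readers >= 1, n_readers %% 2 == 1,
            all(amyloid_levels() %in% names(p_positive)),
            all(p_positive >= 0 & p_positive <= 1))
  structure(list(n_readers = as.integer(n_readers), p_positive = p_positive),
            class = "read_spec")
}

#' Simulate per-reader binary visual reads
#'
#' Each subject receives `n_readers` independent Bernoulli reads with the
#' positivity probability of its amyloid category (assigned from the
#' baseline value with the supplied cutoffs).
#'
#' @param cohort Cohort table.
#' @param spec A [read_spec()].
#' @param cutoffs A [cutoff_set()]; its scale picks the value column.
#' @param seed Integer seed.
#' @return The cohort with `read_1` ... `read_k` columns at baseline rows.
#' @export
generate_visual_reads <- function(cohort, spec, cutoffs, seed) {
  stopifnot(inherits(spec, "read_spec"), inherits(cutoffs, "cutoff_set"))
  value_col <- if (cutoffs$scale == "suvr") "suvr_composite" else "cl_cortex"
  set.seed(as.integer(seed %% .Machine$integer.max))
  ib <- which(cohort$visit_time == 0)
  status <- as.character(classify_amyloid(cohort[[value_col]][ib],
                                          cutoffs$early, cutoffs$estab))
  p <- spec$p_positive[status]
  for (k in seq_len(spec$n_readers)) {
    col <- paste0("read_", k)
    if (!col %in% names(cohort)) cohort[[col]] <- NA_real_
    cohort[[col]][ib] <- stats::rbinom(length(ib), 1, p)
  }
  cohort
}

#' Generate a cohort from staggered logistic trajectories
#'
#' Subjects are placed at latent times uniform over `t_range`; each region's
#' SUVR follows its own logistic trajectory plus Gaussian measurement noise.
#' Used to study how the half-capacity crossing order of regions (their T50
#' stagger) shows up in cross-sectional data.
#'
#' @param params_list List of [logistic_params()], one per region.
#' @param n Number of subjects.
#' @param t_range Length-2 range of latent accumulation times (years).
#' @param noise_sd Measurement noise SD (SUVR).
#' @param seed Integer seed.
#' @return Cohort table (baseline rows only) with attribute `latent_time`.
#' @export
generate_logistic_cohort <- function(params_list, n, t_range = c(0, 30),
                                     noise_sd = 0.02, seed = 1) {
  stopifnot(all(vapply(params_list, inherits, logical(1), "logistic_params")),
            length(t_range) == 2, noise_sd >= 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  t <- stats::runif(n, t_range[1], t_range[2])
  df <- data.frame(subject_id = sprintf("LG_%04d", seq_len(n)),
                   dataset_id = "logistic", group_label = "simulated",
                   visit_time = 0)
  for (p in params_list) {
    df[[suvr_col(p$region)]] <- logistic_suvr(t, p) +
      stats::rnorm(n, 0, noise_sd)
  }
  if (all(suvr_col(composite_regions()) %in% names(df))) {
    df$suvr_composite <- compute_composite(df)
  }
  out <- as_cohort_table(df)
  attr(out, "latent_time") <- t
  out
}
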