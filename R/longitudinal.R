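#' Per-subject annual accumulation slope
#'
#' Ordinary least-squares fit of value = alpha * t + beta over one subject's
#' visits. With exactly two visits the slope is the difference quotient. On
#' the SUVR scale the percent deposition per year is
#' `100 * alpha / value_at_baseline`, with the baseline taken as the
#' observed value at the earliest visit (not the fitted intercept).
#'
#' @param time Visit times in years (>= 2 distinct values).
#' @param value SUVR or CL values at those visits.
#' @param scale `"suvr"` (percent rate computed) or `"cl"`.
#' @return One-row data frame: `alpha`, `beta`, `value_b` (observed
#'   baseline), `abeta_dep` (percent/yr; `NA` on the CL scale), `n_visits`.
#' @export
fit_subject_slope <- function(time, value, scale = c("suvr", "cl")) {
  scale <- match.arg(scale)
  keep <- !is.na(time) & !is.na(value)
  time <- time[keep]
  value <- value[keep]
  if (length(time) < 2 || length(unique(time)) < 2) {
    stop("need at least 2 visits with distinct times")
  }
  tc <- time - mean(time)
  alpha <- sum(tc * value) / sum(tc^2)
  beta <- mean(value) - alpha * mean(time)
  value_b <- value[which.min(time)]
  data.frame(alpha = alpha, beta = beta, value_b = value_b,
             abeta_dep = if (scale == "suvr") 100 * alpha / value_b
                         else NA_real_,
             n_visits = length(time))
}

#' Fit accumulation slopes for every subject in a cohort
#'
#' @param cohort Cohort table with repeated visits.
#' @param scale `"suvr"` (column `suvr_composite`) or `"cl"` (`cl_cortex`);
#'   or supply `value_col` directly (e.g. a regional column).
#' @param value_col Optional explicit value column.
#' @return Data frame of [fit_subject_slope()] rows with `subject_id`;
#'   subjects with fewer than 2 usable visits are dropped.
#' @export
fit_cohort_slopes <- function(cohort, scale = c("suvr", "cl"),
                              value_col = NULL) {
  scale <- match.arg(scale)
  if (is.null(value_col)) {
    value_col <- if (scale == "suvr") "suvr_composite" else "cl_cortex"
  }
  if (!value_col %in% names(cohort)) stop("cohort lacks column ", value_col)
  parts <- split(cohort[, c("visit_time", value_col)], cohort$subject_id)
  rows <- lapply(names(parts), function(id) {
    d <- parts[[id]]
    ok <- !is.na(d[[value_col]])
    if (sum(ok) < 2 || length(unique(d$visit_time[ok])) < 2) return(NULL)
    cbind(subject_id = id,
          fit_subject_slope(d$visit_time, d[[value_col]], scale = scale))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize accumulation rates per amyloid category
#'
#' Per category: mean and SD of the chosen rate, a one-sample one-sided
#' t-test of mean rate > 0 (`p_positive`), and a Welch unequal-variance
#' two-sample test against the negative category (`p_vs_negative`,
#' one-sided: category rate greater). Categories with fewer than `min_n`
#' subjects are reported as not available (`NA`), mirroring the suppression
#' of under-filled regional strata.
#'
#' @param estimates Data frame from [fit_cohort_slopes()].
#' @param statuses Factor/character of per-subject amyloid categories, named
#'   by or aligned with `estimates$subject_id` (assigned at baseline with a
#'   [cutoff_set()] on the same scale as the rates).
#' @param rate_col `"abeta_dep"` (percent/yr) or `"alpha"` (absolute units).
#' @param min_n Minimum category size to report (default 3).
#' @return Data frame: `category`, `n`, `mean_rate`, `sd_rate`,
#'   `p_positive`, `p_vs_negative`.
#' @export
summarize_category_rates <- function(estimates, statuses,
                                     rate_col = c("abeta_dep", "alpha"),
                                     min_n = 3) {
  rate_col <- match.arg(rate_col)
  if (nrow(estimates) == 0) stop("no slope estimates supplied")
  if (!is.null(names(statuses))) {
    statuses <- statuses[estimates$subject_id]
  }
  stopifnot(length(statuses) == nrow(estimates))
  rates <- split(estimates[[rate_col]], factor(statuses, amyloid_levels()))
  neg <- rates[["negative"]]
  rows <- lapply(amyloid_levels(), function(s) {
    x <- rates[[s]]
    n <- length(x)
    if (n < min_n) {
      return(data.frame(category = s, n = n, mean_rate = NA_real_,
                        sd_rate = NA_real_, p_positive = NA_real_,
                        p_vs_negative = NA_real_))
    }
    p_pos <- stats::t.test(x, mu = 0, alternative = "greater")$p.value
    p_vs <- if (s != "negative" && length(neg) >= min_n) {
      stats::t.test(x, neg, alternative = "greater")$p.value
    } else NA_real_
    data.frame(category = s, n = n, mean_rate = mean(x), sd_rate = stats::sd(x),
               p_positive = p_pos, p_vs_negative = p_vs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Progression to AD dementia per amyloid category
#'
#' @param cohort Cohort table whose baseline rows carry `progression_4yr`
#'   (0/1; `NA` where unknown).
#' @param statuses Per-subject amyloid category aligned with (or named by)
#'   the baseline subjects.
#' @return Data frame `category`, `n`, `n_progressed`, `percent_progressed`
#'   (exact) and `percent_rounded` (nearest integer, the reporting style).
#' @export
summarize_progression <- function(cohort, statuses) {
  b <- baseline_rows(cohort)
  if (!"progression_4yr" %in% names(b)) stop("no progression_4yr column")
  if (!is.null(names(statuses))) statuses <- statuses[b$subject_id]
  stopifnot(length(statuses) == nrow(b))
  keep <- !is.na(b$progression_4yr)
  if (!any(keep)) stop("no subjects with a progression label")
  st <- factor(statuses[keep], amyloid_levels())
  prog <- b$progression_4yr[keep]
  n <- tapply(prog, st, length, default = 0L)
  k <- tapply(prog, st, sum, default = 0L)
  pct <- ifelse(n > 0, 100 * k / n, NA_real_)
  data.frame(category = amyloid_levels(), n = as.integer(n),
             n_progressed = as.integer(k), percent_progressed = as.numeric(pct),
             percent_rounded = round(as.numeric(pct)))
}
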