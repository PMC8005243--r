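#' Early-deposition cutoffs: mean + 2 SD of young healthy controls
#'
#' The early cutoff per region is two sample standard deviations (n-1
#' denominator, the convention for reference-limit derivation) above the
#' young-control mean. A Shapiro-Wilk test records whether each regional
#' distribution departs from Gaussian; p < 0.05 triggers a warning (the
#' derivation still proceeds), not a failure.
#'
#' @param yhc Cohort table (or data frame) of young healthy controls;
#'   baseline rows are used.
#' @param regions Character vector of regions. For `scale = "cl"` the single
#'   `cl_cortex` column is used and `regions` is ignored.
#' @param scale `"suvr"` (regional `suvr_<region>` columns plus
#'   `suvr_composite` if requested as region `"composite"`) or `"cl"`.
#' @return Data frame: `region`, `scale`, `n`, `mean`, `sd`, `early_cutoff`,
#'   `normality_p`.
#' @export
derive_early_cutoffs <- function(yhc, regions = cortical_regions(),
                                 scale = c("suvr", "cl")) {
  scale <- match.arg(scale)
  yhc <- baseline_rows(yhc)
  cols <- if (scale == "cl") {
    stats::setNames("cl_cortex", "cortex")
  } else {
    stats::setNames(ifelse(regions == "composite", "suvr_composite",
                           suvr_col(regions)), regions)
  }
  miss <- setdiff(cols, names(yhc))
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  res <- lapply(names(cols), function(region) {
    v <- yhc[[cols[[region]]]]
    v <- v[!is.na(v)]
    if (any(!is.finite(v))) stop("non-finite values in ", cols[[region]])
    n <- length(v)
    if (n < 3) stop("need at least 3 observations per region (", region, ")")
    if (n < 8) warning("fewer than 8 observations in ", region,
                       "; normality check is fragile")
    s <- stats::sd(v)
    if (s == 0) {
      warning("zero variance in ", region, "; early cutoff equals the mean")
      p <- NA_real_
    } else {
      p <- tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
      if (!is.na(p) && p < 0.05) {
        warning("Shapiro-Wilk p = ", signif(p, 3), " in region ", region,
                ": distribution departs from Gaussian; mean + 2 SD cutoff ",
                "may be miscalibrated")
      }
    }
    data.frame(region = region, scale = scale, n = n, mean = mean(v), sd = s,
               early_cutoff = mean(v) + 2 * s, normality_p = p)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Established-pathology cutoff by ROC / Youden index
#'
#' Candidate thresholds are the midpoints between adjacent sorted unique
#' pooled values plus one candidate below the minimum and one above the
#' maximum. A subject is test-positive iff its value is strictly greater
#' than the threshold, so a value exactly at the chosen cutoff classifies as
#' gray zone downstream. The candidate maximizing Youden's J
#' (sensitivity + specificity - 1) is returned; ties are resolved in favour
#' of higher specificity, remaining ties by the larger threshold. AUC is the
#' rank-sum (Mann-Whitney) estimate with ties counted as half.
#'
#' @param negatives Values from the reference-negative class (e.g. visually
#'   negative elderly controls).
#' @param positives Values from the reference-positive class (e.g. visually
#'   positive AD dementia).
#' @return A `roc_result` list: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`, `auc`, `n_neg`, `n_pos`.
#' @export
derive_established_cutoff <- function(negatives, positives) {
  negatives <- negatives[!is.na(negatives)]
  positives <- positives[!is.na(positives)]
  if (length(negatives) == 0 || length(positives) == 0) {
    stop("both classes must be non-empty")
  }
  pooled <- c(negatives, positives)
  u <- sort(unique(pooled))
  if (length(u) == 1) stop("all values identical; no cutoff is identifiable")
  cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
  sens <- vapply(cand, function(c) mean(positives > c), numeric(1))
  spec <- vapply(cand, function(c) mean(negatives <= c), numeric(1))
  j <- sens + spec - 1
  # max J, then max specificity, then the largest threshold
  best <- order(-j, -spec, -cand)[1]
  r <- rank(pooled) # average ranks: ties count half in the U statistic
  n_pos <- length(positives)
  n_neg <- length(negatives)
  auc <- (sum(r[seq_along(positives) + n_neg]) - n_pos * (n_pos + 1) / 2) /
    (n_pos * n_neg)
  structure(list(cutoff = cand[best], sensitivity = sens[best],
                 specificity = spec[best], youden_j = j[best], auc = auc,
                 n_neg = n_neg, n_pos = n_pos),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC cutoff %.4g: sensitivity %.1f%%, specificity %.1f%%, J %.3f, AUC %.3f\n",
    x$cutoff, 100 * x$sensitivity, 100 * x$specificity, x$youden_j, x$auc))
  invisible(x)
}

#' Binormal AUC from class moments
#'
#' Closed-form AUC for two Gaussian classes:
#' `pnorm((mean_pos - mean_neg) / sqrt(sd_neg^2 + sd_pos^2))`. Used as a
#' consistency oracle for empirical ROC AUCs when only the printed group
#' means and SDs are available.
#'
#' @param mean_neg,sd_neg,mean_pos,sd_pos Class moments; SDs must be > 0.
#' @return AUC in (0, 1).
#' @export
auc_binormal <- function(mean_neg, sd_neg, mean_pos, sd_pos) {
  if (any(c(sd_neg, sd_pos) <= 0)) stop("standard deviations must be positive")
  stats::pnorm((mean_pos - mean_neg) / sqrt(sd_neg^2 + sd_pos^2))
}

#' Three-category amyloid classification
#'
#' Given the early and established cutoffs on one scale: negative iff
#' `value < early`; gray zone iff `early <= value <= estab` (both boundaries
#' inclusive); established iff `value > estab`. Every finite value maps to
#' exactly one status and the status is monotone non-decreasing in value.
#'
#' @param value Numeric vector (SUVR or CL).
#' @param early,estab Cutoffs on the same scale; `early <= estab` required.
#' @return Factor with levels [amyloid_levels()]; `NA` in, `NA` out.
#' @export
classify_amyloid <- function(value, early, estab) {
  stopifnot(is.numeric(value), is.numeric(early), is.numeric(estab),
            length(early) == 1, length(estab) == 1)
  if (early > estab) stop("early cutoff must not exceed the established cutoff")
  out <- ifelse(value < early, "negative",
                ifelse(value > estab, "established", "gray_zone"))
  factor(out, levels = amyloid_levels())
}

#' Bundle early and established cutoffs for one scale
#'
#' @param early,estab Cutoff values (`early < estab` expected; a violation
#'   warns, since published pairs satisfy it, but does not fail).
#' @param scale `"suvr"` or `"cl"`.
#' @param region Region label (default composite/cortex).
#' @param provenance Optional list (method notes, ROC summary, normality p).
#' @return A `cutoff_set` list.
#' @export
cutoff_set <- function(early, estab, scale = c("suvr", "cl"),
                       region = "composite", provenance = list()) {
  scale <- match.arg(scale)
  stopifnot(is.numeric(early), is.numeric(estab))
  if (early >= estab) {
    warning("early cutoff (", early, ") is not below the established cutoff (",
            estab, ")")
  }
  structure(list(early = early, estab = estab, scale = scale, region = region,
                 provenance = provenance),
            class = "cutoff_set")
}

#' @export
print.cutoff_set <- function(x, ...) {
  cat(sprintf("cutoff_set [%s, %s]: early %.4g, established %.4g\n",
              x$region, x$scale, x$early, x$estab))
  invisible(x)
}

#' Derive a full cutoff table from the two calibration cohorts
#'
#' Runs [derive_early_cutoffs()] on the young-control dataset and
#' [derive_established_cutoff()] per region on the elderly-control /
#' AD dataset, on both scales where the columns are present.
#'
#' @param yhc Young healthy control cohort (early cutoffs).
#' @param negatives,positives Cohort tables for the ROC classes (visually
#'   negative elderly controls; visually positive AD dementia).
#' @param regions Regions for the SUVR scale; `"composite"` is included by
#'   default.
#' @return Data frame with one row per region x scale: early and established
#'   cutoffs, ROC sensitivity/specificity/AUC, normality p.
#' @export
derive_cutoff_table <- function(yhc, negatives, positives,
                                regions = c(cortical_regions(), "composite")) {
  scales <- c("suvr", if ("cl_cortex" %in% names(yhc)) "cl")
  out <- lapply(scales, function(sc) {
    early <- derive_early_cutoffs(yhc, regions = regions, scale = sc)
    roc <- lapply(early$region, function(region) {
      col <- if (sc == "cl") "cl_cortex" else if (region == "composite")
        "suvr_composite" else suvr_col(region)
      derive_established_cutoff(baseline_rows(negatives)[[col]],
                                baseline_rows(positives)[[col]])
    })
    cbind(early,
          estab_cutoff = vapply(roc, `[[`, numeric(1), "cutoff"),
          sensitivity = vapply(roc, `[[`, numeric(1), "sensitivity"),
          specificity = vapply(roc, `[[`, numeric(1), "specificity"),
          auc = vapply(roc, `[[`, numeric(1), "auc"))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  bad <- res$early_cutoff >= res$estab_cutoff
  if (any(bad)) {
    warning("early cutoff not below established cutoff in region(s): ",
            paste(res$region[bad], collapse = ", "))
  }
  res
}

# --- two-component Gaussian mixture confirmation --------------------------

em_gmm2 <- function(x, mu, sigma, w, max_iter = 500, tol = 1e-8) {
  n <- length(x)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    d1 <- w * stats::dnorm(x, mu[1], sigma[1])
    d2 <- (1 - w) * stats::dnorm(x, mu[2], sigma[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    ll <- sum(log(tot))
    w <- mean(g)
    if (w <= 0 || w >= 1) return(NULL)
    mu <- c(sum(g * x) / sum(g), sum((1 - g) * x) / sum(1 - g))
    sigma <- c(sqrt(sum(g * (x - mu[1])^2) / sum(g)),
               sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)))
    if (any(sigma < 1e-6)) return(NULL)
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      return(list(mu = mu, sigma = sigma, w = w, loglik = ll,
                  converged = TRUE, iterations = iter))
    }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, w = w, loglik = ll_old,
       converged = FALSE, iterations = max_iter)
}

#' Two-component Gaussian mixture confirmation of the dual cutoffs
#'
#' Fits a two-component univariate Gaussian mixture to the whole-population
#' centiloid distribution by expectation-maximization with 10 seeded random
#' restarts (best log-likelihood kept). Two cutoffs are derived from the fit:
#' the early cutoff as the lower-component mean + 2 SD, and the established
#' cutoff as the centiloid value between the two component means at which the
#' posterior membership probabilities of the components are equal.
#'
#' @param cl_values Centiloid values of the whole population; n >= 50.
#' @param seed Integer seed for the restarts.
#' @param n_restarts,max_iter EM control.
#' @return A `mixture_fit` list: component `means`, `sds`, `weight` (lower
#'   component), `loglik`, `early_cutoff`, `estab_cutoff`.
#' @export
fit_mixture_confirmation <- function(cl_values, seed, n_restarts = 10,
                                     max_iter = 500) {
  x <- cl_values[!is.na(cl_values)]
  if (length(x) < 50) stop("need at least 50 values to fit the mixture")
  best <- NULL
  set.seed(as.integer(seed %% .Machine$integer.max))
  for (i in seq_len(n_restarts)) {
    qs <- sort(stats::runif(2, 0.05, 0.95))
    mu0 <- stats::quantile(x, qs, names = FALSE)
    mu0 <- mu0 + stats::rnorm(2, 0, stats::sd(x) / 10)
    fit <- em_gmm2(x, mu = sort(mu0),
                   sigma = rep(stats::sd(x) / 2, 2),
                   w = stats::runif(1, 0.3, 0.7), max_iter = max_iter)
    if (is.null(fit) || !fit$converged) next
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (is.null(best)) stop("EM failed to converge in ", max_iter, " iterations")
  lo <- which.min(best$mu)
  hi <- 3 - lo
  if (abs(diff(best$mu)) < 1) {
    stop("mixture components collapsed (|difference in means| < 1 CL); ",
         "the population does not support two components")
  }
  w_lo <- if (lo == 1) best$w else 1 - best$w
  post_diff <- function(v) {
    log(w_lo) + stats::dnorm(v, best$mu[lo], best$sigma[lo], log = TRUE) -
      log(1 - w_lo) - stats::dnorm(v, best$mu[hi], best$sigma[hi], log = TRUE)
  }
  if (post_diff(best$mu[lo]) <= 0 || post_diff(best$mu[hi]) >= 0) {
    stop("no posterior-equality crossing between the component means")
  }
  crossing <- stats::uniroot(post_diff, c(best$mu[lo], best$mu[hi]),
                             tol = 1e-10)$root
  structure(list(means = best$mu[c(lo, hi)], sds = best$sigma[c(lo, hi)],
                 weight = w_lo, loglik = best$loglik,
                 early_cutoff = best$mu[lo] + 2 * best$sigma[lo],
                 estab_cutoff = crossing, n = length(x)),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "2-component Gaussian mixture (n = %d):\n  lower  %.1f +/- %.1f CL (weight %.2f)\n  upper  %.1f +/- %.1f CL\n  derived cutoffs: early %.1f CL, established %.1f CL\n",
    x$n, x$means[1], x$sds[1], x$weight, x$means[2], x$sds[2],
    x$early_cutoff, x$estab_cutoff))
  invisible(x)
}
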