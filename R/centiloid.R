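#' Centiloid calibration for florbetaben cortical SUVR
#'
#' The centiloid (CL) scale anchors amyloid burden at 0 (young controls) and
#' 100 (typical AD) via a tracer-specific linear map from cortical SUVR
#' computed with the standard cortex/whole-cerebellum ROIs. The default is
#' the published florbetaben map CL = 153.4 * SUVR - 154.9.
#'
#' @param slope CL per SUVR unit; must be > 0.
#' @param intercept CL offset.
#' @param reference_region Reference region label (documentation only).
#' @return An object of class `centiloid_calibration`.
#' @export
centiloid_calibration <- function(slope = 153.4, intercept = -154.9,
                                  reference_region = "whole cerebellum") {
  stopifnot(is.numeric(slope), length(slope) == 1, is.finite(slope),
            is.numeric(intercept), length(intercept) == 1, is.finite(intercept))
  if (slope <= 0) stop("calibration slope must be positive")
  structure(list(slope = slope, intercept = intercept,
                 reference_region = reference_region),
            class = "centiloid_calibration")
}

#' @export
print.centiloid_calibration <- function(x, ...) {
  cat(sprintf("centiloid calibration: CL = %.1f * SUVR %+.1f (ref: %s)\n",
              x$slope, x$intercept, x$reference_region))
  invisible(x)
}

#' Convert cortical SUVR to centiloid
#'
#' Exact affine map, never rounded internally.
#'
#' @param suvr Cortical SUVR (positive, finite); vectorized.
#' @param calib A [centiloid_calibration()].
#' @return Centiloid values.
#' @export
suvr_to_cl <- function(suvr, calib = centiloid_calibration()) {
  stopifnot(inherits(calib, "centiloid_calibration"), is.numeric(suvr))
  if (any(!is.finite(suvr)) || any(suvr <= 0)) {
    stop("SUVR must be finite and positive (it is a ratio of activities)")
  }
  calib$slope * suvr + calib$intercept
}

#' Convert centiloid back to cortical SUVR
#' @param cl Centiloid values.
#' @inheritParams suvr_to_cl
#' @return SUVR values.
#' @export
cl_to_suvr <- function(cl, calib = centiloid_calibration()) {
  stopifnot(inherits(calib, "centiloid_calibration"), is.numeric(cl))
  (cl - calib$intercept) / calib$slope
}

#' Validate a centiloid implementation against a reference pair set
#'
#' Ordinary least-squares regression of local values on reference values,
#' separately per scale. The pass rule operationalizes the standard
#' calibration-transfer criteria: |slope - 1| <= `slope_tol`, |intercept| <=
#' `intercept_tol` on each scale's units, and R^2 >= `r2_min`. Defaults
#' (0.02, 2 CL / 0.02 SUVR, 0.98) accept the canonical published fits
#' (SUVR: 1.01x - 0.01, R^2 = 0.998; CL: 1.00x + 0.00, R^2 = 1.00).
#'
#' @param pairs Data frame with columns `scale` (`"suvr"` or `"cl"`),
#'   `local_value`, `reference_value`. At least 3 pairs per scale.
#' @param slope_tol,r2_min Scalar tolerances shared across scales.
#' @param intercept_tol Named vector `c(suvr = , cl = )` of intercept
#'   tolerances in each scale's units.
#' @return A `calibration_validation` object: per-scale data frame of fitted
#'   slope, intercept, `r_squared`, `pass`, plus overall `pass_flag`.
#' @export
validate_calibration <- function(pairs, slope_tol = 0.02,
                                 intercept_tol = c(suvr = 0.02, cl = 2),
                                 r2_min = 0.98) {
  stopifnot(is.data.frame(pairs),
            all(c("scale", "local_value", "reference_value") %in% names(pairs)))
  out <- lapply(split(pairs, pairs$scale), function(d) {
    if (nrow(d) < 3) stop("need at least 3 pairs per scale")
    if (stats::sd(d$reference_value) == 0) {
      stop("reference column is constant; regression is degenerate")
    }
    fit <- stats::lm(local_value ~ reference_value, data = d)
    cf <- stats::coef(fit)
    r2 <- summary(fit)$r.squared
    itol <- intercept_tol[[match.arg(d$scale[1], names(intercept_tol))]]
    data.frame(scale = d$scale[1], slope = unname(cf[2]),
               intercept = unname(cf[1]), r_squared = r2,
               pass = abs(cf[2] - 1) <= slope_tol &&
                 abs(cf[1]) <= itol && r2 >= r2_min)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(list(fits = res, pass_flag = all(res$pass)),
            class = "calibration_validation")
}

#' @export
print.calibration_validation <- function(x, ...) {
  cat("centiloid calibration validation:",
      if (x$pass_flag) "PASS" else "FAIL", "\n")
  print(x$fits)
  invisible(x)
}
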