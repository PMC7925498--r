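# Internal-standard calibration: response = analyte area / ISD area
# regressed on nominal concentration, with regression-based LOD/LOQ.

#' Fit an internal-standard calibration curve
#'
#' Ordinary (or 1/x-weighted) least squares of the ISD-normalised response
#' on nominal concentration. The response of a level is
#' `analyte_area / isd_area`; supplying a `response` column directly is
#' also accepted. LOD and LOQ are attached from the regression residual
#' standard deviation (see [lod_loq()]).
#'
#' @param levels tibble of calibration levels with column `conc`
#'   (µg/mL) and either `response` or both `analyte_area` and `isd_area`.
#' @param weighting `"none"` (default, matching a plain least-squares
#'   design) or `"1/x"`.
#' @return An object of class `sq_calibration`: list with `slope`,
#'   `intercept`, `r_squared`, `residual_sd`, `n_levels`, `lod_ug_ml`,
#'   `loq_ug_ml`, `weighting`, `lod_method`, and the underlying `lm` fit.
#' @examples
#' lv <- tibble::tibble(conc = 1:10, response = 0.330 * (1:10) + 0.018)
#' fit_calibration(lv)
#' @export
fit_calibration <- function(levels, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  levels <- tibble::as_tibble(levels)
  if (!"response" %in% names(levels)) {
    if (!all(c("analyte_area", "isd_area") %in% names(levels))) {
      stop("levels need a 'response' column or 'analyte_area' + 'isd_area'",
           call. = FALSE)
    }
    if (any(levels$isd_area <= 0)) {
      stop("isd_area must be positive", call. = FALSE)
    }
    levels$response <- levels$analyte_area / levels$isd_area
  }
  if (nrow(levels) < 3L) {
    stop("calibration needs at least 3 levels", call. = FALSE)
  }
  if (stats::var(levels$conc) == 0) {
    stop("singular calibration: all concentrations identical", call. = FALSE)
  }
  if (stats::var(levels$response) == 0) {
    stop("singular calibration: constant response", call. = FALSE)
  }
  w <- if (weighting == "1/x") 1 / levels$conc else NULL
  fit <- stats::lm(response ~ conc, data = levels, weights = w)
  # noiseless fixtures trigger summary.lm's perfect-fit warning
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  out <- list(
    slope = unname(stats::coef(fit)["conc"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    r_squared = sm$r.squared,
    residual_sd = sm$sigma,
    n_levels = nrow(levels),
    weighting = weighting,
    lod_method = "calibration-curve residual SD (3.3*sd/slope, 10*sd/slope)",
    fit = fit,
    levels = levels
  )
  class(out) <- "sq_calibration"
  ll <- lod_loq(out)
  out$lod_ug_ml <- ll[["lod"]]
  out$loq_ug_ml <- ll[["loq"]]
  out
}

#' @export
print.sq_calibration <- function(x, ...) {
  cat("Internal-standard calibration (", x$n_levels, " levels, weighting ",
      x$weighting, ")\n", sep = "")
  cat(sprintf("  response = %.4g * conc + %.4g   (R^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  residual SD %.4g; LOD %.3g, LOQ %.3g ug/mL\n",
              x$residual_sd, x$lod_ug_ml, x$loq_ug_ml))
  invisible(x)
}

#' Limit of detection and quantification from a calibration curve
#'
#' Regression-statistics method: LOD = 3.3·σ/S and LOQ = 10·σ/S where σ is
#' the residual standard deviation and S the slope, so LOQ/LOD = 10/3.3
#' for any curve.
#'
#' @param curve an `sq_calibration` object.
#' @return Named numeric vector `c(lod = ..., loq = ...)` in µg/mL.
#' @examples
#' lv <- tibble::tibble(conc = 1:10,
#'                      response = 0.330 * (1:10) + rnorm(10, sd = 0.01))
#' lod_loq(fit_calibration(lv))
#' @export
lod_loq <- function(curve) {
  stopifnot(inherits(curve, "sq_calibration"))
  if (curve$slope <= 0) {
    stop("LOD/LOQ require a positive calibration slope", call. = FALSE)
  }
  c(lod = 3.3 * curve$residual_sd / curve$slope,
    loq = 10 * curve$residual_sd / curve$slope)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration fit
#'
#' @param x an `sq_calibration` object.
#' @param ... unused.
#' @return `tidy()`: one row per regression term with `estimate`,
#'   `std.error`, `statistic`, `p.value`. `glance()`: one-row model summary
#'   with `r.squared`, `sigma`, `slope`, `intercept`, `lod_ug_ml`,
#'   `loq_ug_ml`, `n_levels`, `weighting`.
#' @exportS3Method generics::tidy
#' @export
tidy.sq_calibration <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = sm[, "Estimate"],
    std.error = sm[, "Std. Error"],
    statistic = sm[, "t value"],
    p.value = sm[, "Pr(>|t|)"]
  )
}

#' @rdname tidy.sq_calibration
#' @exportS3Method generics::glance
#' @export
glance.sq_calibration <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    sigma = x$residual_sd,
    slope = x$slope,
    intercept = x$intercept,
    lod_ug_ml = x$lod_ug_ml,
    loq_ug_ml = x$loq_ug_ml,
    n_levels = x$n_levels,
    weighting = x$weighting
  )
}
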