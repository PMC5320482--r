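#' Standard-preparation uncertainty (U1)
#'
#' Propagates the uncertainty of preparing standards and stock solutions:
#' reference-material purity, the weighing step and each volumetric step
#' are converted to relative standard uncertainties and combined by root
#' sum of squares. Stated tolerances are treated as rectangular by default
#' (divided by sqrt(3)); triangular (sqrt(6)) and normal (already a
#' standard uncertainty) conversions are selectable.
#'
#' @param purity Length-2 numeric `c(value, tolerance)` for purity as a
#'   fraction, or `NULL`.
#' @param mass Length-2 numeric `c(nominal_mg, tolerance_mg)` for the
#'   weighing step, or `NULL`.
#' @param volumes List of length-2 (or length-3) numeric vectors
#'   `c(nominal_mL, tolerance_mL[, temperature_term_mL])` per volumetric
#'   step; the optional third entry is an additional standard uncertainty
#'   (e.g. thermal volume variation) added in quadrature for that step.
#' @param distribution Tolerance-to-SD conversion: `"rectangular"`
#'   (default), `"triangular"`, `"normal"`.
#' @return Relative standard uncertainty (dimensionless fraction).
#' @examples
#' u_standards(purity = c(0.990, 0.005))  # 0.00292
#' @export
u_standards <- function(purity = NULL, mass = NULL, volumes = list(),
                        distribution = c("rectangular", "triangular", "normal")) {
  distribution <- match.arg(distribution)
  divisor <- switch(distribution, rectangular = sqrt(3),
                    triangular = sqrt(6), normal = 1)
  rel <- function(nominal, tol) {
    if (nominal == 0) stop("zero nominal quantity in U1 component", call. = FALSE)
    if (tol < 0) stop("negative tolerance", call. = FALSE)
    (tol / divisor) / abs(nominal)
  }
  comps <- numeric(0)
  if (!is.null(purity)) comps <- c(comps, rel(purity[1], purity[2]))
  if (!is.null(mass)) comps <- c(comps, rel(mass[1], mass[2]))
  for (v in volumes) {
    u <- rel(v[1], v[2])
    if (length(v) >= 3L) u <- sqrt(u^2 + (v[3] / abs(v[1]))^2)
    comps <- c(comps, u)
  }
  if (length(comps) == 0L) return(0)
  sqrt(sum(comps^2))
}

#' Calibration-curve uncertainty (U2)
#'
#' Standard uncertainty of a concentration read off an unweighted linear
#' calibration, relative to the target concentration:
#' \deqn{s_{x_0} = \frac{s_y}{|b_1|}\sqrt{\frac{1}{m} + \frac{1}{n} +
#'   \frac{(x_0-\bar x)^2}{S_{xx}}}}
#' where \eqn{s_y} is the residual SD of the calibration fit, \eqn{b_1}
#' the slope, `n` the number of calibration points, and `m` the number of
#' replicate measurements of the unknown.
#'
#' @param curve A `"cv_calibration"` from [fit_calibration()] (must carry
#'   residual statistics).
#' @param m Replicate measurements of the unknown (>= 1).
#' @param x0 Target concentration (> 0), same units as the levels.
#' @return Relative standard uncertainty `s_x0 / x0`.
#' @export
u_calibration <- function(curve, m, x0) {
  stopifnot(inherits(curve, "cv_calibration"), m >= 1)
  if (is.null(curve$residual_sd)) {
    stop("curve lacks residual statistics; use fit_calibration()", call. = FALSE)
  }
  if (x0 <= 0) stop("x0 must be positive", call. = FALSE)
  s_x0 <- (curve$residual_sd / abs(curve$slope)) *
    sqrt(1 / m + 1 / curve$n + (x0 - curve$x_mean)^2 / curve$s_xx)
  s_x0 / x0
}

#' Precision uncertainty (U3)
#'
#' The RSD from repeatability or intermediate-precision assays expressed
#' as a relative fraction. When the reported result is itself a mean of
#' `n_assay` determinations, set `of_mean = TRUE` to divide by
#' `sqrt(n_assay)`; the default reports per-determination precision.
#'
#' @param rsd_percent RSD in percent (>= 0).
#' @param of_mean Divide by sqrt(n_assay)?
#' @param n_assay Number of determinations averaged.
#' @return Relative standard uncertainty.
#' @export
u_precision <- function(rsd_percent, of_mean = FALSE, n_assay = 1L) {
  stopifnot(rsd_percent >= 0)
  u <- rsd_percent / 100
  if (of_mean) u <- u / sqrt(n_assay)
  u
}

#' Recovery (accuracy) uncertainty (U4)
#'
#' Relative standard uncertainty of the mean recovery:
#' \eqn{(s_R/\sqrt{n}) / \bar R}.
#'
#' @param mean_recovery Mean recovery in percent (> 0).
#' @param sd_recovery SD of the recovery assays in percent.
#' @param n Number of recovery assays (>= 2).
#' @return Relative standard uncertainty.
#' @export
u_recovery <- function(mean_recovery, sd_recovery, n) {
  if (mean_recovery <= 0) stop("mean recovery must be positive", call. = FALSE)
  stopifnot(sd_recovery >= 0, n >= 2)
  (sd_recovery / sqrt(n)) / mean_recovery
}

#' Combine and expand an uncertainty budget
#'
#' The combined uncertainty is the root sum of squares of the relative
#' components, \eqn{U_c = \sqrt{U_1^2 + U_2^2 + U_3^2 + U_4^2}}; the
#' expanded uncertainty multiplies by a coverage factor (k = 2 for ~95 %
#' confidence) and is reported in percent.
#'
#' @param u Numeric vector of relative components (all >= 0); typically
#'   length 4.
#' @return `combine_uncertainty()`: the combined relative uncertainty.
#' @examples
#' uc <- combine_uncertainty(c(0.0015, 0.0232, 0.0045, 0.0303))
#' round(uc, 4)                 # 0.0385
#' expand_uncertainty(uc)       # 7.7 (percent, after 1-decimal rounding)
#' @export
combine_uncertainty <- function(u) {
  if (any(u < 0)) stop("uncertainty components must be >= 0", call. = FALSE)
  sqrt(sum(u^2))
}

#' @rdname combine_uncertainty
#' @param u_c Combined relative uncertainty.
#' @param k Coverage factor (default 2).
#' @param digits Decimals for the percent display (default 1,
#'   half-away-from-zero); `NULL` returns full precision.
#' @return `expand_uncertainty()`: expanded uncertainty in percent.
#' @export
expand_uncertainty <- function(u_c, k = 2, digits = 1) {
  stopifnot(u_c >= 0, k > 0)
  out <- 100 * k * u_c
  if (!is.null(digits)) out <- round_half_away(out, digits)
  out
}

#' Assemble a full uncertainty budget
#'
#' @param u1,u2,u3,u4 Relative components: standards preparation,
#'   calibration, precision, recovery.
#' @param k Coverage factor.
#' @param analyte Optional label.
#' @return A `"cv_uncertainty_budget"` list with the components, `u_c`,
#'   `k`, `u_exp_percent` (1-decimal display) and `u_exp_percent_raw`.
#' @export
uncertainty_budget <- function(u1, u2, u3, u4, k = 2,
                               analyte = NA_character_) {
  u <- c(u1 = u1, u2 = u2, u3 = u3, u4 = u4)
  u_c <- combine_uncertainty(u)
  structure(list(analyte = analyte, u1 = u1, u2 = u2, u3 = u3, u4 = u4,
                 u_c = u_c, k = k,
                 u_exp_percent = expand_uncertainty(u_c, k),
                 u_exp_percent_raw = expand_uncertainty(u_c, k, digits = NULL)),
            class = "cv_uncertainty_budget")
}

#' @export
print.cv_uncertainty_budget <- function(x, ...) {
  cat(sprintf("Uncertainty budget%s: U_c = %.4f, U_exp (k=%g) = %.1f%%\n",
              if (is.na(x$analyte)) "" else paste0(" [", x$analyte, "]"),
              x$u_c, x$k, x$u_exp_percent))
  invisible(x)
}
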