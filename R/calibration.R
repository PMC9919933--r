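#' Fit a Beer-Lambert UV calibration line
#'
#' Ordinary least squares fit of absorbance against concentration,
#' `A = slope * C + intercept`, the standard-curve step of a UV phase
#' solubility study.  The line is later inverted to turn measured absorbances
#' into guest concentrations.
#'
#' @param concentration guest concentrations in mM, strictly increasing,
#'   at least two distinct values.
#' @param absorbance matching optical absorbances (AU), all non-negative.
#' @param wavelength detection wavelength in nm (metadata only).
#' @param data optional data frame with columns `concentration` and
#'   `absorbance`, used when the two vectors are not given directly.
#' @return an object of class `uv_calibration` with components `slope`
#'   (AU/mM), `intercept` (AU), `r_squared` (squared Pearson correlation of
#'   the fit), `n_points`, `wavelength` and the input `data`.
#' @seealso [absorbance_to_concentration()], [fit_isotherm()]
#' @examples
#' cal <- fit_calibration(c(0, 0.5, 1), c(0.01, 0.52, 1.01))
#' coef(cal)
#' @export
fit_calibration <- function(concentration, absorbance, wavelength = NA_real_,
                            data = NULL) {
  if (!is.null(data)) {
    if (missing(concentration)) concentration <- data$concentration
    if (missing(absorbance)) absorbance <- data$absorbance
  }
  check_numeric(concentration, "concentration")
  check_numeric(absorbance, "absorbance")
  if (length(concentration) != length(absorbance))
    stop_invalid("concentration and absorbance must have equal length")
  if (length(concentration) < 2L)
    stop_invalid("need at least 2 calibration points")
  if (any(diff(concentration) <= 0))
    stop_invalid("concentrations must be strictly increasing")
  if (stats::var(concentration) == 0)
    stop_invalid("zero concentration variance: cannot fit a line")
  if (any(absorbance < 0)) stop_invalid("absorbances must be >= 0")

  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 0)
    warning("calibration slope is not positive; the line cannot be inverted",
            call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 n_points = length(concentration),
                 wavelength = wavelength,
                 data = data.frame(concentration = concentration,
                                   absorbance = absorbance)),
            class = "uv_calibration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a calibration from known coefficients
#'
#' Wraps externally reported slope/intercept values (for example a published
#' standard-curve equation) in the same class [fit_calibration()] returns.
#'
#' @param slope line slope in AU/mM; must be positive to be invertible.
#' @param intercept line intercept in AU.
#' @param r_squared optional fit quality.
#' @param wavelength detection wavelength in nm (metadata).
#' @return a `uv_calibration` object.
#' @export
calibration_curve <- function(slope, intercept, r_squared = NA_real_,
                              wavelength = NA_real_) {
  check_numeric(slope, "slope"); check_numeric(intercept, "intercept")
  if (!is.na(r_squared) && (r_squared < 0 || r_squared > 1))
    stop_invalid("`r_squared` must lie in [0, 1]")
  structure(list(slope = slope, intercept = intercept, r_squared = r_squared,
                 n_points = NA_integer_, wavelength = wavelength, data = NULL),
            class = "uv_calibration")
}

#' @export
print.uv_calibration <- function(x, digits = 6, ...) {
  cat("Beer-Lambert calibration: A =",
      fmt_num(x$slope, digits), "* C(mM) +", fmt_num(x$intercept, digits), "\n")
  if (!is.na(x$r_squared)) cat("  R-squared:", fmt_num(x$r_squared, digits), "\n")
  if (!is.na(x$n_points)) cat("  points:", x$n_points, "\n")
  if (!is.na(x$wavelength)) cat("  wavelength:", x$wavelength, "nm\n")
  invisible(x)
}

#' @export
coef.uv_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.uv_calibration <- function(object, newdata = NULL, ...) {
  conc <- if (is.data.frame(newdata)) newdata$concentration else newdata
  if (is.null(conc)) conc <- object$data$concentration
  object$slope * conc + object$intercept
}

#' @export
plot.uv_calibration <- function(x, ...) {
  if (is.null(x$data)) stop_invalid("no data stored with this calibration")
  graphics::plot(x$data$concentration, x$data$absorbance,
                 xlab = "concentration (mM)", ylab = "absorbance (AU)",
                 main = "UV calibration", ...)
  graphics::abline(x$intercept, x$slope, col = "grey40")
  invisible(x)
}

#' Invert a calibration line
#'
#' Converts a measured absorbance back to concentration,
#' `C = d * (A - intercept) / slope`, where `d` is the dilution factor of the
#' measured sample.  Values below the intercept yield negative
#' concentrations, which are returned as-is; the caller decides whether to
#' clip.
#'
#' @param curve a `uv_calibration` with positive slope.
#' @param absorbance measured absorbance(s), AU.
#' @param dilution_factor dimensionless dilution applied before measurement
#'   (>= 1 in practice); default 1.
#' @return concentration(s) in mM.
#' @examples
#' cal <- calibration_curve(slope = 2, intercept = 0)
#' absorbance_to_concentration(cal, 1, dilution_factor = 10)  # 5 mM
#' @export
absorbance_to_concentration <- function(curve, absorbance, dilution_factor = 1) {
  if (!inherits(curve, "uv_calibration"))
    stop_invalid("`curve` must be a uv_calibration")
  if (!is.finite(curve$slope) || curve$slope <= 0)
    stop_invalid("invalid calibration: slope must be > 0 to invert")
  check_numeric(absorbance, "absorbance")
  if (dilution_factor < 1) stop_invalid("`dilution_factor` must be >= 1")
  dilution_factor * (absorbance - curve$intercept) / curve$slope
}
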