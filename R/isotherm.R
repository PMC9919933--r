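#' Fit a phase-solubility isotherm
#'
#' Builds a Higuchi-Connors phase-solubility diagram from UV absorbances
#' measured at increasing host (cyclodextrin) concentrations: absorbances
#' are inverted through the calibration line into guest solubilities, then
#' solubility is OLS-fitted against host concentration with both axes in the
#' same molar unit, so the slope `K` is dimensionless.  A linear diagram with
#' `0 < K < 1` is the AL type diagnostic of 1:1 complexation, and the 1:1
#' stability constant follows as `Ks = K / (S0 * (1 - K))` with `S0` the
#' fitted intercept (the intrinsic guest solubility).
#'
#' The zero-host point is included in the fit but `S0` is taken from the
#' fitted intercept, not from that measured point.  Negative computed
#' solubilities are retained (with a warning) so the fit stays unbiased.
#'
#' @param host_concentration host concentrations in mM; must include 0 and
#'   have at least 3 points.
#' @param absorbance measured absorbances (AU), same length.
#' @param calibration a [fit_calibration()] / [calibration_curve()] object.
#' @param dilution_factor dilution applied before the UV measurement
#'   (default 1).
#' @param al_r2 minimum fit R-squared for the diagram to be called linear
#'   (AL); default 0.95.
#' @return an object of class `phase_solubility` with components
#'   `slope_K` (dimensionless), `intercept_S0` (mM), `r_squared`,
#'   `isotherm_class` (`"AL"` or `"nonlinear"`), `Ks` (1/M; `NA` for a
#'   nonlinear diagram), and the `data` (host concentration, absorbance,
#'   guest solubility).
#' @examples
#' cal <- calibration_curve(slope = 20.83333, intercept = 0.06792)
#' iso <- fit_isotherm(c(0, 2, 4, 6, 8, 10),
#'                     c(0.145, 0.253, 0.298, 0.343, 0.401, 0.447), cal)
#' iso$Ks  # 1:1 stability constant, 1/M
#' @export
fit_isotherm <- function(host_concentration, absorbance, calibration,
                         dilution_factor = 1, al_r2 = 0.95) {
  check_numeric(host_concentration, "host_concentration")
  check_numeric(absorbance, "absorbance")
  if (length(host_concentration) != length(absorbance))
    stop_invalid("host_concentration and absorbance must have equal length")
  if (length(host_concentration) < 3L)
    stop_invalid("need at least 3 points for a phase-solubility diagram")
  if (!any(host_concentration == 0))
    stop_invalid("the diagram must include the zero-host point")
  solubility <- absorbance_to_concentration(calibration, absorbance,
                                            dilution_factor)
  if (any(solubility < 0))
    warning("negative computed solubilities retained in the fit ",
            "(absorbance below the calibration intercept)", call. = FALSE)
  fit <- stats::lm(solubility ~ host_concentration)
  K <- unname(stats::coef(fit)[2L])           # dimensionless: mM per mM
  S0 <- unname(stats::coef(fit)[1L])          # mM
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (K <= 0 || K >= 1)
    stop_invalid("not AL: isotherm slope K = ", fmt_num(K),
                 " outside (0, 1); a 1:1 AL diagram requires 0 < K < 1")
  cls <- if (r2 >= al_r2) "AL" else "nonlinear"
  Ks <- if (cls == "AL" && S0 > 0) stability_constant(K, S0 * 1e-3) else NA_real_
  structure(list(slope_K = K, intercept_S0 = S0, r_squared = r2,
                 isotherm_class = cls, Ks = Ks,
                 dilution_factor = dilution_factor,
                 data = data.frame(host_concentration = host_concentration,
                                   absorbance = absorbance,
                                   solubility = solubility),
                 fit = fit),
            class = "phase_solubility")
}

#' @export
print.phase_solubility <- function(x, digits = 5, ...) {
  cat("Phase-solubility isotherm (", x$isotherm_class, " type)\n", sep = "")
  cat("  slope K     :", fmt_num(x$slope_K, digits), "\n")
  cat("  intercept S0:", fmt_num(x$intercept_S0, digits), "mM\n")
  cat("  R-squared   :", fmt_num(x$r_squared, digits), "\n")
  if (!is.na(x$Ks))
    cat("  Ks (1:1)    :", fmt_num(x$Ks, digits), "1/M\n")
  invisible(x)
}

#' @export
summary.phase_solubility <- function(object, ...) {
  out <- list(isotherm = object,
              n_points = nrow(object$data),
              solubility_range_mM = range(object$data$solubility),
              lm_summary = summary(object$fit))
  class(out) <- "summary.phase_solubility"
  out
}

#' @export
print.summary.phase_solubility <- function(x, ...) {
  print(x$isotherm)
  cat("  points      :", x$n_points, "\n")
  cat("  solubility  :", fmt_num(x$solubility_range_mM[1]), "to",
      fmt_num(x$solubility_range_mM[2]), "mM\n")
  cat("\nUnderlying linear fit:\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.phase_solubility <- function(object, ...) {
  c(S0 = object$intercept_S0, K = object$slope_K)
}

#' @export
predict.phase_solubility <- function(object, newdata = NULL, ...) {
  host <- if (is.data.frame(newdata)) newdata$host_concentration else newdata
  if (is.null(host)) host <- object$data$host_concentration
  object$intercept_S0 + object$slope_K * host
}

#' @export
residuals.phase_solubility <- function(object, ...) {
  object$data$solubility - predict(object)
}

#' @export
plot.phase_solubility <- function(x, ...) {
  graphics::plot(x$data$host_concentration, x$data$solubility,
                 xlab = "host concentration (mM)",
                 ylab = "guest solubility (mM)",
                 main = "Phase-solubility diagram", ...)
  graphics::abline(x$intercept_S0, x$slope_K, col = "grey40")
  invisible(x)
}

#' 1:1 stability constant from an AL isotherm
#'
#' `Ks = K / (S0 * (1 - K))` where `K` is the dimensionless isotherm slope
#' and `S0` the intrinsic guest solubility in mol/L.  Valid on
#' `0 < K < 1`, `S0 > 0`.
#'
#' @param slope_K dimensionless isotherm slope, in (0, 1).
#' @param intercept_S0 intrinsic solubility in mol/L (note: not mM).
#' @return stability constant in 1/M.
#' @examples
#' stability_constant(0.5, 1)  # 1
#' @export
stability_constant <- function(slope_K, intercept_S0) {
  check_numeric(slope_K, "slope_K"); check_numeric(intercept_S0, "intercept_S0")
  if (any(slope_K <= 0 | slope_K >= 1))
    stop_invalid("`slope_K` must lie strictly in (0, 1)")
  if (any(intercept_S0 <= 0)) stop_invalid("`intercept_S0` must be > 0 (mol/L)")
  slope_K / (intercept_S0 * (1 - slope_K))
}

#' Rank systems by stability constant
#'
#' Orders named isotherms by descending `Ks`; ties keep input order.
#'
#' @param isotherms a named list of `phase_solubility` objects, or a named
#'   numeric vector of Ks values.
#' @return character vector of names, most stable first.
#' @export
rank_by_ks <- function(isotherms) {
  if (is.list(isotherms)) {
    ks <- vapply(isotherms, function(x) {
      if (inherits(x, "phase_solubility")) x$Ks else as.numeric(x)
    }, numeric(1))
  } else ks <- as.numeric(isotherms)
  nms <- names(isotherms)
  if (is.null(nms)) stop_invalid("`isotherms` must be named")
  ok <- !is.na(ks)
  if (!any(ok)) stop_invalid("no isotherm with a valid Ks")
  nms <- nms[ok]; ks <- ks[ok]
  nms[order(-ks, seq_along(ks))]
}
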