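#' Mean square displacement
#'
#' `MSD(t) = <|r_i(t) - r_i(0)|^2>`, averaged over the selected particles.
#' With `origins = "single"` the first frame is the one time origin, which is
#' the literal textbook definition; with `origins = "multiple"` (default)
#' every frame that admits a given lag serves as an origin, which improves
#' statistics at the cost of correlated samples.  Coordinates must be
#' unwrapped: a jump larger than half a cell edge between consecutive frames
#' triggers a warning.
#'
#' @param traj an [md_trajectory()].
#' @param selection atom selection (see [select_atoms()] forms: `NULL`,
#'   indices, logical mask, or `"key=value"` such as `"role=guest"`).
#' @param origins `"multiple"` or `"single"`.
#' @param max_lag largest lag in frames; defaults to `n_frames - 1` for
#'   single-origin and `floor((n_frames - 1) / 2)` for multiple origins.
#' @return an object of class `msd_result`: data frame columns `lag_ps` and
#'   `msd` (Angstrom^2), plus attributes `selection`, `origins`,
#'   `n_origins` (origins averaged per lag).
#' @seealso [estimate_diffusion()]
#' @export
mean_square_displacement <- function(traj, selection = NULL,
                                     origins = c("multiple", "single"),
                                     max_lag = NULL) {
  origins <- match.arg(origins)
  if (!inherits(traj, "md_trajectory")) stop_invalid("`traj` must be an md_trajectory")
  nf <- n_frames(traj)
  if (nf < 2L) stop_invalid("need at least 2 frames")
  sel <- select_atoms(traj$atoms, selection)
  if (length(sel) == 0L) stop_invalid("empty atom selection")
  A <- traj$coords[sel, , , drop = FALSE]

  if (traj$cell$periodic) {
    half <- min(traj$cell$edges) / 2
    jumps <- abs(A[, , -1L, drop = FALSE] - A[, , -nf, drop = FALSE])
    if (any(jumps > half))
      warning("consecutive-frame jump exceeds half a cell edge: coordinates ",
              "look wrapped; MSD requires unwrapped coordinates", call. = FALSE)
  }

  if (is.null(max_lag))
    max_lag <- if (origins == "single") nf - 1L else (nf - 1L) %/% 2L
  max_lag <- max(1L, min(as.integer(max_lag), nf - 1L))
  lags <- 0:max_lag

  msd <- numeric(length(lags))
  n_orig <- integer(length(lags))
  n_orig[1L] <- if (origins == "single") 1L else nf
  for (j in seq_along(lags)[-1L]) {
    L <- lags[j]
    if (origins == "single") {
      d <- A[, , 1L + L] - A[, , 1L]
      msd[j] <- mean(rowSums(matrix(d, ncol = 3L)^2))
      n_orig[j] <- 1L
    } else {
      d <- A[, , (1L + L):nf, drop = FALSE] - A[, , 1:(nf - L), drop = FALSE]
      msd[j] <- sum(d * d) / (dim(d)[1L] * dim(d)[3L])
      n_orig[j] <- nf - L
    }
  }
  dt <- if (nf > 1L) traj$times[2L] - traj$times[1L] else traj$timestep
  structure(data.frame(lag_ps = lags * dt, msd = msd),
            selection = if (is.null(selection)) "all" else
              paste(deparse(selection), collapse = ""),
            origins = origins, n_origins = n_orig,
            class = c("msd_result", "data.frame"))
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("MSD over %d lags (0..%s ps), %s time origin(s)\n",
              nrow(x), fmt_num(max(x$lag_ps)), attr(x, "origins")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5L) cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  invisible(x)
}

#' @export
plot.msd_result <- function(x, ...) {
  graphics::plot(x$lag_ps, x$msd, type = "l", xlab = "lag (ps)",
                 ylab = expression(MSD ~ (ring(A)^2)),
                 main = "Mean square displacement", ...)
  invisible(x)
}

#' Diffusion coefficient from an MSD curve
#'
#' Einstein relation in three dimensions: `MSD(t) ~ 6 D t`, so `D` is one
#' sixth of the OLS slope of MSD against lag time inside the fit window.
#'
#' @param msd an `msd_result`.
#' @param fit_window numeric length-2 lag range in ps (inclusive); default
#'   the full computed range.
#' @return diffusion coefficient `D` in Angstrom^2/ps.
#' @examples
#' m <- structure(data.frame(lag_ps = 0:10, msd = 0.6 * (0:10)),
#'                class = c("msd_result", "data.frame"))
#' estimate_diffusion(m)  # 0.1
#' @export
estimate_diffusion <- function(msd, fit_window = NULL) {
  if (!inherits(msd, "msd_result")) stop_invalid("`msd` must be an msd_result")
  if (is.null(fit_window)) fit_window <- range(msd$lag_ps)
  keep <- msd$lag_ps >= fit_window[1L] & msd$lag_ps <= fit_window[2L]
  if (sum(keep) < 2L)
    stop_invalid("fit window [", fit_window[1L], ", ", fit_window[2L],
                 "] ps holds fewer than 2 MSD points")
  fit <- stats::lm(msd ~ lag_ps, data = as.data.frame(msd)[keep, ])
  unname(stats::coef(fit)[2L]) / 6
}
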