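#' Radial distribution function
#'
#' `g(r) = dN / (N_a * rho_b * 4 pi r^2 dr)`: the frame-averaged histogram of
#' minimum-image pair distances between two atom groups, normalised by shell
#' volume, by the number of reference atoms and by the mean number density of
#' the partner group, so an ideal gas plateaus at 1.  Self pairs are excluded
#' when the groups overlap.
#'
#' @param traj an [md_trajectory()] (or a single [md_frame()]) with a
#'   periodic cell.
#' @param group_a,group_b atom selections (reference and partner group);
#'   `NULL` selects all atoms.
#' @param dr bin width in Angstrom (half-open bins `[r, r + dr)`).
#' @param r_max histogram range; defaults to half the smallest cell edge and
#'   may not exceed it.
#' @return an object of class `rdf_result`: data frame columns `r` (bin
#'   centers, Angstrom), `g` (dimensionless) and `counts` (raw pair counts
#'   summed over frames), with attributes `dr`, `density` (partner atoms per
#'   Angstrom^3), `n_frames`.
#' @examples
#' traj <- ideal_gas_frames(n = 200, box_edge = 20, n_frames = 5, seed = 1)
#' rdf <- radial_distribution(traj, dr = 0.5)
#' @export
radial_distribution <- function(traj, group_a = NULL, group_b = NULL,
                                dr = 0.1, r_max = NULL) {
  if (inherits(traj, "md_frame")) traj <- md_trajectory(list(traj))
  if (!inherits(traj, "md_trajectory")) stop_invalid("`traj` must be an md_trajectory")
  cell <- traj$cell
  if (!cell$periodic)
    stop_invalid("radial_distribution requires a periodic cell")
  half_edge <- min(cell$edges) / 2
  if (is.null(r_max)) r_max <- half_edge
  if (r_max > half_edge + 1e-9)
    stop_invalid("r_max = ", r_max, " exceeds half the smallest cell edge (",
                 fmt_num(half_edge), ")")
  if (dr <= 0 || r_max <= dr) stop_invalid("need 0 < dr < r_max")

  ia <- select_atoms(traj$atoms, group_a)
  ib <- select_atoms(traj$atoms, group_b)
  if (length(ia) == 0L || length(ib) == 0L)
    stop_invalid("empty atom group")
  nf <- n_frames(traj)
  # use whole bins only: the histogram stops at the last full bin edge
  n_bins <- max(1L, floor(r_max / dr + 1e-9))
  r_max <- n_bins * dr
  edges <- (0:n_bins) * dr
  counts <- numeric(n_bins)

  same <- outer(traj$atoms$index[ia], traj$atoms$index[ib], "==")
  for (f in seq_len(nf)) {
    xa <- matrix(traj$coords[ia, , f], ncol = 3L)
    xb <- matrix(traj$coords[ib, , f], ncol = 3L)
    d2 <- matrix(0, length(ia), length(ib))
    for (k in 1:3) {
      dk <- outer(xa[, k], xb[, k], "-")
      dk <- dk - cell$edges[k] * round(dk / cell$edges[k])
      d2 <- d2 + dk * dk
    }
    r <- sqrt(d2[!same])
    r <- r[r < r_max]
    if (length(r))
      counts <- counts + tabulate(findInterval(r, edges), nbins = n_bins)
  }

  vol <- cell_volume(cell)
  rho_b <- length(ib) / vol
  centers <- edges[-length(edges)] + dr / 2
  shell <- 4 * pi * centers^2 * dr
  g <- counts / (nf * length(ia) * rho_b * shell)
  if (all(counts == 0))
    warning("no pair within r_max; g(r) is identically zero", call. = FALSE)
  structure(data.frame(r = centers, g = g, counts = counts),
            dr = dr, density = rho_b, n_frames = nf,
            class = c("rdf_result", "data.frame"))
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("g(r): %d bins of %s Angstrom over %d frame(s); partner density %s /A^3\n",
              nrow(x), fmt_num(attr(x, "dr")), attr(x, "n_frames"),
              fmt_num(attr(x, "density"))))
  pk <- x$r[which.max(x$g)]
  if (any(x$g > 0))
    cat("  first maximum: g =", fmt_num(max(x$g)), "at r =", fmt_num(pk),
        "A (", classify_interaction(pk), ")\n")
  invisible(x)
}

#' @export
plot.rdf_result <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "l", xlab = "r (Angstrom)", ylab = "g(r)",
                 main = "Radial distribution function", ...)
  graphics::abline(h = 1, lty = 3, col = "grey60")
  invisible(x)
}

#' Classify an RDF peak position into an interaction band
#'
#' Peaks between 2.5 and 3.0 Angstrom indicate hydrogen bonds, 3.0 to 5.0
#' strong van der Waals contacts, and beyond 5.0 weak van der Waals
#' interactions.  Distances below 2.5 Angstrom fall outside the published
#' bands; they are reported as hydrogen bonds with a warning because nothing
#' longer-ranged can act there.
#'
#' @param r peak position(s) in Angstrom, positive.
#' @return character vector over `{"hydrogen_bond", "strong_vdw", "weak_vdw"}`.
#' @examples
#' classify_interaction(c(2.7, 4.0, 6.0))
#' @export
classify_interaction <- function(r) {
  check_numeric(r, "r")
  if (any(r <= 0)) stop_invalid("peak position must be > 0")
  if (any(r < 2.5))
    warning("peak below 2.5 Angstrom is unusually short for a noncovalent ",
            "contact; classified as hydrogen_bond", call. = FALSE)
  ifelse(r < 3.0, "hydrogen_bond", ifelse(r < 5.0, "strong_vdw", "weak_vdw"))
}
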