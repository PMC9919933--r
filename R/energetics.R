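#' Host-guest binding energy
#'
#' `E_binding = -E_inter = -(E_total - E_guest - E_host)`.  A positive
#' binding energy means favourable association: the complex sits lower in
#' energy than its separated components.
#'
#' @param e_total energy of the complex system, kcal/mol.
#' @param e_guest energy of the isolated guest, kcal/mol.
#' @param e_host energy of the isolated host, kcal/mol.
#' @return an object of class `energy_components` with fields `e_total`,
#'   `e_guest`, `e_host`, `e_binding` (all kcal/mol).
#' @examples
#' binding_energy(-100, -30, -50)$e_binding  # 20
#' @export
binding_energy <- function(e_total, e_guest, e_host) {
  check_numeric(e_total, "e_total"); check_numeric(e_guest, "e_guest")
  check_numeric(e_host, "e_host")
  structure(list(e_total = e_total, e_guest = e_guest, e_host = e_host,
                 e_binding = -(e_total - e_guest - e_host)),
            class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat("E_total =", fmt_num(x$e_total), " E_guest =", fmt_num(x$e_guest),
      " E_host =", fmt_num(x$e_host), "kcal/mol\n")
  cat("E_binding = -(E_total - E_guest - E_host) =",
      fmt_num(x$e_binding), "kcal/mol\n")
  invisible(x)
}

#' Binding energy from a per-frame energy table
#'
#' Averages the `total`, `guest` and `host` components over a trailing
#' window of frames (production-run practice: the last few frames of an
#' equilibrated trajectory) before applying [binding_energy()].
#'
#' @param energies data frame with columns `frame`, `component`,
#'   `value_kcal_mol`; components must include `total`, `guest`, `host`.
#' @param window number of trailing frames to average (default 5).
#' @return an `energy_components` object, with attribute `frames_used`.
#' @export
binding_energy_from_table <- function(energies, window = 5) {
  need <- c("total", "guest", "host")
  if (!all(need %in% energies$component))
    stop_invalid("energy table must contain components ",
                 paste(need, collapse = ", "))
  if (window < 1) stop_invalid("`window` must be >= 1")
  frames <- sort(unique(energies$frame))
  use <- utils::tail(frames, window)
  mean_of <- function(comp) {
    v <- energies$value_kcal_mol[energies$component == comp &
                                 energies$frame %in% use]
    if (!length(v)) stop_invalid("component '", comp, "' missing in window")
    mean(v)
  }
  out <- binding_energy(mean_of("total"), mean_of("guest"), mean_of("host"))
  attr(out, "frames_used") <- use
  out
}

#' Nonbonded force-field parameters
#'
#' Per-element 12-6 Lennard-Jones parameters plus a Coulomb term, the toy
#' pairwise-additive stand-in used by [pairwise_energy()] and the synthetic
#' two-cluster systems.  Mixing is Lorentz-Berthelot: arithmetic-mean sigma,
#' geometric-mean epsilon.
#'
#' @param epsilon named numeric vector of LJ well depths per element,
#'   kcal/mol.
#' @param sigma named numeric vector of LJ diameters per element, Angstrom.
#' @param coulomb_k Coulomb constant, kcal Angstrom / (mol e^2).
#' @param cutoff pair interaction cutoff, Angstrom.
#' @return an object of class `nonbonded_params`.
#' @export
nonbonded_params <- function(epsilon = c(O = 0.21, H = 0.03, C = 0.10, X = 0.15),
                             sigma = c(O = 3.12, H = 2.20, C = 3.40, X = 3.00),
                             coulomb_k = 332.0637, cutoff = 12) {
  check_numeric(epsilon, "epsilon"); check_numeric(sigma, "sigma")
  if (any(epsilon <= 0) || any(sigma <= 0) || cutoff <= 0)
    stop_invalid("epsilon, sigma and cutoff must all be > 0")
  if (is.null(names(epsilon)) || is.null(names(sigma)))
    stop_invalid("epsilon and sigma must be named by element")
  structure(list(epsilon = epsilon, sigma = sigma,
                 coulomb_k = coulomb_k, cutoff = cutoff),
            class = "nonbonded_params")
}

#' Pairwise nonbonded energy of a frame
#'
#' Sums `4 eps_ij [ (sig_ij/r)^12 - (sig_ij/r)^6 ] + k q_i q_j / r` over
#' unique atom pairs within the cutoff, with minimum-image distances under a
#' periodic cell and Lorentz-Berthelot mixing.  No tail corrections.
#'
#' @param frame an [md_frame()] carrying elements and charges.
#' @param params a [nonbonded_params()].
#' @param subset optional atom selection; the energy is computed among those
#'   atoms only (used to get isolated host / guest energies of a complex).
#' @return total energy in kcal/mol.
#' @export
pairwise_energy <- function(frame, params = nonbonded_params(), subset = NULL) {
  if (!inherits(frame, "md_frame")) stop_invalid("`frame` must be an md_frame")
  idx <- select_atoms(frame$atoms, subset)
  n <- length(idx)
  if (n < 2L) return(0)
  el <- frame$atoms$element[idx]
  unknown <- setdiff(el, names(params$epsilon))
  if (length(unknown))
    stop_invalid("no LJ parameters for element(s): ",
                 paste(unknown, collapse = ", "))
  q <- frame$atoms$charge[idx]
  X <- frame$coords[idx, , drop = FALSE]
  D <- cross_dist(X, X, frame$cell)
  pair <- which(upper.tri(D), arr.ind = TRUE)
  r <- D[pair]
  keep <- r <= params$cutoff
  pair <- pair[keep, , drop = FALSE]; r <- r[keep]
  if (!nrow(pair)) return(0)
  if (any(r == 0))
    stop_invalid("degenerate geometry: coincident atom pair at zero distance")
  i <- pair[, 1L]; j <- pair[, 2L]
  sig <- (params$sigma[el[i]] + params$sigma[el[j]]) / 2
  eps <- sqrt(params$epsilon[el[i]] * params$epsilon[el[j]])
  sr6 <- (sig / r)^6
  sum(4 * eps * (sr6^2 - sr6) + params$coulomb_k * q[i] * q[j] / r)
}

#' Hildebrand solubility parameter
#'
#' `delta = sqrt(CED) = sqrt(DeltaE / V)`, the square root of the cohesive
#' energy density.  The cohesive energy may be given directly (cal/mol) or
#' derived from a molar heat of vaporisation via `DeltaE = DeltaH - R T`
#' (the RT term removes the expansion work of vaporisation).
#'
#' @param cohesive_energy cohesive energy DeltaE in cal/mol (positive by the
#'   convention E_isolated - E_bulk); give either this or `delta_h`.
#' @param molar_volume molar volume V in cm^3/mol, positive.
#' @param delta_h molar heat of vaporisation in cal/mol (alternative input).
#' @param temperature temperature in K (DeltaH path only), default 298.
#' @param gas_constant R in cal/(mol K), default 1.9872.
#' @return an object of class `cohesive_energy` with fields
#'   `cohesive_energy` (cal/mol), `molar_volume` (cm^3/mol), `ced`
#'   (cal/cm^3) and `delta` ((cal/cm^3)^(1/2)).
#' @examples
#' solubility_parameter(cohesive_energy = 160.0225 * 100,
#'                      molar_volume = 100)$delta  # 12.650
#' @export
solubility_parameter <- function(cohesive_energy = NULL, molar_volume,
                                 delta_h = NULL, temperature = 298,
                                 gas_constant = 1.9872) {
  check_numeric(molar_volume, "molar_volume")
  if (molar_volume <= 0) stop_invalid("`molar_volume` must be > 0 (cm^3/mol)")
  if (is.null(cohesive_energy)) {
    if (is.null(delta_h))
      stop_invalid("give either `cohesive_energy` or `delta_h`")
    check_numeric(delta_h, "delta_h")
    cohesive_energy <- delta_h - gas_constant * temperature
  }
  check_numeric(cohesive_energy, "cohesive_energy")
  if (cohesive_energy < 0)
    stop_invalid("cohesive energy must be >= 0: use the convention ",
                 "DeltaE = E_isolated - E_bulk (positive for a cohesive phase)")
  ced <- cohesive_energy / molar_volume
  structure(list(cohesive_energy = cohesive_energy,
                 molar_volume = molar_volume, ced = ced, delta = sqrt(ced),
                 temperature = temperature, gas_constant = gas_constant),
            class = "cohesive_energy")
}

#' @export
print.cohesive_energy <- function(x, ...) {
  cat("CED =", fmt_num(x$ced), "cal/cm^3; delta =", fmt_num(x$delta),
      "(cal/cm^3)^1/2\n")
  invisible(x)
}

#' Solubility-parameter compatibility verdict
#'
#' Classifies the absolute difference of two Hildebrand parameters:
#' below 1.0 (cal/cm^3)^(1/2) the pair is compatible, from 1.0 to 3.4 it may
#' be compatible, above 4.9 it is incompatible.  The published rules leave
#' (3.4, 4.9\] unassigned; that gap is reported as `indeterminate` rather
#' than silently extended onto a neighbour.
#'
#' @param delta_a,delta_b solubility parameters, (cal/cm^3)^(1/2).
#' @return an object of class `compatibility_verdict` with fields `delta_a`,
#'   `delta_b`, `difference` and `category`.
#' @examples
#' compatibility(12.650, 12.422)$category  # "compatible"
#' @export
compatibility <- function(delta_a, delta_b) {
  check_numeric(delta_a, "delta_a"); check_numeric(delta_b, "delta_b")
  d <- abs(delta_a - delta_b)
  category <- if (d < 1.0) "compatible"
  else if (d <= 3.4) "may_be_compatible"
  else if (d <= 4.9) "indeterminate"
  else "incompatible"
  structure(list(delta_a = delta_a, delta_b = delta_b, difference = d,
                 category = category),
            class = "compatibility_verdict")
}

#' @export
print.compatibility_verdict <- function(x, ...) {
  cat(sprintf("|%s - %s| = %s (cal/cm^3)^1/2 -> %s\n", fmt_num(x$delta_a),
              fmt_num(x$delta_b), fmt_num(x$difference), x$category))
  invisible(x)
}
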