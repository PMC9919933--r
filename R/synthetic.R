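## Seeded generators producing every input the analyses consume, with known
## ground truth.  Each is a pure function of its arguments plus `seed`; the
## caller's RNG state is never touched.

#' Simulate a phase-solubility experiment
#'
#' Generates a noiseless Beer-Lambert calibration series plus a noisy
#' AL-type isotherm from a known stability constant.  Under the 1:1 model
#' the isotherm slope is `K = Ks S0 / (1 + Ks S0)` (the algebraic inverse of
#' `Ks = K / (S0 (1 - K))`), guest solubility is `S(C) = S0 + K C`, and the
#' measured absorbance is `A = m S + b` perturbed multiplicatively by
#' Gaussian noise `(1 + eps)`, `eps ~ N(0, noise_sd)` - instrument-like
#' relative noise.  Defaults mirror the study design: host grid 0-10 mM in
#' 2 mM steps, calibration 0.02-0.09 mM, and the published standard-curve
#' coefficients.
#'
#' @param true_ks ground-truth stability constant, 1/M (>= 0; 0 gives a flat
#'   diagram that the fitting pipeline rejects as non-AL).
#' @param true_s0 ground-truth intrinsic solubility, mol/L (> 0).
#' @param cal_slope,cal_intercept calibration line, AU/mM and AU.
#' @param host_concentrations host grid in mM (must include 0).
#' @param cal_concentrations calibration grid in mM.
#' @param noise_sd relative (multiplicative) absorbance noise sd; default 1%.
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @return a list with `calibration` (data frame concentration/absorbance),
#'   `isotherm` (data frame host_concentration/absorbance) and `truth`
#'   (list with `ks`, `s0`, `slope_K`).
#' @examples
#' sim <- simulate_isotherm(true_ks = 1000, true_s0 = 3e-6, noise_sd = 0)
#' sim$truth$slope_K  # 2.991e-3
#' @export
simulate_isotherm <- function(true_ks, true_s0,
                              cal_slope = 20.83333, cal_intercept = 0.06792,
                              host_concentrations = seq(0, 10, by = 2),
                              cal_concentrations = seq(0.02, 0.09, by = 0.01),
                              noise_sd = 0.01, seed = NULL) {
  check_numeric(true_ks, "true_ks"); check_numeric(true_s0, "true_s0")
  if (true_ks < 0) stop_invalid("`true_ks` must be >= 0")
  if (true_s0 <= 0) stop_invalid("`true_s0` must be > 0 (mol/L)")
  if (cal_slope <= 0) stop_invalid("`cal_slope` must be > 0")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0")
  K <- true_ks * true_s0 / (1 + true_ks * true_s0)
  if (K >= 1) stop_invalid("spec error: implied isotherm slope K >= 1")
  s_mM <- true_s0 * 1e3 + K * host_concentrations        # mM
  a_iso <- cal_slope * s_mM + cal_intercept
  a_iso <- with_seed(seed, a_iso * (1 + stats::rnorm(length(a_iso), 0, noise_sd)))
  a_cal <- cal_slope * cal_concentrations + cal_intercept
  list(calibration = data.frame(concentration = cal_concentrations,
                                absorbance = a_cal),
       isotherm = data.frame(host_concentration = host_concentrations,
                             absorbance = a_iso),
       truth = list(ks = true_ks, s0 = true_s0, slope_K = K))
}

#' Brownian particle trajectory
#'
#' Independent Gaussian steps per particle and axis with variance
#' `2 D dt`, so three-dimensional diffusion gives `MSD(t) = 6 D t`.
#' Coordinates are unwrapped (they may leave the box); the periodic cell is
#' attached as metadata only.
#'
#' @param n_particles number of particles.
#' @param d diffusion coefficient, Angstrom^2/ps.
#' @param dt timestep, ps.
#' @param n_steps number of steps (the trajectory has `n_steps + 1` frames).
#' @param box_edge cubic cell edge, Angstrom.
#' @param seed integer seed.
#' @return an [md_trajectory()] with unwrapped coordinates.
#' @export
brownian_trajectory <- function(n_particles = 500, d = 0.1, dt = 1,
                                n_steps = 1000, box_edge = 100, seed = NULL) {
  if (n_particles < 1 || dt <= 0 || n_steps < 1 || box_edge <= 0 || d < 0)
    stop_invalid("invalid Brownian spec: need n_particles, dt, n_steps, ",
                 "box_edge > 0 and d >= 0")
  coords <- with_seed(seed, {
    x0 <- matrix(stats::runif(n_particles * 3, 0, box_edge), n_particles, 3L)
    steps <- array(stats::rnorm(n_particles * 3 * n_steps, 0, sqrt(2 * d * dt)),
                   dim = c(n_particles, 3L, n_steps))
    out <- array(NA_real_, dim = c(n_particles, 3L, n_steps + 1L))
    out[, , 1L] <- x0
    for (t in seq_len(n_steps)) out[, , t + 1L] <- out[, , t] + steps[, , t]
    out
  })
  atoms <- make_atom_table(n_particles, element = "X")
  structure(list(atoms = atoms, coords = coords,
                 times = (0:n_steps) * dt, cell = periodic_cell(box_edge),
                 timestep = dt, energies = NULL),
            class = "md_trajectory")
}

#' Ideal-gas frames
#'
#' Uniform i.i.d. positions in a cubic periodic box, independently per
#' frame: the exactly structureless reference whose RDF plateaus at 1.
#'
#' @param n atoms per frame.
#' @param box_edge cubic cell edge, Angstrom.
#' @param n_frames number of frames.
#' @param seed integer seed.
#' @return an [md_trajectory()].
#' @export
ideal_gas_frames <- function(n = 1000, box_edge = 30, n_frames = 50,
                             seed = NULL) {
  if (n < 1 || box_edge <= 0 || n_frames < 1)
    stop_invalid("invalid spec: need n, box_edge, n_frames > 0")
  coords <- with_seed(seed,
    array(stats::runif(n * 3 * n_frames, 0, box_edge),
          dim = c(n, 3L, n_frames)))
  atoms <- make_atom_table(n, element = "X")
  structure(list(atoms = atoms, coords = coords,
                 times = seq_len(n_frames) - 1, cell = periodic_cell(box_edge),
                 timestep = 1, energies = NULL),
            class = "md_trajectory")
}

# unit vector orthogonal to u (any)
orthogonal_unit <- function(u) {
  v <- if (abs(u[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- v - sum(v * u) * u
  w / sqrt(sum(w * w))
}

# One O-H...O triple around `center`.  `angle_deg` is the D-H...A angle and
# `r_ha` the H...A distance; the O-H covalent bond is 0.96 A.
place_triple <- function(center, r_ha, angle_deg) {
  u <- stats::rnorm(3); u <- u / sqrt(sum(u * u))   # D -> H direction
  d_pos <- center
  h_pos <- center + 0.96 * u
  phi <- (180 - angle_deg) * pi / 180               # deviation from linear
  w <- orthogonal_unit(u)
  az <- stats::runif(1, 0, 2 * pi)
  w2 <- cos(az) * w + sin(az) * pracma_cross(u, w)
  dir <- cos(phi) * u + sin(phi) * w2               # H -> A direction
  a_pos <- h_pos + r_ha * dir
  rbind(d_pos, h_pos, a_pos)
}

pracma_cross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Hydrogen-bond detection fixture
#'
#' Builds a frame containing exactly `k_bonds` O-H...O triples that satisfy
#' the default detection criteria (H...A drawn from 1.8-2.9 Angstrom,
#' D-H...A angle from 150-180 degrees) plus `decoys` triples that violate
#' them (half by distance, half by angle).  Donor oxygens and hydrogens sit
#' on a host molecule (classes `donor_label`/`h_label`), acceptor oxygens on
#' a guest molecule (class `acceptor_label`), so every true bond is
#' intermolecular.  Groups are laid out on a jittered grid with at least
#' 12 Angstrom spacing so no accidental cross-group bond can form, in the
#' periodic sense too.
#'
#' @param k_bonds number of valid hydrogen-bond triples (>= 0).
#' @param decoys number of violating triples.
#' @param box_edge cubic cell edge, Angstrom; must give >= 12 A grid
#'   spacing for `k_bonds + decoys` groups or generation errors out.
#' @param seed integer seed.
#' @param acceptor_label,h_label,donor_label atom-class labels stamped on
#'   the acceptor O, the hydrogen and the donor O.
#' @return a list with `frame` (an [md_frame()]) and `bonds` (data frame of
#'   ground-truth donor/hydrogen/acceptor 0-based indices).
#' @export
hbond_fixture <- function(k_bonds, decoys = 0, box_edge = 40, seed = NULL,
                          acceptor_label = "O1", h_label = "H2",
                          donor_label = "O7") {
  if (k_bonds < 0 || decoys < 0) stop_invalid("counts must be >= 0")
  n_groups <- k_bonds + decoys
  if (n_groups == 0L)
    stop_invalid("need at least one triple (k_bonds + decoys >= 1)")
  side <- ceiling(n_groups^(1 / 3))
  spacing <- box_edge / side
  if (spacing < 12)
    stop_invalid("box too small: ", n_groups, " groups in a ", box_edge,
                 " A box gives ", fmt_num(spacing),
                 " A spacing; need >= 12 A to rule out accidental bonds")
  with_seed(seed, {
    cells <- as.matrix(expand.grid(0:(side - 1), 0:(side - 1), 0:(side - 1)))
    cells <- cells[sample(nrow(cells), n_groups), , drop = FALSE]
    centers <- (cells + 0.5) * spacing +
      matrix(stats::runif(n_groups * 3, -1, 1), n_groups, 3L)
    coords <- vector("list", n_groups)
    valid <- rep(c(TRUE, FALSE), c(k_bonds, decoys))
    for (g in seq_len(n_groups)) {
      if (valid[g]) {
        coords[[g]] <- place_triple(centers[g, ],
                                    r_ha = stats::runif(1, 1.8, 2.9),
                                    angle_deg = stats::runif(1, 150, 180))
      } else if (g %% 2L == 0L) {
        # distance violation: angle fine, H...A beyond the 3.0 A cutoff
        coords[[g]] <- place_triple(centers[g, ],
                                    r_ha = stats::runif(1, 3.3, 4.5),
                                    angle_deg = stats::runif(1, 150, 180))
      } else {
        # angle violation: distance fine, bent well below the 120 deg cutoff
        coords[[g]] <- place_triple(centers[g, ],
                                    r_ha = stats::runif(1, 1.8, 2.9),
                                    angle_deg = stats::runif(1, 60, 110))
      }
    }
    X <- do.call(rbind, coords)
    n_atoms <- nrow(X)
    element <- rep(c("O", "H", "O"), n_groups)
    # donor O and its H on the host molecule; acceptor O on the guest
    molecule_id <- rep_len(c(0L, 0L, 1L), n_atoms)
    role <- rep_len(c("host", "host", "guest"), n_atoms)
    class_label <- rep_len(c(donor_label, h_label, acceptor_label), n_atoms)
    frame <- md_frame(X, element = element, molecule_id = molecule_id,
                      role = role, class_label = class_label,
                      cell = periodic_cell(box_edge))
    idx0 <- (seq_len(n_groups) - 1L) * 3L
    bonds <- data.frame(donor = idx0[valid], hydrogen = idx0[valid] + 1L,
                        acceptor = idx0[valid] + 2L)
    list(frame = frame, bonds = bonds)
  })
}

#' Two-cluster pairwise-additive system
#'
#' Two rigid random atom clusters ("host" and "guest") separated along x,
#' with random partial charges, plus exact ground-truth energies from direct
#' summation: total, host-only, guest-only and the host-guest cross term.
#' Because the toy force field is pairwise additive, the binding energy
#' computed from the three totals equals minus the cross term exactly.
#'
#' @param n_host,n_guest atoms per cluster.
#' @param separation distance between cluster centers, Angstrom.
#' @param params a [nonbonded_params()].
#' @param seed integer seed.
#' @param cluster_radius cluster half-extent, Angstrom.
#' @return a list with `frame` (open-cell [md_frame()]) and `energies`
#'   (list `e_total`, `e_host`, `e_guest`, `cross`, kcal/mol).
#' @export
two_cluster_system <- function(n_host, n_guest, separation,
                               params = nonbonded_params(), seed = NULL,
                               cluster_radius = 3.5) {
  if (n_host < 1 || n_guest < 1) stop_invalid("cluster sizes must be >= 1")
  if (separation <= 0) stop_invalid("`separation` must be > 0")
  with_seed(seed, {
    gen_cluster <- function(n, center) {
      for (try in 1:50) {
        x <- matrix(stats::runif(n * 3, -cluster_radius, cluster_radius), n, 3L)
        x <- sweep(x, 2L, center, "+")
        if (n == 1L || min(stats::dist(x)) > 1.8) return(x)
      }
      stop_invalid("could not place a cluster without atom overlap")
    }
    xh <- gen_cluster(n_host, c(0, 0, 0))
    xg <- gen_cluster(n_guest, c(separation, 0, 0))
    X <- rbind(xh, xg)
    n <- n_host + n_guest
    element <- sample(names(params$epsilon), n, replace = TRUE)
    charge <- stats::runif(n, -0.3, 0.3)
    frame <- md_frame(X, element = element, charge = charge,
                      molecule_id = rep(0:1, c(n_host, n_guest)),
                      role = rep(c("host", "guest"), c(n_host, n_guest)))
    # ground truth by direct per-pair summation (independent bookkeeping)
    pair_e <- function(i, j) {
      r <- sqrt(sum((X[i, ] - X[j, ])^2))
      if (r > params$cutoff) return(0)
      sig <- (params$sigma[element[i]] + params$sigma[element[j]]) / 2
      eps <- sqrt(params$epsilon[element[i]] * params$epsilon[element[j]])
      sr6 <- (sig / r)^6
      unname(4 * eps * (sr6^2 - sr6) + params$coulomb_k * charge[i] * charge[j] / r)
    }
    e_total <- 0; e_host <- 0; e_guest <- 0; cross <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      e <- pair_e(i, j)
      e_total <- e_total + e
      if (j <= n_host) e_host <- e_host + e
      else if (i > n_host) e_guest <- e_guest + e
      else cross <- cross + e
    }
    list(frame = frame,
         energies = list(e_total = e_total, e_host = e_host,
                         e_guest = e_guest, cross = cross))
  })
}
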