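#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond D-H...A is accepted when the hydrogen sits within
#' `covalent_cutoff` of a donor-element atom D (the covalent assignment),
#' the H...A distance does not exceed `max_distance`, and the D-H...A angle
#' (at the hydrogen) is at least `min_angle`.  The defaults (3.0 Angstrom,
#' 120 degrees, O donors/acceptors) take the distance cutoff from the upper
#' edge of the hydrogen-bond band of the RDF classification and a standard
#' permissive angle.
#'
#' @param max_distance maximum H...A distance, Angstrom.
#' @param min_angle minimum D-H...A angle, degrees, in \[0, 180\].
#' @param donors,acceptors element symbols acting as donors / acceptors.
#' @param covalent_cutoff D-H covalent assignment distance, Angstrom.
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_distance = 3.0, min_angle = 120,
                           donors = "O", acceptors = "O",
                           covalent_cutoff = 1.2) {
  if (max_distance <= 0) stop_invalid("`max_distance` must be > 0")
  if (min_angle < 0 || min_angle > 180)
    stop_invalid("`min_angle` must lie in [0, 180] degrees")
  if (covalent_cutoff <= 0) stop_invalid("`covalent_cutoff` must be > 0")
  structure(list(max_distance = max_distance, min_angle = min_angle,
                 donors = normalise_element(donors),
                 acceptors = normalise_element(acceptors),
                 covalent_cutoff = covalent_cutoff),
            class = "hbond_criteria")
}

#' @export
print.hbond_criteria <- function(x, ...) {
  cat(sprintf("H-bond criteria: H...A <= %s A, D-H...A angle >= %s deg, D-H <= %s A\n",
              fmt_num(x$max_distance), fmt_num(x$min_angle),
              fmt_num(x$covalent_cutoff)))
  cat("  donors:", paste(x$donors, collapse = " "),
      " acceptors:", paste(x$acceptors, collapse = " "), "\n")
  invisible(x)
}

#' Detect hydrogen bonds in a frame
#'
#' Enumerates covalent D-H pairs (every hydrogen within the covalent cutoff
#' of a donor-element atom, minimum image) and tests each acceptor-element
#' atom against the distance and angle criteria.  Records are flagged
#' intramolecular or intermolecular by comparing donor and acceptor
#' `molecule_id`.
#'
#' @param frame an [md_frame()].
#' @param criteria an [hbond_criteria()].
#' @return an object of class `hbond_set`: a data frame with columns
#'   `donor`, `hydrogen`, `acceptor` (0-based atom indices), `distance`
#'   (H...A, Angstrom), `angle` (degrees), `frame`, `kind`
#'   (`"intramolecular"` / `"intermolecular"`).  Empty when no donors,
#'   acceptors or hydrogens are present.
#' @export
detect_hbonds <- function(frame, criteria = hbond_criteria()) {
  if (!inherits(frame, "md_frame")) stop_invalid("`frame` must be an md_frame")
  if (!inherits(criteria, "hbond_criteria"))
    stop_invalid("`criteria` must be hbond_criteria")
  at <- frame$atoms; X <- frame$coords; cell <- frame$cell
  iH <- which(at$element == "H")
  iD <- which(at$element %in% criteria$donors)
  iA <- which(at$element %in% criteria$acceptors)
  empty <- structure(
    data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
               distance = numeric(), angle = numeric(), frame = integer(),
               kind = character(), stringsAsFactors = FALSE),
    criteria = criteria, class = c("hbond_set", "data.frame"))
  if (!length(iH) || !length(iD) || !length(iA)) return(empty)

  # covalent D-H pairs: every (donor, hydrogen) closer than the cutoff
  dDH <- cross_dist(X[iD, , drop = FALSE], X[iH, , drop = FALSE], cell)
  dh <- which(dDH <= criteria$covalent_cutoff, arr.ind = TRUE)
  if (!nrow(dh)) return(empty)

  rows <- vector("list", nrow(dh))
  for (p in seq_len(nrow(dh))) {
    d <- iD[dh[p, 1L]]; h <- iH[dh[p, 2L]]
    acc <- iA[iA != d]
    if (!length(acc)) next
    vHA <- min_image_disp(X[h, , drop = FALSE][rep(1L, length(acc)), , drop = FALSE],
                          X[acc, , drop = FALSE], cell)
    rHA <- sqrt(rowSums(vHA^2))
    keep <- rHA <= criteria$max_distance & rHA > 0
    if (!any(keep)) next
    acc <- acc[keep]; vHA <- vHA[keep, , drop = FALSE]; rHA <- rHA[keep]
    vHD <- min_image_disp(X[h, , drop = FALSE], X[d, , drop = FALSE], cell)
    rHD <- sqrt(sum(vHD^2))
    cosang <- (vHA %*% t(vHD)) / (rHA * rHD)
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    keep2 <- ang >= criteria$min_angle
    if (!any(keep2)) next
    acc <- acc[keep2]
    rows[[p]] <- data.frame(
      donor = at$index[d], hydrogen = at$index[h], acceptor = at$index[acc],
      distance = rHA[keep2], angle = ang[keep2], frame = 0L,
      kind = ifelse(at$molecule_id[acc] == at$molecule_id[d],
                    "intramolecular", "intermolecular"),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, criteria = criteria, class = c("hbond_set", "data.frame"))
}

# all-pairs distance matrix between two coordinate sets under the cell
cross_dist <- function(a, b, cell) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    if (cell$periodic) dk <- dk - cell$edges[k] * round(dk / cell$edges[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

#' @export
print.hbond_set <- function(x, ...) {
  cat(sprintf("%d hydrogen bond(s): %d intermolecular, %d intramolecular\n",
              nrow(x), sum(x$kind == "intermolecular"),
              sum(x$kind == "intramolecular")))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Per-frame hydrogen-bond counts over a trajectory
#'
#' @param traj an [md_trajectory()].
#' @param criteria an [hbond_criteria()].
#' @param kind count `"all"`, `"intermolecular"` or `"intramolecular"` bonds.
#' @return a list with `per_frame` (integer vector), `mean`, `sd`, and
#'   `n_rounded` (the mean rounded to the nearest integer, the count to use
#'   in [hbond_concentration()] for a trajectory).
#' @export
count_hbonds <- function(traj, criteria = hbond_criteria(), kind = "all") {
  if (!inherits(traj, "md_trajectory")) stop_invalid("`traj` must be an md_trajectory")
  counts <- vapply(seq_len(n_frames(traj)), function(i) {
    hb <- detect_hbonds(get_frame(traj, i), criteria)
    if (kind == "all") nrow(hb) else sum(hb$kind == kind)
  }, integer(1))
  list(per_frame = counts, mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else 0,
       n_rounded = as.integer(round(mean(counts))))
}

#' Hydrogen-bond molar concentration
#'
#' `C_HBs = N_HBs / (N_A * V)` with Avogadro's constant
#' `N_A = 6.02214076e23 1/mol` and the periodic cell volume `V` in cm^3
#' (1 Angstrom^3 = 1e-24 cm^3).
#'
#' @param n_hbonds number of hydrogen bonds in the cell (>= 0).
#' @param cell a periodic [periodic_cell()].
#' @return an object of class `hbond_concentration` with fields `n_hbonds`,
#'   `volume_cm3`, `c_hbs` (mol/cm^3).
#' @examples
#' hbond_concentration(100, periodic_cell(10))$c_hbs  # 0.16606 mol/cm^3
#' @export
hbond_concentration <- function(n_hbonds, cell) {
  check_numeric(n_hbonds, "n_hbonds")
  if (n_hbonds < 0) stop_invalid("`n_hbonds` must be >= 0")
  if (!inherits(cell, "periodic_cell") || !cell$periodic)
    stop_invalid("hydrogen-bond concentration needs a periodic cell with a volume")
  avogadro <- 6.02214076e23
  v <- cell_volume(cell, "cm3")
  structure(list(n_hbonds = n_hbonds, volume_cm3 = v, avogadro = avogadro,
                 c_hbs = n_hbonds / (avogadro * v)),
            class = "hbond_concentration")
}

#' @export
print.hbond_concentration <- function(x, ...) {
  cat(sprintf("C_HBs = %s mol/cm^3 (%s bonds in %s cm^3)\n",
              fmt_num(x$c_hbs), fmt_num(x$n_hbonds), fmt_num(x$volume_cm3)))
  invisible(x)
}
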