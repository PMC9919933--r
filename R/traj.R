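#' Periodic simulation cell
#'
#' Constructs an orthorhombic (or cubic) periodic cell, or an open
#' (non-periodic) cell.  All downstream pair distances are measured under the
#' minimum-image convention when the cell is periodic.
#'
#' @param edges numeric vector of 1 or 3 edge lengths in Angstrom; a single
#'   value gives a cubic cell.  Ignored when `periodic = FALSE`.
#' @param periodic logical; `FALSE` gives an open cell (plain Euclidean
#'   distances, no volume).
#' @return an object of class `periodic_cell` with fields `edges` and
#'   `periodic`.
#' @examples
#' periodic_cell(19.2)            # the cubic cell of a 19.2 A box
#' periodic_cell(periodic = FALSE)
#' @export
periodic_cell <- function(edges = NULL, periodic = TRUE) {
  if (periodic) {
    check_numeric(edges, "edges")
    if (length(edges) == 1L) edges <- rep(edges, 3L)
    if (length(edges) != 3L) stop_invalid("`edges` must have length 1 or 3")
    if (any(edges <= 0)) stop_invalid("periodic cell edges must be > 0")
  } else {
    edges <- rep(NA_real_, 3L)
  }
  structure(list(edges = as.numeric(edges), periodic = isTRUE(periodic)),
            class = "periodic_cell")
}

#' @export
print.periodic_cell <- function(x, ...) {
  if (x$periodic)
    cat(sprintf("Periodic orthorhombic cell: %s Angstrom\n",
                paste(fmt_num(x$edges), collapse = " x ")))
  else cat("Open (non-periodic) cell\n")
  invisible(x)
}

#' Cell volume
#'
#' @param cell a [periodic_cell()].
#' @param unit `"A3"` (cubic Angstrom) or `"cm3"` (1 A^3 = 1e-24 cm^3).
#' @return volume as a single number.
#' @export
cell_volume <- function(cell, unit = c("A3", "cm3")) {
  unit <- match.arg(unit)
  if (!inherits(cell, "periodic_cell")) stop_invalid("`cell` must be a periodic_cell")
  if (!cell$periodic) stop_invalid("an open cell has no volume")
  v <- prod(cell$edges)
  if (unit == "cm3") v * 1e-24 else v
}

# Minimum-image displacement vectors: rows of `b` minus rows of `a`
# (recycled), wrapped into [-L/2, L/2) per axis when the cell is periodic.
min_image_disp <- function(a, b, cell) {
  a <- matrix(as.numeric(a), ncol = 3L)
  b <- matrix(as.numeric(b), ncol = 3L)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (nrow(a) != nrow(b)) stop_invalid("`a` and `b` must have matching rows")
  d <- b - a
  if (cell$periodic) {
    for (k in 1:3) d[, k] <- d[, k] - cell$edges[k] * round(d[, k] / cell$edges[k])
  }
  d
}

#' Minimum-image distance
#'
#' Euclidean distance between two points (or row-wise between two coordinate
#' matrices) under the minimum-image convention of an orthorhombic periodic
#' cell; plain Euclidean distance for an open cell.
#'
#' @param a,b coordinates in Angstrom: length-3 vectors or n x 3 matrices.
#' @param cell a [periodic_cell()].
#' @return numeric vector of distances in Angstrom.
#' @examples
#' minimum_image_distance(c(0, 0, 0), c(9.9, 0, 0), periodic_cell(10))  # 0.1
#' @export
minimum_image_distance <- function(a, b, cell) {
  if (!inherits(cell, "periodic_cell")) stop_invalid("`cell` must be a periodic_cell")
  d <- min_image_disp(a, b, cell)
  sqrt(rowSums(d * d))
}

make_atom_table <- function(n, element = "X", charge = 0, molecule_id = 0L,
                            role = "other", class_label = NA_character_) {
  data.frame(index = seq_len(n) - 1L,
             element = rep_len(as.character(element), n),
             charge = rep_len(as.numeric(charge), n),
             molecule_id = rep_len(as.integer(molecule_id), n),
             role = rep_len(as.character(role), n),
             class_label = rep_len(as.character(class_label), n),
             stringsAsFactors = FALSE)
}

# Case-normalise an element symbol: "CL" -> "Cl", "o" -> "O".
normalise_element <- function(el) {
  el <- trimws(as.character(el))
  bad <- !nzchar(el)
  el[!bad] <- paste0(toupper(substr(el[!bad], 1L, 1L)),
                     tolower(substring(el[!bad], 2L)))
  if (any(bad)) stop_invalid("empty element symbol")
  el
}

#' Single structure frame
#'
#' A snapshot of a particle system: coordinates plus per-atom annotations
#' (element, partial charge, molecule id, host/guest role, atom-class label)
#' and the periodic cell.  Coordinates are stored as given, possibly outside
#' the box; wrapping happens only inside distance computations.
#'
#' @param coords n x 3 numeric matrix of coordinates (Angstrom).
#' @param element character vector of element symbols (recycled).
#' @param charge partial charges in units of e (recycled).
#' @param molecule_id integer molecule membership (recycled).
#' @param role one of `"host"`, `"guest"`, `"other"` per atom (recycled).
#' @param class_label optional atom-class tag such as `"O1"` or `"H2"`.
#' @param cell a [periodic_cell()]; defaults to an open cell.
#' @param time frame time in ps.
#' @return an object of class `md_frame` with fields `atoms` (data frame),
#'   `coords`, `cell`, `time`.
#' @export
md_frame <- function(coords, element = "X", charge = 0, molecule_id = 0L,
                     role = "other", class_label = NA_character_,
                     cell = periodic_cell(periodic = FALSE), time = 0) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop_invalid("`coords` must have 3 columns")
  check_numeric(coords, "coords")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  atoms <- make_atom_table(nrow(coords), normalise_element(element), charge,
                           molecule_id, role, class_label)
  structure(list(atoms = atoms, coords = coords, cell = cell,
                 time = as.numeric(time)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("md_frame: %d atoms, t = %s ps\n", nrow(x$atoms), fmt_num(x$time)))
  print(x$cell)
  cat("elements:", paste(names(table(x$atoms$element)), collapse = " "), "\n")
  invisible(x)
}

#' Particle trajectory
#'
#' A time-ordered stack of frames over a constant atom set and a constant
#' cell, with optional per-frame energy components.
#'
#' @param frames list of [md_frame()] objects with identical atom tables and
#'   cells, or a single `md_frame`.
#' @param timestep frame spacing in ps, used to assign times when the frames
#'   carry none (all zero).
#' @param energies optional data frame of per-frame energies with columns
#'   `frame`, `component`, `value_kcal_mol`.
#' @return an object of class `md_trajectory` with fields `atoms`, `coords`
#'   (an n_atoms x 3 x n_frames array), `times`, `cell`, `energies`.
#' @export
md_trajectory <- function(frames, timestep = 1, energies = NULL) {
  if (inherits(frames, "md_frame")) frames <- list(frames)
  if (length(frames) < 1L) stop_invalid("need at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "md_frame")))
    stop_invalid("`frames` must be md_frame objects")
  n <- nrow(frames[[1L]]$atoms)
  counts <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (any(counts != n))
    stop_invalid("inconsistent atom count across frames: ",
                 paste(unique(counts), collapse = ", "))
  coords <- array(NA_real_, dim = c(n, 3L, length(frames)))
  for (i in seq_along(frames)) coords[, , i] <- frames[[i]]$coords
  times <- unname(vapply(frames, `[[`, numeric(1), "time"))
  if (all(times == 0) && length(frames) > 1L)
    times <- (seq_along(frames) - 1L) * timestep
  if (length(times) > 1L && any(diff(times) <= 0))
    stop_invalid("frame times must be strictly increasing")
  structure(list(atoms = frames[[1L]]$atoms, coords = coords, times = times,
                 cell = frames[[1L]]$cell, timestep = as.numeric(timestep),
                 energies = energies),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory: %d atoms, %d frames, t = %s..%s ps\n",
              dim(x$coords)[1L], dim(x$coords)[3L],
              fmt_num(x$times[1L]), fmt_num(x$times[length(x$times)])))
  print(x$cell)
  invisible(x)
}

#' @rdname md_trajectory
#' @param traj an `md_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' @rdname md_trajectory
#' @export
n_atoms <- function(traj) dim(traj$coords)[1L]

#' @rdname md_trajectory
#' @param i frame number (1-based).
#' @export
get_frame <- function(traj, i) {
  nf <- n_frames(traj)
  if (i < 1L || i > nf) stop_invalid("frame index out of range [1, ", nf, "]")
  structure(list(atoms = traj$atoms, coords = matrix(traj$coords[, , i], ncol = 3L),
                 cell = traj$cell, time = traj$times[i]),
            class = "md_frame")
}
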