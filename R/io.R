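## Readers and writers for the three supported structure dialects:
##   - XYZ (single- and multi-frame; comment line may carry
##     "time=<ps> cell=<a,b,c>")
##   - minimal PDB (ATOM/HETATM coordinates + element, CRYST1 for the cell)
##   - native CSV (columns frame, time_ps, atom, element, x, y, z, charge,
##     molecule_id, role, optionally class_label and cell_a/cell_b/cell_c),
##     the only dialect that carries charges and host/guest roles.

parse_xyz_comment <- function(line) {
  time <- 0; cell <- periodic_cell(periodic = FALSE)
  m <- regmatches(line, regexec("time=([0-9eE+.-]+)", line))[[1L]]
  if (length(m) == 2L) time <- as.numeric(m[2L])
  m <- regmatches(line, regexec("cell=([0-9eE+.,-]+)", line))[[1L]]
  if (length(m) == 2L) {
    edges <- as.numeric(strsplit(m[2L], ",", fixed = TRUE)[[1L]])
    cell <- periodic_cell(edges)
  }
  list(time = time, cell = cell)
}

read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  if (length(lines) == 0L) stop_invalid("parse error in '", path, "': empty file")
  frames <- list(); pos <- 1L
  while (pos <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1L)
      stop_invalid("parse error in '", path, "' at line ", pos,
                   ": expected atom count")
    if (pos + 1L + n > length(lines))
      stop_invalid("parse error in '", path, "' at line ", pos,
                   ": truncated frame (", n, " atoms declared)")
    meta <- parse_xyz_comment(lines[pos + 1L])
    body <- lines[(pos + 2L):(pos + 1L + n)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(vapply(toks, length, integer(1)) < 4L)
    if (length(bad))
      stop_invalid("parse error in '", path, "' at line ", pos + 1L + bad[1L],
                   ": expected 'element x y z'")
    el <- vapply(toks, `[[`, character(1), 1L)
    xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
    if (any(!is.finite(xyz)))
      stop_invalid("parse error in '", path, "': non-numeric coordinate in frame ",
                   length(frames) + 1L)
    frames[[length(frames) + 1L]] <-
      md_frame(xyz, element = el, cell = meta$cell, time = meta$time)
    pos <- pos + 2L + n
  }
  frames
}

read_pdb_frame <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || !any(nzchar(trimws(lines))))
    stop_invalid("parse error in '", path, "': empty file")
  cell <- periodic_cell(periodic = FALSE)
  cry <- grep("^CRYST1", lines)
  if (length(cry)) {
    l <- lines[cry[1L]]
    edges <- suppressWarnings(as.numeric(c(substr(l, 7, 15), substr(l, 16, 24),
                                           substr(l, 25, 33))))
    if (any(!is.finite(edges)))
      stop_invalid("parse error in '", path, "' at line ", cry[1L],
                   ": malformed CRYST1 record")
    cell <- periodic_cell(edges)
  }
  rec <- grep("^(ATOM  |HETATM)", lines)
  if (!length(rec)) stop_invalid("parse error in '", path, "': no ATOM/HETATM records")
  xyz <- matrix(NA_real_, length(rec), 3L)
  el <- character(length(rec))
  for (k in seq_along(rec)) {
    l <- lines[rec[k]]
    xyz[k, ] <- suppressWarnings(as.numeric(c(substr(l, 31, 38), substr(l, 39, 46),
                                              substr(l, 47, 54))))
    if (any(!is.finite(xyz[k, ])))
      stop_invalid("parse error in '", path, "' at line ", rec[k],
                   ": malformed coordinates")
    e <- trimws(substr(l, 77, 78))
    if (!nzchar(e)) {
      # fall back to the atom-name column, stripped of digits
      e <- gsub("[0-9]", "", trimws(substr(l, 13, 16)))
      e <- substr(e, 1L, 2L)
    }
    if (!nzchar(e))
      stop_invalid("parse error in '", path, "' at line ", rec[k],
                   ": no element symbol")
    el[k] <- e
  }
  md_frame(xyz, element = el, cell = cell)
}

csv_to_frames <- function(df, path) {
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop_invalid("parse error in '", path, "': native CSV needs columns ",
                 paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop_invalid("parse error in '", path, "': empty table")
  if (is.null(df$frame)) df$frame <- 0L
  if (is.null(df$time_ps)) df$time_ps <- 0
  if (is.null(df$charge)) df$charge <- 0
  if (is.null(df$molecule_id)) df$molecule_id <- 0L
  if (is.null(df$role)) df$role <- "other"
  if (is.null(df$class_label)) df$class_label <- NA_character_
  cell <- periodic_cell(periodic = FALSE)
  if (all(c("cell_a", "cell_b", "cell_c") %in% names(df)))
    cell <- periodic_cell(c(df$cell_a[1L], df$cell_b[1L], df$cell_c[1L]))
  frame_fac <- factor(df$frame, levels = sort(unique(df$frame)))
  lapply(split(df, frame_fac), function(fr) {
    if (!is.null(fr$atom)) fr <- fr[order(fr$atom), , drop = FALSE]
    md_frame(cbind(fr$x, fr$y, fr$z), element = fr$element, charge = fr$charge,
             molecule_id = fr$molecule_id, role = fr$role,
             class_label = fr$class_label, cell = cell, time = fr$time_ps[1L])
  })
}

#' Read a single structure frame
#'
#' @param path file path.
#' @param format `"xyz"`, `"pdb"` or `"csv"` (the package's native CSV
#'   dialect, the only one carrying charges, molecule ids, roles and atom
#'   class labels); guessed from the file extension when missing.
#' @param cell optional [periodic_cell()] overriding any cell metadata in the
#'   file.
#' @return an [md_frame()].
#' @export
read_structure <- function(path, format = NULL, cell = NULL) {
  format <- guess_format(path, format)
  frame <- switch(format,
    xyz = {
      fr <- read_xyz_frames(path)
      if (length(fr) > 1L)
        stop_invalid("'", path, "' holds ", length(fr),
                     " frames; use read_trajectory()")
      fr[[1L]]
    },
    pdb = read_pdb_frame(path),
    csv = {
      fr <- csv_to_frames(utils::read.csv(path, stringsAsFactors = FALSE), path)
      if (length(fr) > 1L)
        stop_invalid("'", path, "' holds ", length(fr),
                     " frames; use read_trajectory()")
      fr[[1L]]
    },
    stop_invalid("unknown format '", format, "'"))
  if (!is.null(cell)) frame$cell <- cell
  frame
}

guess_format <- function(path, format) {
  if (!is.null(format)) return(match.arg(format, c("xyz", "pdb", "csv")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xyz", "pdb", "csv")) ext
  else stop_invalid("cannot guess format from '", path, "'; pass `format`")
}

#' Read a multi-frame trajectory
#'
#' @inheritParams read_structure
#' @param timestep frame spacing in ps, used when the file carries no time
#'   metadata.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, format = NULL, timestep = 1, cell = NULL) {
  format <- guess_format(path, format)
  frames <- switch(format,
    xyz = read_xyz_frames(path),
    csv = csv_to_frames(utils::read.csv(path, stringsAsFactors = FALSE), path),
    pdb = stop_invalid("multi-frame PDB is not supported; use xyz or csv"),
    stop_invalid("unknown format '", format, "'"))
  if (!is.null(cell)) frames <- lapply(frames, function(f) { f$cell <- cell; f })
  md_trajectory(frames, timestep = timestep)
}

#' Write structures to XYZ or native CSV
#'
#' @param x an [md_frame()] or [md_trajectory()].
#' @param path output file path.
#' @param digits coordinate precision.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(x, path, digits = 10) {
  frames <- if (inherits(x, "md_trajectory"))
    lapply(seq_len(n_frames(x)), function(i) get_frame(x, i)) else list(x)
  con <- file(path, "w"); on.exit(close(con))
  for (f in frames) {
    comment <- sprintf("time=%.*g", digits, f$time)
    if (f$cell$periodic)
      comment <- paste0(comment, " cell=",
                        paste(sprintf("%.*g", digits, f$cell$edges), collapse = ","))
    writeLines(c(sprintf("%d", nrow(f$atoms)), comment), con)
    writeLines(sprintf("%s %.*g %.*g %.*g", f$atoms$element,
                       digits, f$coords[, 1L], digits, f$coords[, 2L],
                       digits, f$coords[, 3L]), con)
  }
  invisible(path)
}

#' @rdname write_xyz
#' @export
write_trajectory_csv <- function(x, path) {
  frames <- if (inherits(x, "md_trajectory"))
    lapply(seq_len(n_frames(x)), function(i) get_frame(x, i)) else list(x)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    d <- data.frame(frame = i - 1L, time_ps = f$time, atom = f$atoms$index,
                    element = f$atoms$element, x = f$coords[, 1L],
                    y = f$coords[, 2L], z = f$coords[, 3L],
                    charge = f$atoms$charge, molecule_id = f$atoms$molecule_id,
                    role = f$atoms$role, class_label = f$atoms$class_label,
                    stringsAsFactors = FALSE)
    if (f$cell$periodic) {
      d$cell_a <- f$cell$edges[1L]; d$cell_b <- f$cell$edges[2L]
      d$cell_c <- f$cell$edges[3L]
    }
    d
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-frame energy table
#'
#' Long-format CSV with columns `frame`, `component`, `value_kcal_mol`;
#' component names are free-form (conventionally `total`, `guest`, `host`).
#'
#' @param path CSV file path.
#' @return a data frame with those three columns.
#' @export
read_energy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "component", "value_kcal_mol")
  if (!all(need %in% names(df)))
    stop_invalid("parse error in '", path, "': energy CSV needs columns ",
                 paste(need, collapse = ", "))
  check_numeric(df$value_kcal_mol, "value_kcal_mol")
  df
}
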