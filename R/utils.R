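## Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so generators never leak global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number", call. = FALSE)
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) stop_invalid("`", name, "` must be numeric")
  if (finite && any(!is.finite(x)))
    stop_invalid("`", name, "` must contain only finite values")
  invisible(x)
}

#' Resolve an atom selection
#'
#' Accepted forms: `NULL` (all atoms), a logical mask, 1-based integer row
#' positions, or a `"key=value"` string where the key is one of `element`,
#' `role`, `class` (atom-class label) or `molecule` (molecule id), e.g.
#' `"role=guest"` or `"class=O1"`.
#'
#' @param atoms an atom table (the `atoms` field of an [md_frame()] or
#'   [md_trajectory()]), or an object carrying one.
#' @param selection the selection in any accepted form.
#' @return integer vector of 1-based row positions.
#' @export
select_atoms <- function(atoms, selection) {
  if (is.list(atoms) && !is.data.frame(atoms) && !is.null(atoms$atoms))
    atoms <- atoms$atoms
  n <- nrow(atoms)
  if (is.null(selection)) return(seq_len(n))
  if (is.logical(selection)) {
    if (length(selection) != n)
      stop_invalid("logical selection must have one entry per atom")
    return(which(selection))
  }
  if (is.numeric(selection)) {
    idx <- as.integer(selection)
    if (any(idx < 1L | idx > n))
      stop_invalid("numeric selection out of range [1, ", n, "]")
    return(idx)
  }
  if (is.character(selection) && length(selection) == 1L) {
    if (!grepl("=", selection, fixed = TRUE))
      stop_invalid("string selection must look like \"key=value\"")
    kv <- strsplit(selection, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); value <- trimws(kv[2L])
    col <- switch(key,
      element  = atoms$element,
      role     = atoms$role,
      class    = atoms$class_label,
      molecule = as.character(atoms$molecule_id),
      stop_invalid("unknown selection key '", key,
                   "' (use element, role, class or molecule)"))
    idx <- which(!is.na(col) & col == value)
    return(idx)
  }
  stop_invalid("unsupported selection type")
}

# Polynomial rolling hash of a character vector; used for config provenance
# (stability across runs is what matters, not cryptographic strength).
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%010.0f", h)
}

fmt_num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")
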