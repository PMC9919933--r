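## End-to-end study runner: phase solubility -> stability constants ->
## trajectory descriptors -> energetics, with JSON / Markdown reporting.

read_two_col_csv <- function(path, xcol, ycol) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c(xcol, ycol) %in% names(df))) df[, c(xcol, ycol)]
  else if (ncol(df) >= 2L) stats::setNames(df[, 1:2], c(xcol, ycol))
  else stop_invalid("parse error in '", path, "': need columns ", xcol,
                    " and ", ycol)
}

#' Assemble a study configuration
#'
#' Collects file paths and analysis parameters for [run_study()].  Every
#' entry is optional: stages whose inputs are missing are skipped and
#' logged.  A configuration may also be loaded from a JSON file.
#'
#' @param calibration CSV path: columns `concentration` (mM), `absorbance`.
#' @param isotherms CSV path with columns `system`, `host_conc_mM`,
#'   `absorbance` (one diagram per system), or a named list of per-system
#'   CSVs with columns `host_conc_mM`, `absorbance`.
#' @param dilution_factor dilution applied to isotherm absorbances.
#' @param trajectory list with `path`, optional `format` and `timestep`.
#' @param msd list of [mean_square_displacement()] / [estimate_diffusion()]
#'   parameters: `selection`, `max_lag`, `fit_window`.
#' @param rdf list of [radial_distribution()] parameters: `group_a`,
#'   `group_b`, `dr`, `r_max`.
#' @param hbonds list of [hbond_criteria()] parameters.
#' @param energies CSV path of per-frame energies (`frame`, `component`,
#'   `value_kcal_mol`).
#' @param energy_window trailing frames averaged for the binding energy.
#' @param classes CSV path of the atom-class table (`label`, `role`,
#'   `charge`, `kind`).
#' @param deltas data frame with columns `name_a`, `delta_a`, `name_b`,
#'   `delta_b` for compatibility verdicts.
#' @param seed integer seed recorded in provenance and used by any stage
#'   that draws random numbers.
#' @param path JSON file to load a configuration from (other arguments are
#'   then ignored).
#' @return an object of class `study_config`.
#' @export
study_config <- function(calibration = NULL, isotherms = NULL,
                         dilution_factor = 1, trajectory = NULL, msd = list(),
                         rdf = list(), hbonds = list(), energies = NULL,
                         energy_window = 5, classes = NULL, deltas = NULL,
                         seed = NULL, path = NULL) {
  if (!is.null(path)) {
    cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- do.call(study_config, cfg[setdiff(names(cfg), "path")])
    return(cfg)
  }
  cfg <- list(calibration = calibration, isotherms = isotherms,
              dilution_factor = dilution_factor, trajectory = trajectory,
              msd = msd, rdf = rdf, hbonds = hbonds, energies = energies,
              energy_window = energy_window, classes = classes,
              deltas = deltas, seed = seed)
  if (all(vapply(cfg[c("calibration", "isotherms", "trajectory", "energies",
                       "classes", "deltas")], is.null, logical(1))))
    stop_invalid("usage error: empty configuration; provide at least one of ",
                 "calibration+isotherms, trajectory, energies, classes, deltas")
  for (p in c(cfg$calibration, cfg$energies, cfg$classes,
              if (is.character(cfg$isotherms)) cfg$isotherms,
              if (is.list(cfg$isotherms))
                unlist(cfg$isotherms, use.names = FALSE),
              cfg$trajectory$path))
    if (!file.exists(p)) stop_invalid("configured file not found: ", p)
  structure(cfg, class = "study_config")
}

run_stage <- function(name, expr, log) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run a full study
#'
#' Executes every stage whose inputs are configured: (1) UV calibration fit,
#' per-system phase-solubility isotherms, stability constants and ranking;
#' (2) trajectory descriptors - MSD slope and diffusion coefficient,
#' RDF with first-peak interaction class, per-frame hydrogen-bond counts
#' and molar concentration; (3) energetics - trailing-window binding energy,
#' compatibility verdicts, hydrogen-bond type catalogue (with per-type RDFs
#' when both classes and a trajectory are configured).  Stages with missing
#' inputs are skipped and listed in the report.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, writes `report.json`,
#'   `report.md` and per-stage CSVs there.
#' @return an object of class `study_report`.
#' @export
run_study <- function(config, out_dir = NULL) {
  if (!inherits(config, "study_config"))
    stop_invalid("`config` must be a study_config")
  skipped <- character()
  report <- list()
  report$provenance <- list(
    package = "hostguest",
    version = as.character(utils::packageVersion("hostguest")),
    seed = config$seed,
    config_hash = content_hash(jsonlite::toJSON(unclass(config),
                                                auto_unbox = TRUE,
                                                null = "null", force = TRUE)))

  ## ---- phase solubility -------------------------------------------------
  if (!is.null(config$calibration) && !is.null(config$isotherms)) {
    report$solubility <- run_stage("solubility", {
      cal_df <- read_two_col_csv(config$calibration, "concentration",
                                 "absorbance")
      cal <- fit_calibration(cal_df$concentration, cal_df$absorbance)
      iso_tabs <- if (is.character(config$isotherms)) {
        df <- utils::read.csv(config$isotherms, stringsAsFactors = FALSE)
        if (!all(c("system", "host_conc_mM", "absorbance") %in% names(df)))
          stop_invalid("combined isotherm CSV needs columns system, ",
                       "host_conc_mM, absorbance")
        lapply(split(df, factor(df$system, levels = unique(df$system))),
               function(d) d[, c("host_conc_mM", "absorbance")])
      } else {
        lapply(config$isotherms, read_two_col_csv,
               xcol = "host_conc_mM", ycol = "absorbance")
      }
      isos <- lapply(iso_tabs, function(d)
        fit_isotherm(d$host_conc_mM, d$absorbance, cal,
                     dilution_factor = config$dilution_factor))
      list(calibration = list(slope = cal$slope, intercept = cal$intercept,
                              r_squared = cal$r_squared,
                              n_points = cal$n_points),
           systems = lapply(isos, function(x)
             list(slope_K = x$slope_K, intercept_S0_mM = x$intercept_S0,
                  r_squared = x$r_squared, class = x$isotherm_class,
                  Ks = x$Ks)),
           ranking = rank_by_ks(isos))
    })
  } else skipped <- c(skipped, "solubility")

  ## ---- trajectory descriptors ------------------------------------------
  traj <- NULL
  if (!is.null(config$trajectory)) {
    report$descriptors <- run_stage("descriptors", {
      tc <- config$trajectory
      traj <- read_trajectory(tc$path, format = tc$format,
                              timestep = tc$timestep %||% 1)
      out <- list(n_atoms = n_atoms(traj), n_frames = n_frames(traj))
      msd <- mean_square_displacement(traj,
               selection = config$msd$selection,
               max_lag = config$msd$max_lag)
      fw <- config$msd$fit_window %||% range(msd$lag_ps)
      out$msd <- list(max_lag_ps = max(msd$lag_ps),
                      diffusion_A2_per_ps = estimate_diffusion(msd, fw))
      if (traj$cell$periodic) {
        rdf <- radial_distribution(traj, config$rdf$group_a,
                                   config$rdf$group_b,
                                   dr = config$rdf$dr %||% 0.1,
                                   r_max = config$rdf$r_max)
        pk <- rdf$r[which.max(rdf$g)]
        out$rdf <- list(first_peak_A = pk,
                        g_at_peak = max(rdf$g),
                        interaction = suppressWarnings(classify_interaction(pk)))
        crit <- do.call(hbond_criteria, config$hbonds)
        hb <- count_hbonds(traj, crit)
        out$hbonds <- list(mean = hb$mean, sd = hb$sd,
                           n_rounded = hb$n_rounded,
                           c_hbs_mol_per_cm3 =
                             hbond_concentration(hb$n_rounded, traj$cell)$c_hbs)
        attr(out, "msd_curve") <- as.data.frame(msd)
        attr(out, "rdf_curve") <- as.data.frame(rdf)
        attr(out, "hb_counts") <- hb$per_frame
      }
      out
    })
  } else skipped <- c(skipped, "descriptors")

  ## ---- energetics -------------------------------------------------------
  ener <- list()
  if (!is.null(config$energies)) {
    ener$binding <- run_stage("binding_energy", {
      be <- binding_energy_from_table(read_energy_table(config$energies),
                                      window = config$energy_window)
      list(e_total = be$e_total, e_guest = be$e_guest, e_host = be$e_host,
           e_binding_kcal_mol = be$e_binding,
           frames_used = attr(be, "frames_used"))
    })
  } else skipped <- c(skipped, "binding_energy")
  if (!is.null(config$deltas)) {
    ener$compatibility <- run_stage("compatibility", {
      d <- as.data.frame(config$deltas)
      lapply(seq_len(nrow(d)), function(i) {
        v <- compatibility(d$delta_a[i], d$delta_b[i])
        list(pair = paste(d$name_a[i], d$name_b[i], sep = "/"),
             difference = v$difference, category = v$category)
      })
    })
  } else skipped <- c(skipped, "compatibility")
  if (!is.null(config$classes)) {
    ener$hbond_types <- run_stage("hbond_types", {
      catalogue <- enumerate_hbond_types(read_atom_classes(config$classes))
      out <- list(n_types = nrow(catalogue),
                  types = stats::setNames(
                    paste(catalogue$acceptor_class, catalogue$donor_class,
                          sep = "-"), catalogue$type))
      if (!is.null(traj) && traj$cell$periodic &&
          any(!is.na(traj$atoms$class_label))) {
        per <- rdf_per_type(traj, catalogue, dr = config$rdf$dr %||% 0.1,
                            r_max = config$rdf$r_max)
        out$first_peaks_A <- vapply(per, function(r)
          if (any(r$g > 0)) r$r[which.max(r$g)] else NA_real_, numeric(1))
      }
      out
    })
  } else skipped <- c(skipped, "hbond_types")
  if (length(ener)) report$energetics <- ener
  report$skipped_stages <- skipped

  rep_obj <- structure(list(body = report, created = Sys.time()),
                       class = "study_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(render_report(rep_obj, "json"), file.path(out_dir, "report.json"))
    writeLines(render_report(rep_obj, "markdown"), file.path(out_dir, "report.md"))
    d <- report$descriptors
    if (!is.null(attr(d, "msd_curve")))
      utils::write.csv(attr(d, "msd_curve"), file.path(out_dir, "msd.csv"),
                       row.names = FALSE)
    if (!is.null(attr(d, "rdf_curve")))
      utils::write.csv(attr(d, "rdf_curve"), file.path(out_dir, "rdf.csv"),
                       row.names = FALSE)
    if (!is.null(attr(d, "hb_counts")))
      utils::write.csv(data.frame(frame = seq_along(attr(d, "hb_counts")) - 1L,
                                  n_bonds = attr(d, "hb_counts")),
                       file.path(out_dir, "hbond_counts.csv"),
                       row.names = FALSE)
  }
  rep_obj
}

#' Render a study report
#'
#' @param report a `study_report` from [run_study()].
#' @param format `"json"` (lossless, deterministic for identical inputs -
#'   the creation timestamp is kept out of the serialised body) or
#'   `"markdown"`.
#' @return a character scalar (the document).
#' @export
render_report <- function(report, format = c("json", "markdown")) {
  if (!inherits(report, "study_report"))
    stop_invalid("`report` must be a study_report")
  format <- match.arg(format)
  body <- report$body
  if (format == "json")
    return(as.character(jsonlite::toJSON(body, auto_unbox = TRUE, digits = NA,
                                         null = "null", pretty = TRUE)))
  ## markdown
  lines <- c("# Host-guest study report", "")
  pv <- body$provenance
  lines <- c(lines, sprintf("Package %s %s; seed %s; config hash %s.", pv$package,
                            pv$version, pv$seed %||% "none", pv$config_hash), "")
  if (!is.null(body$solubility)) {
    s <- body$solubility
    lines <- c(lines, "## Phase solubility", "",
               sprintf("Calibration: A = %s C + %s (R2 = %s, n = %d)",
                       fmt_num(s$calibration$slope), fmt_num(s$calibration$intercept),
                       fmt_num(s$calibration$r_squared), s$calibration$n_points), "",
               "| system | K | S0 (mM) | R2 | class | Ks (1/M) |",
               "|---|---|---|---|---|---|")
    for (nm in names(s$systems)) {
      x <- s$systems[[nm]]
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s |", nm,
                                fmt_num(x$slope_K), fmt_num(x$intercept_S0_mM),
                                fmt_num(x$r_squared), x$class, fmt_num(x$Ks)))
    }
    lines <- c(lines, "",
               paste("Stability ranking:", paste(s$ranking, collapse = " > ")), "")
  }
  if (!is.null(body$descriptors)) {
    d <- body$descriptors
    lines <- c(lines, "## Trajectory descriptors", "",
               sprintf("%d atoms, %d frames.", d$n_atoms, d$n_frames),
               sprintf("Diffusion coefficient D = %s A^2/ps.",
                       fmt_num(d$msd$diffusion_A2_per_ps)))
    if (!is.null(d$rdf))
      lines <- c(lines, sprintf("RDF first peak at %s A (%s).",
                                fmt_num(d$rdf$first_peak_A), d$rdf$interaction))
    if (!is.null(d$hbonds))
      lines <- c(lines, sprintf(
        "Hydrogen bonds: %s +/- %s per frame; C_HBs = %s mol/cm^3.",
        fmt_num(d$hbonds$mean), fmt_num(d$hbonds$sd),
        fmt_num(d$hbonds$c_hbs_mol_per_cm3)))
    lines <- c(lines, "")
  }
  if (!is.null(body$energetics)) {
    e <- body$energetics
    lines <- c(lines, "## Energetics", "")
    if (!is.null(e$binding))
      lines <- c(lines, sprintf("Binding energy: %s kcal/mol (frames %s).",
                                fmt_num(e$binding$e_binding_kcal_mol),
                                paste(e$binding$frames_used, collapse = ", ")))
    if (!is.null(e$compatibility))
      for (v in e$compatibility)
        lines <- c(lines, sprintf("Compatibility %s: |d| = %s -> %s.",
                                  v$pair, fmt_num(v$difference), v$category))
    if (!is.null(e$hbond_types))
      lines <- c(lines, sprintf("Hydrogen-bond types (%d): %s.",
                                e$hbond_types$n_types,
                                paste(sprintf("%s (%s)",
                                              names(e$hbond_types$types),
                                              e$hbond_types$types),
                                      collapse = ", ")))
    lines <- c(lines, "")
  }
  if (length(body$skipped_stages))
    lines <- c(lines, paste("Skipped stages:",
                            paste(body$skipped_stages, collapse = ", ")))
  paste(lines, collapse = "\n")
}

#' @export
print.study_report <- function(x, ...) {
  cat(render_report(x, "markdown"), "\n")
  invisible(x)
}
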