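#' Build a run configuration
#'
#' Collects the paths and parameters the pipeline stages need. Can also be
#' loaded from a YAML file with [read_run_config()].
#'
#' @param titration_files Named character vector of titration file paths;
#'   names are temperatures in K (or use `temperatures_c`).
#' @param temperatures_c Optional numeric vector of temperatures in C,
#'   one per titration file (alternative to K names).
#' @param orbitals_file Path to a `label,e_homo,e_lumo` file.
#' @param trajectory_files Character vector of trajectory paths (multi-model
#'   PDB or XYZ), optionally named.
#' @param complex_file Path to a protein-ligand complex PDB.
#' @param wavelength Analysis wavelength, nm.
#' @param hb_cutoff,hb_angle_cutoff,hydrophobic_cutoff Contact criteria
#'   (Angstrom, degrees, Angstrom).
#' @param probe_radius SASA probe radius, Angstrom.
#' @param n_sphere_points SASA test points per atom.
#' @param seed Integer seed recorded in every report header.
#' @param output_dir Directory for reports and series files.
#' @return Object of class `run_config`.
#' @export
run_config <- function(titration_files = character(0), temperatures_c = NULL,
                       orbitals_file = NULL, trajectory_files = character(0),
                       complex_file = NULL, wavelength = 340,
                       hb_cutoff = 3.5, hb_angle_cutoff = 30,
                       hydrophobic_cutoff = 4.0, probe_radius = 1.4,
                       n_sphere_points = 960, seed = 1L,
                       output_dir = tempfile("bindscope_run")) {
  if (!is.null(temperatures_c)) {
    if (length(temperatures_c) != length(titration_files))
      stop("one temperature per titration file required")
    names(titration_files) <- format(celsius_to_kelvin(temperatures_c), trim = TRUE)
  }
  structure(list(titration_files = titration_files,
                 orbitals_file = orbitals_file,
                 trajectory_files = trajectory_files,
                 complex_file = complex_file,
                 wavelength = wavelength, hb_cutoff = hb_cutoff,
                 hb_angle_cutoff = hb_angle_cutoff,
                 hydrophobic_cutoff = hydrophobic_cutoff,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file with keys matching [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  vals$titration_files <- unlist(vals$titration_files)
  do.call(run_config, vals)
}

stage_error <- function(stage, e) {
  stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
}

write_report <- function(df, path, config, stage) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  header <- c(
    sprintf("# bindscope %s report", stage),
    sprintf("# package_version: %s", as.character(utils::packageVersion("bindscope"))),
    sprintf("# seed: %d", config$seed),
    sprintf("# config_hash: %s",
            rlang::hash(unclass(config)[setdiff(names(config), "output_dir")])))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Binding and thermodynamics pipeline
#'
#' Reads one titration file per temperature, fits the double-reciprocal
#' binding model at the configured analysis wavelength, and (with at least
#' two temperatures) runs the Van 't Hoff analysis to obtain enthalpy,
#' entropy, per-temperature free energy and the force classification,
#' assembled as one tidy report row per temperature (temperature C, Kb,
#' R^2, dG, dH, dS in kJ/mol-based units, force class).
#'
#' @param config A [run_config()] with `titration_files` set.
#' @param write If `TRUE`, write `binding_report.tsv` under the output
#'   directory.
#' @param verbose If `TRUE`, log each stage with its parameters.
#' @return List with `fits` (per-temperature `binding_fit`), `thermo`
#'   (`thermo_result` or NULL for a single temperature) and `report`
#'   (data frame).
#' @export
run_binding_pipeline <- function(config, write = TRUE, verbose = FALSE) {
  if (!length(config$titration_files)) stop("[binding] no titration files configured")
  temps <- as.numeric(names(config$titration_files))
  if (anyNA(temps)) stop("[binding] titration files must be named by temperature in K")
  fits <- list()
  for (i in seq_along(config$titration_files)) {
    if (verbose)
      message(sprintf("[binding] fitting %s at %.2f K (wavelength %g nm)",
                      config$titration_files[[i]], temps[i], config$wavelength))
    fits[[i]] <- tryCatch({
      ts <- read_titration(config$titration_files[[i]], temperature = temps[i])
      pts <- delta_f_series(ts, config$wavelength)
      fit_double_reciprocal(pts, config$wavelength, temps[i])
    }, error = function(e) stage_error("binding", e))
  }
  kb <- vapply(fits, function(f) f$kb, 0)
  thermo <- NULL
  if (length(unique(temps)) >= 2L) {
    names(kb) <- format(temps, trim = TRUE)
    thermo <- tryCatch(vant_hoff(kb), error = function(e) stage_error("vant-hoff", e))
  }
  report <- data.frame(
    temperature_c = round(temps - 273.15, 2),
    kb_m1 = signif(kb, 4),
    r_squared = round(vapply(fits, function(f) f$r_squared, 0), 4),
    delta_g_kj_mol = if (is.null(thermo)) NA_real_ else
      round(thermo$delta_g_by_temperature[format(temps, trim = TRUE)] / 1000, 1),
    delta_h_kj_mol = if (is.null(thermo)) NA_real_ else round(thermo$delta_h / 1000, 1),
    delta_s_j_mol_k = if (is.null(thermo)) NA_real_ else round(thermo$delta_s, 1),
    force_class = if (is.null(thermo)) "unavailable" else thermo$force_class)
  rownames(report) <- NULL
  if (write)
    write_report(report, file.path(config$output_dir, "binding_report.tsv"),
                 config, "binding")
  list(fits = fits, thermo = thermo, report = report)
}

#' Frontier-orbital descriptor pipeline
#'
#' @param config A [run_config()] with `orbitals_file` set.
#' @param write If `TRUE`, write `fmo_report.tsv`.
#' @param verbose If `TRUE`, log each stage with its parameters.
#' @return List with `table` (the [descriptor_table()] data frame).
#' @export
run_fmo_pipeline <- function(config, write = TRUE, verbose = FALSE) {
  if (is.null(config$orbitals_file)) stop("[fmo] no orbitals file configured")
  if (verbose) message("[fmo] reading ", config$orbitals_file)
  tab <- tryCatch(descriptor_table(read_orbitals(config$orbitals_file)),
                  error = function(e) stage_error("fmo", e))
  if (write)
    write_report(tab, file.path(config$output_dir, "fmo_report.tsv"), config, "fmo")
  list(table = tab)
}

#' Trajectory summary pipeline
#'
#' One summary row per trajectory (mean RMSD, RMSF, Rg, SASA, covariance
#' trace in nm-based units); per-frame RMSD/Rg/SASA (and hydrogen-bond
#' counts when a ligand is present) series are written alongside the
#' report.
#'
#' @param config A [run_config()] with `trajectory_files` set.
#' @param write If `TRUE`, write `trajectory_report.tsv` and per-frame
#'   series files.
#' @param verbose If `TRUE`, log each stage with its parameters.
#' @return List with `summaries` (per-trajectory `trajectory_summary`) and
#'   `report` (data frame).
#' @export
run_trajectory_pipeline <- function(config, write = TRUE, verbose = FALSE) {
  paths <- config$trajectory_files
  if (!length(paths)) stop("[trajectory] no trajectory files configured")
  labels <- if (is.null(names(paths)) || !all(nzchar(names(paths))))
    tools::file_path_sans_ext(basename(paths)) else names(paths)
  radii <- atom_radii(probe_radius = config$probe_radius)
  summaries <- lapply(seq_along(paths), function(i) {
    if (verbose)
      message(sprintf("[trajectory] %s (probe %g A, %d sphere points)",
                      paths[[i]], config$probe_radius, config$n_sphere_points))
    tryCatch({
      traj <- read_trajectory(paths[[i]])
      summarize_trajectory(traj, radii = radii,
                           n_sphere_points = config$n_sphere_points)
    }, error = function(e) stage_error(paste0("trajectory:", labels[i]), e))
  })
  report <- data.frame(
    trajectory = labels,
    mean_rmsd_nm = vapply(summaries, function(s) s$mean_rmsd, 0),
    mean_rmsf_nm = vapply(summaries, function(s) s$mean_rmsf, 0),
    mean_rg_nm = vapply(summaries, function(s) s$mean_rg, 0),
    mean_sasa_nm2 = vapply(summaries, function(s) s$mean_sasa, 0),
    covariance_trace_nm2 = vapply(summaries, function(s) s$covariance_trace, 0))
  if (write) {
    write_report(report, file.path(config$output_dir, "trajectory_report.tsv"),
                 config, "trajectory")
    for (i in seq_along(summaries)) {
      s <- summaries[[i]]
      series <- data.frame(frame = seq_along(s$rmsd_series),
                           rmsd_nm = s$rmsd_series, rg_nm = s$rg_series)
      series$sasa_nm2 <- NA_real_
      series$sasa_nm2[s$sasa_frames] <- s$sasa_series
      if (!is.null(s$hbond_counts)) series$n_hbonds <- s$hbond_counts
      write_report(series,
                   file.path(config$output_dir, paste0(labels[i], "_series.tsv")),
                   config, "trajectory-series")
    }
  }
  list(summaries = summaries, report = report)
}
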