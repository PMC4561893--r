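.read_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_input("config must be a list or a YAML file path")
  config
}

.check_keys <- function(config, allowed, where = "config") {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_input("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  config
}

.write_manifest <- function(out_dir, files) {
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(file.path(out_dir, files))))
  write.table(man, file.path(out_dir, "manifest.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
}

.log_line <- function(con, level, ...) {
  writeLines(paste0("[", level, "] ", ...), con)
}

.write_field_map <- function(grid, path) {
  d <- data.frame(x = grid$points[, 1], y = grid$points[, 2],
                  z = grid$points[, 3],
                  re_ex = Re(grid$field[, 1]), im_ex = Im(grid$field[, 1]),
                  re_ey = Re(grid$field[, 2]), im_ey = Im(grid$field[, 2]),
                  re_ez = Re(grid$field[, 3]), im_ez = Im(grid$field[, 3]),
                  intensity = grid$intensity)
  write.table(format(d, digits = 8, trim = TRUE), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
}

#' Near-field simulation workflow
#'
#' End-to-end run of the coupled-dipole simulation for one seeded random
#' ensemble: intensity maps at the evaluation plane under normal incidence
#' and under oblique TM illumination, a vertical slice through the ensemble,
#' and an enhancement summary comparing the two illumination conditions.
#' All artifacts (maps, summary, resolved config, manifest with file
#' hashes, log) are written to `out_dir` and are reproducible from (config,
#' seed).
#'
#' Config keys (YAML file or list; all optional): `wavelength` (nm, default
#' 532), `oblique_angle` (degrees, default 65), `polarization` (default
#' "TM"), `plane_height` (nm above the substrate, default 60), `grid_n`
#' (lateral points per axis, default 41), and an `ensemble` block with `n`
#' (default 30), `radius_range` (default 20-25 nm), `region` (default
#' 600x600 nm), `min_gap` (default 2 nm).
#'
#' @param config list or YAML path.
#' @param seed integer seed for the ensemble.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return invisibly, a list with the two enhancement summaries, their
#'   ratio, the solver diagnostics and the grids.
#' @export
run_field_workflow <- function(config = list(), seed = 1, out_dir = NULL) {
  config <- .read_config(config)
  .check_keys(config, c("wavelength", "oblique_angle", "polarization",
                        "plane_height", "grid_n", "ensemble", "seed"))
  if (!is.null(config$seed)) seed <- config$seed
  ens_cfg <- .check_keys(config$ensemble %||% list(),
                         c("n", "radius_range", "region", "min_gap"),
                         "ensemble")
  wavelength <- config$wavelength %||% 532
  angle <- config$oblique_angle %||% 65
  pol <- config$polarization %||% "TM"
  plane_h <- config$plane_height %||% 60
  grid_n <- config$grid_n %||% 41
  region <- unlist(ens_cfg$region %||% c(600, 600))

  opt <- optical_constants(wavelength)
  ens <- generate_ensemble(n = ens_cfg$n %||% 30,
                           radius_range = unlist(ens_cfg$radius_range %||% c(20, 25)),
                           region = region,
                           min_gap = ens_cfg$min_gap %||% 2,
                           seed = seed, optics = opt)
  pts <- plane_grid(plane_h, region, grid_n, grid_n)
  run_one <- function(ang) {
    wv <- plane_wave(wavelength, ang, pol)
    sol <- solve_dipoles(ens, wv)
    grid <- total_field(ens, sol, pts)
    bg <- background_field(pts, wv, opt)
    list(sol = sol, grid = grid, summary = enhancement_summary(grid, bg))
  }
  normal <- run_one(0)
  oblique <- run_one(angle)
  # vertical slice (x-z plane through y = 0) under oblique TM illumination
  zs <- seq(1, plane_h + 40, length.out = grid_n)
  xs <- seq(-region[1] / 2, region[1] / 2, length.out = grid_n)
  slice_pts <- cbind(rep(xs, times = length(zs)), 0, rep(zs, each = length(xs)))
  slice <- suppressWarnings(total_field(ens, oblique$sol, slice_pts))

  result <- list(
    seed = seed,
    mean_enhancement_normal = normal$summary$mean_enhancement,
    mean_enhancement_oblique = oblique$summary$mean_enhancement,
    max_enhancement_oblique = oblique$summary$max_enhancement,
    oblique_over_normal = oblique$summary$mean_enhancement /
      normal$summary$mean_enhancement,
    residual_normal = normal$sol$residual_norm,
    residual_oblique = oblique$sol$residual_norm,
    rcond = oblique$sol$rcond)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file(file.path(out_dir, "log.txt"), "w")
    on.exit(close(log))
    .log_line(log, "INFO", "ensemble of ", nrow(ens$centers),
              " particles, seed ", seed)
    .log_line(log, "INFO", "solver residual (oblique): ",
              format(oblique$sol$residual_norm, digits = 3),
              ", rcond: ", format(oblique$sol$rcond, digits = 3))
    .write_field_map(normal$grid, file.path(out_dir, "map_normal.tsv"))
    .write_field_map(oblique$grid, file.path(out_dir, "map_oblique.tsv"))
    .write_field_map(slice, file.path(out_dir, "slice_vertical.tsv"))
    jsonlite::write_json(result, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    resolved <- list(wavelength = wavelength, oblique_angle = angle,
                     polarization = pol, plane_height = plane_h,
                     grid_n = grid_n, seed = seed,
                     ensemble = list(n = nrow(ens$centers),
                                     radius_range = unlist(ens_cfg$radius_range %||% c(20, 25)),
                                     region = region,
                                     min_gap = ens_cfg$min_gap %||% 2))
    yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
    .write_manifest(out_dir, c("map_normal.tsv", "map_oblique.tsv",
                               "slice_vertical.tsv", "summary.json",
                               "config_resolved.yaml"))
  }
  invisible(c(result, list(normal = normal, oblique = oblique, ensemble = ens)))
}

#' Spectral analysis workflow
#'
#' Baseline subtraction, band ratios, redox calls, and (when a control is
#' named) percent-of-control statistics, for a set of spectra read from
#' two-column ASCII files or synthesized in place. Reports are written as
#' JSON and TSV alongside the resolved config and a file-hash manifest.
#'
#' Config keys: either `spectra` (named list of file paths) or a
#' `synthesis` block (`f_red` vector of reduced fractions, optional
#' `noise_sd`, `baseline_knots`/`baseline_values` of the additive synthetic
#' background); `knots` (baseline-subtraction knot positions, default
#' [default_baseline_knots()]), `control` (name of the control spectrum),
#' `ratio_state` ("oxidized"/"reduced" window centers).
#'
#' @param config list or YAML path.
#' @param seed integer seed used for synthetic noise.
#' @param out_dir output directory, or `NULL`.
#' @return invisibly, a list with per-spectrum `ratios` (data frame),
#'   `calls` (redox calls) and optionally `percent_of_control`.
#' @export
run_spectral_workflow <- function(config = list(), seed = 1, out_dir = NULL) {
  config <- .read_config(config)
  .check_keys(config, c("spectra", "synthesis", "knots", "control",
                        "ratio_state", "seed"))
  if (!is.null(config$seed)) seed <- config$seed
  state <- config$ratio_state %||% "oxidized"
  knots <- if (is.null(config$knots)) default_baseline_knots()
  else baseline_knots(unlist(config$knots))

  traces <- list()
  if (!is.null(config$spectra)) {
    if (length(config$spectra) == 0L) stop_input("empty spectra list")
    missing <- Filter(function(p) !file.exists(p), unlist(config$spectra))
    if (length(missing))
      stop_input("missing spectrum file(s): ", paste(missing, collapse = ", "))
    traces <- lapply(config$spectra, read_spectrum)
  } else if (!is.null(config$synthesis)) {
    syn <- .check_keys(config$synthesis,
                       c("f_red", "noise_sd", "baseline_knots",
                         "baseline_values", "which"), "synthesis")
    fr <- unlist(syn$f_red)
    if (is.null(fr) || length(fr) == 0L)
      stop_input("synthesis block needs a non-empty f_red vector")
    names(fr) <- names(syn$f_red) %||% paste0("f", seq_along(fr))
    traces <- lapply(seq_along(fr), function(i)
      mixture_spectrum(fr[i],
                       which = syn$which %||% "mitochondria",
                       baseline_knots = unlist(syn$baseline_knots %||%
                                                 c(600, 900, 1200, 1500, 1800)),
                       baseline_values = unlist(syn$baseline_values %||%
                                                  c(1.2, 0.9, 0.75, 0.55, 0.5)),
                       noise_sd = syn$noise_sd %||% 0.03,
                       seed = derive_seed(seed, i)))
    names(traces) <- names(fr)
  } else stop_input("config needs a 'spectra' or a 'synthesis' block")

  subtracted <- lapply(traces, subtract_baseline, knots = knots)
  reports <- lapply(subtracted, peak_ratios, state = state)
  calls <- lapply(subtracted, classify_redox)
  ratios <- data.frame(
    name = names(reports),
    r748 = vapply(reports, `[[`, numeric(1), "r748"),
    r1170 = vapply(reports, `[[`, numeric(1), "r1170"),
    r1371 = vapply(reports, `[[`, numeric(1), "r1371"),
    state = vapply(calls, `[[`, character(1), "state"),
    reduced_fraction = vapply(calls, `[[`, numeric(1),
                              "reduced_fraction_estimate"),
    row.names = NULL)
  result <- list(ratios = ratios, calls = calls)
  if (!is.null(config$control)) {
    if (!config$control %in% names(reports))
      stop_input("control spectrum '", config$control, "' not found")
    ctrl <- reports[[config$control]]
    result$percent_of_control <- t(vapply(
      reports, percent_of_control, numeric(3), control = ctrl))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(ratios, file.path(out_dir, "ratios.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(ratios = ratios,
           percent_of_control = result$percent_of_control,
           calls = lapply(calls, function(cl)
             list(state = cl$state,
                  reduced_fraction = cl$reduced_fraction_estimate,
                  low_confidence = cl$low_confidence))),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    resolved <- config
    resolved$seed <- seed
    resolved$knots <- as.list(knots$positions)
    yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))
    .write_manifest(out_dir, c("ratios.tsv", "reports.json",
                               "config_resolved.yaml"))
  }
  invisible(result)
}
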