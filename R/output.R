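# File interfaces: VTK structured points, tidy CSV, YAML configs, manifests.

#' Write cell arrays as a legacy-ASCII VTK structured-points file
#'
#' @param path Output `.vtk` path.
#' @param cell_size Grid spacing (m).
#' @param arrays Named list of `nx x ny` matrices (numeric or integer).
#' @return `path`, invisibly.
#' @export
write_vtk_structured <- function(path, cell_size, arrays) {
  stopifnot(length(arrays) >= 1, !is.null(names(arrays)))
  nx <- nrow(arrays[[1]]); ny <- ncol(arrays[[1]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "implantflow field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d 1", nx + 1L, ny + 1L),
               sprintf("ORIGIN 0 0 0"),
               sprintf("SPACING %.9g %.9g %.9g", cell_size, cell_size, cell_size),
               sprintf("CELL_DATA %d", nx * ny)), con)
  for (nm in names(arrays)) {
    m <- arrays[[nm]]
    if (is.integer(m) || all(m == round(m))) {
      writeLines(sprintf("SCALARS %s int 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(paste(as.integer(t(matrix(m, nx, ny))[, , drop = TRUE]),
                       collapse = "\n"), con)
    } else {
      writeLines(sprintf("SCALARS %s float 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(paste(signif(t(matrix(m, nx, ny)), 7), collapse = "\n"), con)
    }
  }
  invisible(path)
}

#' Write grid and zone masks as VTK
#'
#' Emits integer cell arrays `cell_class` and `zone`.
#'
#' @param grid A `domain_grid`.
#' @param mask A `zone_mask`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_vtk <- function(grid, mask, path) {
  write_vtk_structured(path, grid$cell_size,
                       list(cell_class = grid$cell_class, zone = mask$zone))
}

#' Serialize a scenario configuration to YAML
#'
#' The persisted keys are sufficient to reconstruct the run exactly.
#'
#' @param config A [scenario_config()].
#' @param path Output `.yaml` path.
#' @return `path`, invisibly.
#' @export
write_scenario_config <- function(config, path) {
  out <- list(
    surface = config$surface, theta = config$theta,
    resolution = config$resolution, wetting_mode = config$wetting_mode,
    initial_fill = config$initial_fill, delta = config$delta,
    output_every = config$output_every,
    blood_threshold = config$blood_threshold,
    geometry = unclass(config$geometry),
    roughness = unclass(config$roughness),
    props = unclass(config$props),
    settings = unclass(config$settings))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a scenario configuration from YAML
#'
#' @param path A YAML file written by [write_scenario_config()].
#' @param out_dir Optional output directory to attach.
#' @return A [scenario_config()].
#' @export
read_scenario_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  geo <- do.call(implant_geometry, y$geometry[setdiff(names(y$geometry), "n_threads")])
  rs <- do.call(roughness_spec, y$roughness)
  pr <- do.call(fluid_properties, y$props)
  st <- do.call(solver_settings, y$settings)
  scenario_config(surface = y$surface, theta = y$theta,
                  resolution = y$resolution, wetting_mode = y$wetting_mode,
                  geometry = geo, roughness = rs, props = pr, settings = st,
                  initial_fill = y$initial_fill, delta = y$delta,
                  output_every = y$output_every,
                  blood_threshold = y$blood_threshold, out_dir = out_dir)
}

# Emit all scenario artifacts under config$out_dir.
write_scenario_outputs <- function(result) {
  config <- result$config
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  lbl <- scenario_label(config)
  files <- character(0)
  f <- file.path(config$out_dir, paste0(lbl, "_series.csv"))
  utils::write.csv(result$series, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(config$out_dir, paste0(lbl, "_budget.csv"))
  utils::write.csv(result$budget, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(config$out_dir, paste0(lbl, "_config.yaml"))
  write_scenario_config(config, f)
  files <- c(files, f)
  f <- file.path(config$out_dir, paste0(lbl, "_final.vtk"))
  write_vtk_structured(f, result$grid$cell_size,
                       list(cell_class = result$grid$cell_class,
                            zone = result$mask$zone,
                            alpha = result$sim$phase$alpha,
                            fibrinogen_load = result$sim$species$C,
                            speed = cell_speed(result$sim$state)))
  files <- c(files, f)
  ok_png <- requireNamespace("ggplot2", quietly = TRUE)
  if (ok_png) {
    f <- file.path(config$out_dir, paste0(lbl, "_density_map.png"))
    try({
      ggplot2::ggsave(f, plot_density_map(result), width = 4, height = 7,
                      dpi = 120)
      files <- c(files, f)
    }, silent = TRUE)
    f <- file.path(config$out_dir, paste0(lbl, "_vector_map.png"))
    try({
      ggplot2::ggsave(f, plot_vector_map(result), width = 4, height = 7,
                      dpi = 120)
      files <- c(files, f)
    }, silent = TRUE)
  }
  result$manifest$files <- basename(files)
  f <- file.path(config$out_dir, paste0(lbl, "_manifest.json"))
  jsonlite::write_json(result$manifest, f, auto_unbox = TRUE, digits = NA)
  invisible(c(files, f))
}

#' Write the study comparison report
#'
#' Fold-change table and ordering checks as CSV, plus the zone time-series
#' summary figure as PNG.
#'
#' @param study A [run_study()] result.
#' @param out_dir Output directory.
#' @return Written file paths, invisibly.
#' @export
write_study_report <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(out_dir, "fold_changes.csv")
  utils::write.csv(study$fold_changes, f, row.names = FALSE)
  files <- c(files, f)
  f <- file.path(out_dir, "ordering_checks.csv")
  utils::write.csv(study$checks, f, row.names = FALSE)
  files <- c(files, f)
  series <- dplyr::bind_rows(purrr::map(study$results, "series"))
  f <- file.path(out_dir, "zone_series.csv")
  utils::write.csv(series, f, row.names = FALSE)
  files <- c(files, f)
  try({
    f <- file.path(out_dir, "zone_series.png")
    ggplot2::ggsave(f, plot_zone_series(series), width = 9, height = 6,
                    dpi = 120)
    files <- c(files, f)
  }, silent = TRUE)
  invisible(files)
}
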