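# Orchestration of the 2x2 study: smooth/microrough surfaces crossed with
# superhydrophilic (0 deg) / hydrophobic (70 deg) wettability.

#' Scenario configuration
#'
#' A fully serializable description of one simulation scenario. Resolution
#' presets: `"test"` (coarse, seconds-to-minutes), `"desk"` (default
#' analysis resolution), `"fine"`.
#'
#' @param surface `"smooth"` or `"microrough"`.
#' @param theta Implant contact angle (degrees); 0 superhydrophilic, 70
#'   hydrophobic.
#' @param resolution Grid preset; sets the cell size
#'   (test 1e-4, desk 6.4e-5, fine 3.2e-5 m). The desk preset resolves the
#'   thread depth with 6.25 cells and the domain width with 25.
#' @param wetting_mode Wetting treatment for microrough surfaces:
#'   `"wenzel_effective"` (default; Wenzel-corrected angle plus near-wall
#'   momentum sink) or `"explicit_contact_angle"` (resolved coarsened
#'   roughness on the profile). Smooth surfaces always use the explicit
#'   angle.
#' @param geometry [implant_geometry()].
#' @param roughness [roughness_spec()]; its seed fixes the realization.
#' @param props [fluid_properties()]; by default the scenario presets use a
#'   numerically regularized gas density (10 kg/m^3) for the passive air
#'   phase.
#' @param settings [solver_settings()]; the scenario default applies a
#'   surface tension scale of 0.02 (recorded in the manifest), the largest
#'   scale whose capillary time-step limit stays above the reference time
#'   step at desk resolution, so wetting-driven redistribution is preserved
#'   while the run keeps the reference step.
#' @param initial_fill `"air"` (gap initially empty) or `"blood"`.
#' @param delta Interface-band width (m); defaults to one cell width so the
#'   band stays thin relative to the thread recess.
#' @param output_every Zone-statistics cadence (s).
#' @param blood_threshold Blood-cell threshold for zone mean speeds.
#' @param out_dir Optional output directory; when set, the run writes CSV
#'   series, VTK snapshots, PNG maps and a JSON manifest.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(surface = c("smooth", "microrough"),
                            theta = 70,
                            resolution = c("desk", "test", "fine"),
                            wetting_mode = NULL,
                            geometry = implant_geometry(),
                            roughness = roughness_spec(),
                            props = NULL, settings = NULL,
                            initial_fill = c("air", "blood"),
                            delta = NULL, output_every = 0.1,
                            blood_threshold = 0.5, out_dir = NULL) {
  surface <- match.arg(surface)
  resolution <- match.arg(resolution)
  initial_fill <- match.arg(initial_fill)
  cell_size <- switch(resolution, test = 1e-4, desk = 6.4e-5, fine = 3.2e-5)
  if (is.null(props)) props <- fluid_properties(rho_air = 10)
  if (is.null(settings)) settings <- solver_settings(sigma_scale = 0.02)
  if (is.null(wetting_mode)) {
    wetting_mode <- if (surface == "microrough") "wenzel_effective"
                    else "explicit_contact_angle"
  }
  if (surface == "smooth") wetting_mode <- "explicit_contact_angle"
  if (is.null(delta)) delta <- cell_size
  stopifnot(theta >= 0, theta <= 180, output_every > 0)
  if (geometry$thread_depth / cell_size < 4 - 1e-9) {
    stop("resolution preset does not resolve thread_depth with >= 4 cells")
  }
  structure(list(surface = surface, theta = theta, resolution = resolution,
                 cell_size = cell_size, wetting_mode = wetting_mode,
                 geometry = geometry, roughness = roughness, props = props,
                 settings = settings, initial_fill = initial_fill,
                 delta = delta, output_every = output_every,
                 blood_threshold = blood_threshold, out_dir = out_dir),
            class = "scenario_config")
}

scenario_label <- function(config) {
  paste0(if (config$surface == "microrough") "rough" else "smooth", "_",
         config$theta)
}

#' Run one scenario
#'
#' Builds the geometry (with explicit roughness or the Wenzel-effective
#' treatment), rasterizes, asserts the laminar regime against the
#' turbulence-transition threshold (Re = 2800), advances the coupled
#' flow/VOF/species system to `settings$t_end`, and reduces each output
#' time to zone statistics. With `out_dir` set it also writes the tidy
#' series CSV, budget CSV, VTK snapshots, density/vector PNG maps and a
#' JSON run manifest.
#'
#' @param config A [scenario_config()].
#' @param keep_fields Keep intermediate field snapshots at the PNG map
#'   times (1, 2, 3 s)?
#' @return Object of class `scenario_result`: `config`, `grid`, `mask`,
#'   `series` (tidy zone time series), `budget`, `sim` (final state),
#'   `manifest`.
#' @export
run_scenario <- function(config, keep_fields = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  t_start <- Sys.time()
  rough_explicit <- config$surface == "microrough" &&
    config$wetting_mode == "explicit_contact_angle"
  profile <- build_implant_profile(
    config$geometry,
    roughness = if (rough_explicit) config$roughness else NULL,
    cell_size = if (rough_explicit) config$cell_size else NULL)
  grid <- rasterize_domain(profile, config$geometry, config$cell_size)
  mask <- compute_zone_masks(grid, config$delta)
  bc <- boundary_conditions(contact_angle_theta = config$theta)
  Re <- reynolds_number(config$props, bc, config$geometry$outer_gap_width)
  if (Re >= 2800) stop("flow is not laminar: Re = ", signif(Re, 4), " >= 2800")
  r_w <- if (config$surface == "microrough") {
    roughness_ratio_physical(config$roughness)
  } else 1
  phase <- phase_field(grid, initial_fill = config$initial_fill,
                       wetting_mode = config$wetting_mode,
                       roughness_ratio = r_w)
  species <- species_field(grid, phase)
  sim <- new_simulation(grid, config$props, bc, config$settings, phase,
                        species,
                        roughness = if (config$surface == "microrough")
                          config$roughness else NULL)
  times <- seq(config$output_every, config$settings$t_end,
               by = config$output_every)
  series <- vector("list", length(times))
  fields <- list()
  map_times <- c(1, 2, 3)
  for (k in seq_along(times)) {
    sim <- advance_simulation(sim, times[k])
    series[[k]] <- zone_snapshot_stats(sim$state, sim$phase, sim$species,
                                       mask, grid, config$props,
                                       config$blood_threshold)
    if (keep_fields && any(abs(times[k] - map_times) < 1e-9)) {
      fields[[as.character(times[k])]] <-
        list(alpha = sim$phase$alpha, C = sim$species$C,
             speed = cell_speed(sim$state))
    }
  }
  series <- dplyr::bind_rows(series) |>
    dplyr::mutate(scenario = scenario_label(config), .before = 1)
  result <- structure(
    list(config = config, grid = grid, mask = mask, series = series,
         budget = budget_report(sim), sim = sim, fields = fields,
         reynolds = Re, roughness_ratio = r_w,
         wall_time = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "scenario_result")
  result$manifest <- build_manifest(result)
  if (!is.null(config$out_dir)) {
    written <- write_scenario_outputs(result)
    result$manifest$files <- basename(written)
  }
  result
}

build_manifest <- function(result) {
  config <- result$config
  ser <- config
  ser$props <- unclass(ser$props); ser$settings <- unclass(ser$settings)
  ser$geometry <- unclass(ser$geometry); ser$roughness <- unclass(ser$roughness)
  list(scenario = scenario_label(config),
       config_hash = rlang::hash(unclass(ser)),
       code_version = as.character(utils::packageVersion("implantflow")),
       seed = config$roughness$seed,
       sigma_scale = config$settings$sigma_scale,
       reynolds = result$reynolds,
       roughness_ratio = result$roughness_ratio,
       wall_time_s = result$wall_time,
       cells = c(nx = result$grid$nx, ny = result$grid$ny),
       t_end = config$settings$t_end,
       convergence_metric_final = result$sim$diag$convergence_metric,
       files = character(0))
}

#' Run the four-scenario surface study
#'
#' Smooth/microrough crossed with contact angles 0/70 degrees, followed by
#' the fold-change comparison table and the qualitative ordering
#' assertions: outer > thread > interface zone speeds in every scenario,
#' wettability and topography orderings of zone mass, and the
#' superhydrophilic-microrough interface index as the global maximum.
#'
#' @param configs Optional named list of four [scenario_config()]s
#'   (`smooth_0`, `smooth_70`, `rough_0`, `rough_70`); built from `...`
#'   defaults when omitted.
#' @param ... Arguments passed to [scenario_config()] for the default
#'   matrix (e.g. `resolution`, `out_dir`).
#' @return Object of class `study_result`: `results` (named list),
#'   `fold_changes`, `checks` (tibble of ordering assertions), `window`
#'   statistics per scenario.
#' @export
run_study <- function(configs = NULL, ...) {
  if (is.null(configs)) {
    configs <- list(
      smooth_0 = scenario_config(surface = "smooth", theta = 0, ...),
      smooth_70 = scenario_config(surface = "smooth", theta = 70, ...),
      rough_0 = scenario_config(surface = "microrough", theta = 0, ...),
      rough_70 = scenario_config(surface = "microrough", theta = 70, ...))
  }
  stopifnot(length(configs) == 4, !is.null(names(configs)))
  results <- purrr::imap(configs, function(cf, nm) {
    res <- run_scenario(cf)
    res
  })
  t_end <- configs[[1]]$settings$t_end
  win <- c(min(1, t_end / 3), t_end)
  fc <- fold_change_table(results, t_min = win[1], t_max = win[2])
  stats <- purrr::map(results, function(r) {
    zone_window_stats(r$series, win[1], win[2])
  })
  checks <- study_checks(results, stats)
  structure(list(results = results, fold_changes = fc, checks = checks,
                 window_stats = stats, window = win),
            class = "study_result")
}

# The qualitative findings as machine-checked assertions.
study_checks <- function(results, stats) {
  g <- function(nm, zone, what) {
    st <- stats[[nm]]
    st[[what]][st$zone == zone]
  }
  final_mass <- function(nm, zone) {
    s <- results[[nm]]$series
    tmax <- max(s$time)
    s$mass[s$zone == zone & abs(s$time - tmax) < 1e-12]
  }
  rows <- list()
  addrow <- function(name, pass, detail) {
    rows[[length(rows) + 1]] <<- tibble::tibble(check = name, pass = pass,
                                                detail = detail)
  }
  for (nm in names(results)) {
    vo <- g(nm, "outer", "mean_speed"); vt <- g(nm, "thread", "mean_speed")
    vi <- g(nm, "interface", "mean_speed")
    addrow(paste0("speed_ordering_", nm), vo > vt && vt > vi,
           sprintf("outer %.3g > thread %.3g > interface %.3g", vo, vt, vi))
  }
  for (zone in c("thread", "interface")) {
    addrow(paste0("wetting_mass_smooth_", zone),
           final_mass("smooth_0", zone) >= final_mass("smooth_70", zone),
           "M(theta=0) >= M(theta=70), smooth")
    addrow(paste0("wetting_mass_rough_", zone),
           final_mass("rough_0", zone) >= final_mass("rough_70", zone),
           "M(theta=0) >= M(theta=70), microrough")
    addrow(paste0("topography_mass_70_", zone),
           final_mass("smooth_70", zone) >= final_mass("rough_70", zone),
           "M(smooth) >= M(microrough) at theta=70")
  }
  addrow("interface_speed_rough_slower_70",
         g("rough_70", "interface", "mean_speed") <=
           g("smooth_70", "interface", "mean_speed"),
         "V_interface(microrough) <= V_interface(smooth) at theta=70")
  idx <- purrr::map_dfr(names(results), function(nm) {
    st <- stats[[nm]]
    tibble::tibble(scenario = nm, zone = st$zone, index = st$index)
  })
  best <- idx[which.max(idx$index), ]
  addrow("global_max_index_rough_0_interface",
         best$scenario == "rough_0" && best$zone == "interface",
         sprintf("max index at %s/%s", best$scenario, best$zone))
  ratio_it <- function(nm) {
    s <- results[[nm]]$series
    tmax <- max(s$time)
    at <- s[abs(s$time - tmax) < 1e-12, ]
    (at$mass[at$zone == "interface"] + at$mass[at$zone == "thread"]) /
      max(at$mass[at$zone == "outer"], 1e-30)
  }
  addrow("superhydrophilic_rough_beats_hydrophobic_smooth",
         ratio_it("rough_0") >= ratio_it("smooth_70"),
         "interface+thread infiltration ratio comparison")
  dplyr::bind_rows(rows)
}

#' @export
print.scenario_result <- function(x, ...) {
  cat("<scenario_result> ", scenario_label(x$config),
      " | t = ", max(x$series$time), " s | Re = ", signif(x$reynolds, 3),
      "\n", sep = "")
  print(utils::tail(x$series, 3))
  invisible(x)
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result> scenarios:", paste(names(x$results), collapse = ", "),
      "\n")
  cat("checks passed:", sum(x$checks$pass), "/", nrow(x$checks), "\n")
  invisible(x)
}
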