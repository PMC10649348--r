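# broom-style tidiers for fitted/simulated result objects.

#' Tidy a scenario result
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return The tidy zone time series: `scenario`, `time`, `zone`, `mass`,
#'   `blood_volume`, `mean_speed`, `blood_cells`.
#' @export
tidy.scenario_result <- function(x, ...) {
  x$series
}

#' One-row summary of a scenario run
#'
#' @param x A [run_scenario()] result.
#' @param ... Unused.
#' @return Tibble with scenario label, horizon, Reynolds number, cell
#'   counts, budget closure errors, and wall time.
#' @export
glance.scenario_result <- function(x, ...) {
  tibble::tibble(
    scenario = scenario_label(x$config),
    surface = x$config$surface,
    theta = x$config$theta,
    resolution = x$config$resolution,
    t_end = max(x$series$time),
    reynolds = x$reynolds,
    nx = x$grid$nx, ny = x$grid$ny,
    volume_closure_error = x$budget$volume_closure_error,
    fibrinogen_closure_error = x$budget$fibrinogen_closure_error,
    wall_time_s = x$wall_time)
}

#' Tidy a study result
#'
#' @param x A [run_study()] result.
#' @param ... Unused.
#' @return Combined tidy zone series of the four scenarios.
#' @export
tidy.study_result <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$results, "series"))
}

#' One-row-per-scenario summary of a study
#'
#' @param x A [run_study()] result.
#' @param ... Unused.
#' @return Tibble of per-scenario glances plus ordering-check counts.
#' @export
glance.study_result <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$results, glance)) |>
    dplyr::mutate(checks_passed = sum(x$checks$pass),
                  checks_total = nrow(x$checks))
}
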