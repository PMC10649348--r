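# ggplot2 visualization: density maps, vector maps, zone time series.

field_to_tibble <- function(m, cell_size, mask = NULL) {
  nx <- nrow(m); ny <- ncol(m)
  out <- tibble::tibble(
    x = rep((seq_len(nx) - 0.5) * cell_size, times = ny),
    y = rep((seq_len(ny) - 0.5) * cell_size, each = nx),
    value = as.vector(m))
  if (!is.null(mask)) out$keep <- as.vector(mask)
  out
}

#' Fibrinogen density color map
#'
#' The analogue of the density-based fibrinogen maps: the per-cell
#' fibrinogen load `alpha * Y` over the domain, solids greyed out. A fixed
#' scale limit keeps panels comparable across scenarios.
#'
#' @param result A [run_scenario()] result (or a list with `grid`, `sim`).
#' @param limits Color scale limits; defaults to `c(0, Y0)`.
#' @return A ggplot object.
#' @export
plot_density_map <- function(result, limits = NULL) {
  grid <- result$grid
  sim <- result$sim
  if (is.null(limits)) limits <- c(0, sim$species$Y0)
  df <- field_to_tibble(sim$species$C, grid$cell_size)
  df$solid <- as.vector(is_solid_class(grid$cell_class))
  side <- grid$cell_size * 1e3
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x * 1e3, y = .data$y * 1e3)) +
    ggplot2::geom_tile(data = df[!df$solid, ],
                       ggplot2::aes(fill = pmin(.data$value, limits[2])),
                       width = side, height = side) +
    ggplot2::geom_tile(data = df[df$solid, ], fill = "grey35",
                       width = side, height = side) +
    ggplot2::scale_fill_viridis_c(limits = limits, option = "inferno",
                                  name = "fibrinogen\nload") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Fibrinogen density map") +
    ggplot2::theme_minimal()
}

#' Blood-flow vector map
#'
#' Cell-centered velocity vectors in blood-containing cells, colored by
#' speed — the vector-field analogue plot.
#'
#' @param result A [run_scenario()] result.
#' @param every Subsample stride of cells.
#' @param speed_limits Optional fixed color limits (m/s) for comparability.
#' @return A ggplot object.
#' @export
plot_vector_map <- function(result, every = 2L, speed_limits = NULL) {
  grid <- result$grid
  sim <- result$sim
  h <- grid$cell_size
  u <- sim$state$u; v <- sim$state$v
  nx <- grid$nx; ny <- grid$ny
  uc <- (u[1:nx, ] + u[2:(nx + 1), ]) / 2
  vc <- (v[, 1:ny] + v[, 2:(ny + 1)]) / 2
  keep <- sim$phase$alpha > 0.5 & !is_solid_class(grid$cell_class)
  ii <- seq(1, nx, by = every); jj <- seq(1, ny, by = every)
  sel <- expand.grid(i = ii, j = jj)
  sel <- sel[keep[as.matrix(sel)], , drop = FALSE]
  sp <- sqrt(uc[as.matrix(sel)]^2 + vc[as.matrix(sel)]^2)
  scale_len <- every * h / max(sp, 1e-12)
  df <- tibble::tibble(
    x = (sel$i - 0.5) * h * 1e3, y = (sel$j - 0.5) * h * 1e3,
    dx = uc[as.matrix(sel)] * scale_len * 1e3,
    dy = vc[as.matrix(sel)] * scale_len * 1e3,
    speed = sp)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + .data$dx,
                                       yend = .data$y + .data$dy,
                                       color = .data$speed),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.2, "pt"))) +
    ggplot2::scale_color_viridis_c(limits = speed_limits, name = "speed (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", title = "Blood flow vectors") +
    ggplot2::theme_minimal()
}

#' Zone time-series panel
#'
#' Per-zone fibrinogen mass and mean speed over time, faceted by scenario.
#'
#' @param series Tidy zone series (possibly multiple scenarios).
#' @return A ggplot object.
#' @export
plot_zone_series <- function(series) {
  long <- series |>
    dplyr::select("scenario", "time", "zone", "mass", "mean_speed") |>
    tidyr::pivot_longer(c("mass", "mean_speed"), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     color = .data$zone)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(quantity ~ scenario, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.scenario_result <- function(object, type = c("density", "vectors", "series"),
                                     ...) {
  type <- match.arg(type)
  switch(type,
         density = plot_density_map(object, ...),
         vectors = plot_vector_map(object, ...),
         series = plot_zone_series(object$series))
}

#' @export
autoplot.study_result <- function(object, ...) {
  series <- dplyr::bind_rows(purrr::map(object$results, "series"))
  plot_zone_series(series)
}

#' @export
autoplot.domain_grid <- function(object, ...) {
  df <- field_to_tibble(object$cell_class, object$cell_size)
  df$class <- factor(df$value, levels = cell_class_codes(),
                     labels = names(cell_class_codes()))
  ggplot2::ggplot(df, ggplot2::aes(.data$x * 1e3, .data$y * 1e3,
                                   fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}
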