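# Zone-wise reduction of field snapshots: fibrinogen mass, blood volume,
# mean blood speed, infiltration ratios, and the recruitment/retention index.

zone_labels <- c("interface", "thread", "outer")

#' Per-zone fibrinogen mass
#'
#' `M_z = sum_{cells in z} alpha * rho_blood * Y * cell_area` (kg per unit
#' depth).
#'
#' @param alpha Blood volume fraction matrix.
#' @param Y Fibrinogen mass fraction matrix (same shape).
#' @param rho_blood Blood density (kg/m^3).
#' @param zone_mask A [compute_zone_masks()] result.
#' @param cell_size Grid spacing (m).
#' @return Tibble with `zone` and `mass` rows for interface, thread, outer.
#' @export
zone_fibrinogen_mass <- function(alpha, Y, rho_blood, zone_mask, cell_size) {
  z <- zone_mask$zone
  if (!all(dim(alpha) == dim(z)) || !all(dim(Y) == dim(z))) {
    stop("field and zone mask shapes do not match")
  }
  load <- alpha * Y * rho_blood * cell_size^2
  tibble::tibble(
    zone = zone_labels,
    mass = c(sum(load[z == ZONE_INTERFACE]),
             sum(load[z == ZONE_THREAD]),
             sum(load[z == ZONE_OUTER])))
}

#' Per-zone mean blood speed
#'
#' Arithmetic mean of the cell-centered speed over zone cells containing
#' blood (`alpha > blood_threshold`); zones with no blood cells report 0
#' and are flagged. Volume-weighted averaging is available.
#'
#' @param state [flow_state()].
#' @param alpha Blood volume fraction matrix.
#' @param zone_mask A [compute_zone_masks()] result.
#' @param blood_threshold Minimum volume fraction counting a cell as blood.
#' @param weighted Use alpha-weighted averaging instead of arithmetic.
#' @return Tibble with `zone`, `mean_speed`, `blood_cells`, `empty` flag.
#' @export
zone_mean_speed <- function(state, alpha, zone_mask, blood_threshold = 0.5,
                            weighted = FALSE) {
  z <- zone_mask$zone
  if (!all(dim(alpha) == dim(z))) stop("field and zone mask shapes do not match")
  sp <- cell_speed(state)
  purrr::map_dfr(seq_along(zone_labels), function(k) {
    sel <- z == k & alpha > blood_threshold
    n <- sum(sel)
    v <- if (n == 0) 0 else if (weighted) {
      sum(sp[sel] * alpha[sel]) / sum(alpha[sel])
    } else mean(sp[sel])
    tibble::tibble(zone = zone_labels[k], mean_speed = v,
                   blood_cells = as.integer(n), empty = n == 0L)
  })
}

#' Per-zone blood volume
#'
#' @param alpha Volume fraction matrix.
#' @param zone_mask Zone mask.
#' @param cell_size Grid spacing (m).
#' @return Tibble with `zone`, `blood_volume` (m^2 per unit depth).
#' @export
zone_blood_volume <- function(alpha, zone_mask, cell_size) {
  z <- zone_mask$zone
  tibble::tibble(
    zone = zone_labels,
    blood_volume = vapply(seq_along(zone_labels),
                          function(k) sum(alpha[z == k]) * cell_size^2,
                          numeric(1)))
}

#' Infiltration ratio
#'
#' Percentage of the target-zone fibrinogen mass relative to the outer-zone
#' mass: `100 * M_target / M_outer`. A vanishing outer mass yields `NA`
#' with attribute `undefined = TRUE`.
#'
#' @param M_target Target-zone mass (kg).
#' @param M_outer Outer-zone mass (kg), >= 0.
#' @return Percent (possibly `NA` when undefined).
#' @export
infiltration_ratio <- function(M_target, M_outer) {
  stopifnot(all(M_outer >= 0))
  out <- ifelse(M_outer < 1e-18, NA_real_, 100 * M_target / M_outer)
  if (anyNA(out)) attr(out, "undefined") <- TRUE
  out
}

#' Fibrinogen recruitment/retention index
#'
#' `I_z = M_z / max(V_z, epsilon_v)`: the mass of fibrinogen present in the
#' zone per unit blood speed (kg s/m) — high when much protein sits in
#' slowly moving blood. Velocities below the floor are flagged.
#'
#' @param M_z Zone fibrinogen mass (kg), >= 0.
#' @param V_z Zone mean blood speed (m/s), >= 0.
#' @param epsilon_v Velocity floor (m/s).
#' @return Numeric index, with attribute `floored` marking floored entries.
#' @export
recruitment_retention_index <- function(M_z, V_z, epsilon_v = 1e-9) {
  stopifnot(all(M_z >= 0), all(V_z >= 0), epsilon_v > 0)
  floored <- V_z < epsilon_v
  out <- M_z / pmax(V_z, epsilon_v)
  if (any(floored)) attr(out, "floored") <- floored
  out
}

#' Reduce one snapshot to a zone statistics row set
#'
#' @param state,phase,species Current fields.
#' @param zone_mask,grid,props Domain and property objects.
#' @param blood_threshold Blood-cell threshold for the mean speed.
#' @return Tidy tibble: `time`, `zone`, `mass`, `blood_volume`,
#'   `mean_speed`, `blood_cells`.
#' @export
zone_snapshot_stats <- function(state, phase, species, zone_mask, grid, props,
                                blood_threshold = 0.5) {
  Y <- species_Y(species, phase)
  m <- zone_fibrinogen_mass(phase$alpha, Y, props$rho_blood, zone_mask,
                            grid$cell_size)
  v <- zone_mean_speed(state, phase$alpha, zone_mask, blood_threshold)
  b <- zone_blood_volume(phase$alpha, zone_mask, grid$cell_size)
  dplyr::left_join(m, b, by = "zone") |>
    dplyr::left_join(v, by = "zone") |>
    dplyr::mutate(time = state$time, .before = 1)
}

#' Time-averaged zone statistics from a zone time series
#'
#' Averages mass and mean speed over an interval and derives the
#' recruitment/retention index from the averaged pair.
#'
#' @param series Tidy zone time series (from [run_scenario()]).
#' @param t_min,t_max Averaging window (s).
#' @param epsilon_v Velocity floor for the index.
#' @return Tibble with `zone`, `mass`, `mean_speed`, `index`.
#' @export
zone_window_stats <- function(series, t_min = 1, t_max = 3, epsilon_v = 1e-9) {
  series |>
    dplyr::filter(.data$time >= t_min - 1e-9, .data$time <= t_max + 1e-9) |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(mass = mean(.data$mass),
                     mean_speed = mean(.data$mean_speed), .groups = "drop") |>
    dplyr::mutate(index = recruitment_retention_index(.data$mass,
                                                      .data$mean_speed,
                                                      epsilon_v))
}

#' Fold-change comparison table across the four study scenarios
#'
#' Emits the cross-zone and cross-scenario ratios used to summarise the
#' study: zone-vs-zone velocity ratios within each scenario, and
#' scenario-vs-scenario ratios of mass, velocity, and index per zone, with
#' numerator/denominator provenance recorded. Statistics are taken from the
#' time-averaged window by default, or from the snapshot nearest `at_time`.
#'
#' @param results Named list of four scenario results (see [run_study()]);
#'   names conventionally `smooth_0`, `smooth_70`, `rough_0`, `rough_70`.
#' @param t_min,t_max Averaging window (s) for the default variant.
#' @param at_time Optional single time (s): use the nearest-snapshot
#'   instantaneous statistics instead of the window average.
#' @param epsilon_v Velocity floor for the index.
#' @return Tidy tibble: `comparison`, `quantity`, `zone`, `numerator`,
#'   `denominator`, `value`.
#' @export
fold_change_table <- function(results, t_min = 1, t_max = 3, at_time = NULL,
                              epsilon_v = 1e-9) {
  if (length(results) < 2 || is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list of scenario results")
  }
  stats <- purrr::map(results, function(res) {
    series <- if (inherits(res, "scenario_result")) res$series else res
    if (is.null(series)) stop("missing scenario series in fold_change_table input")
    if (is.null(at_time)) {
      zone_window_stats(series, t_min, t_max, epsilon_v)
    } else {
      tt <- unique(series$time)
      t0 <- tt[which.min(abs(tt - at_time))]
      series |>
        dplyr::filter(abs(.data$time - t0) < 1e-12) |>
        dplyr::transmute(zone = .data$zone, mass = .data$mass,
                         mean_speed = .data$mean_speed,
                         index = recruitment_retention_index(
                           .data$mass, .data$mean_speed, epsilon_v))
    }
  })
  scen <- names(stats)
  rows <- list()
  # zone-vs-zone velocity ratios within each scenario
  for (s in scen) {
    st <- stats[[s]]
    v <- setNames(st$mean_speed, st$zone)
    for (pair in list(c("outer", "thread"), c("outer", "interface"),
                      c("thread", "interface"))) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        comparison = "zone_vs_zone", quantity = "mean_speed",
        zone = paste(pair[1], "over", pair[2]),
        numerator = s, denominator = s,
        value = unname(v[pair[1]] / max(v[pair[2]], epsilon_v)))
    }
  }
  # scenario-vs-scenario ratios per zone and quantity
  combs <- utils::combn(scen, 2, simplify = FALSE)
  for (q in c("mass", "mean_speed", "index")) {
    for (cb in combs) {
      a <- stats[[cb[1]]]; b <- stats[[cb[2]]]
      for (z in zone_labels) {
        num <- a[[q]][a$zone == z]; den <- b[[q]][b$zone == z]
        rows[[length(rows) + 1]] <- tibble::tibble(
          comparison = "scenario_vs_scenario", quantity = q, zone = z,
          numerator = cb[1], denominator = cb[2],
          value = if (den > 0) num / den else NA_real_)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Look up one ratio from a fold-change table
#'
#' @param table A [fold_change_table()] result.
#' @param quantity,zone,numerator,denominator Row selectors.
#' @return Scalar ratio.
#' @export
fold_change <- function(table, quantity, zone, numerator, denominator) {
  hit <- table |>
    dplyr::filter(.data$quantity == !!quantity, .data$zone == !!zone,
                  .data$numerator == !!numerator,
                  .data$denominator == !!denominator)
  if (nrow(hit) == 1) return(hit$value)
  # try the reciprocal orientation
  rev <- table |>
    dplyr::filter(.data$quantity == !!quantity, .data$zone == !!zone,
                  .data$numerator == !!denominator,
                  .data$denominator == !!numerator)
  if (nrow(rev) == 1) return(1 / rev$value)
  stop("no unique fold-change row for ", quantity, "/", zone)
}
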