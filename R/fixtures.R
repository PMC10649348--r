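# Analytic benchmark fixtures. Every fixture runs on the production grid and
# kernel stack, and every expectation is a closed form computable without
# running the solver.

new_fixture <- function(name, grid, props, bc, settings, phase, species,
                        expectation, runtime_budget = 60) {
  structure(list(name = name, grid = grid, props = props, bc = bc,
                 settings = settings, phase = phase, species = species,
                 expectation = expectation, runtime_budget = runtime_budget),
            class = "fixture_case")
}

#' Plane Poiseuille channel fixture
#'
#' Steady laminar flow between parallel no-slip plates driven by a uniform
#' inflow: the developed profile is `u(y) = 1.5 U_mean (1 - (y/h)^2)` with
#' centerline-to-mean ratio 3/2.
#'
#' @param half_width Channel half-width `h` (m).
#' @param U_mean Mean (inflow) speed (m/s).
#' @param props [fluid_properties()]; surface tension is irrelevant here.
#' @param n_across Fluid cells across the channel (odd keeps a centerline
#'   cell).
#' @param n_along Cells along the channel.
#' @return A `fixture_case` whose expectation holds the analytic profile.
#' @export
make_poiseuille <- function(half_width = 4e-4, U_mean = 1e-3,
                            props = fluid_properties(), n_across = 15L,
                            n_along = 3L * n_across) {
  stopifnot(half_width > 0, U_mean >= 0)
  h <- 2 * half_width / n_across
  grid <- channel_grid(n_across, n_along, h)
  bc <- boundary_conditions(inlet_speed = U_mean, contact_angle_theta = 90,
                            contact_angle_bone = 90)
  props$sigma <- 0
  settings <- solver_settings(t_end = 1, pressure_tolerance = 1e-10,
                              sigma_scale = 1)
  phase <- phase_field(grid, initial_fill = "blood")
  species <- species_field(grid, phase)
  profile <- function(y) 1.5 * U_mean * (1 - (y / half_width)^2)
  t_dev <- props$rho_blood * half_width^2 / props$mu_blood
  new_fixture("poiseuille", grid, props, bc, settings, phase, species,
              expectation = list(centerline_mean_ratio = 1.5, tolerance = 0.02,
                                 profile = profile, develop_time = t_dev))
}

#' Run the Poiseuille fixture to steady state
#'
#' @param case A [make_poiseuille()] fixture.
#' @param t_end Horizon (s); defaults to 4 viscous development times.
#' @return List: `ratio` (centerline/mean), `profile` tibble
#'   (`y`, `speed`, `analytic`), `rel_error` (max relative profile error at
#'   the centerline scale), and the final `sim`.
#' @export
run_poiseuille <- function(case, t_end = NULL) {
  if (is.null(t_end)) t_end <- 4 * case$expectation$develop_time
  sim <- new_simulation(case$grid, case$props, case$bc, case$settings,
                        case$phase, case$species)
  sim <- advance_simulation(sim, t_end)
  grid <- case$grid
  jmid <- round(grid$ny / 2)
  fluid_cols <- which(grid$cell_class[, jmid] == CLASS_FLUID)
  v <- sim$state$v
  vmid <- (v[fluid_cols, jmid] + v[fluid_cols, jmid + 1]) / 2
  xc <- (fluid_cols - 0.5) * grid$cell_size
  y <- xc - mean(range(xc))
  analytic <- case$expectation$profile(y)
  ratio <- max(vmid) / mean(vmid)
  list(ratio = ratio,
       profile = tibble::tibble(y = y, speed = vmid, analytic = analytic),
       rel_error = max(abs(vmid - analytic)) / max(analytic),
       sim = sim)
}

#' Capillary infiltration fixture
#'
#' A vertical 2-D channel of half-width `R` connected to a blood reservoir
#' at zero pressure; wetting walls pull the front in. After the inertial
#' transient the front obeys the channel Lucas-Washburn law
#' `dL/dt = sigma R cos(theta) / (4 mu L)`, i.e.
#' `L(t) = sqrt(sigma R cos(theta) / (2 mu)) * sqrt(t)`.
#'
#' @param R Channel half-width (m).
#' @param theta Wall contact angle (degrees).
#' @param props [fluid_properties()].
#' @param n_across Fluid cells across the full channel width.
#' @param channel_length Channel length (m).
#' @return A `fixture_case` with the Washburn coefficient expectation.
#' @export
make_capillary <- function(R = 2.5e-4, theta = 0, props = fluid_properties(),
                           n_across = 16L, channel_length = 12 * R) {
  stopifnot(R > 0)
  h <- 2 * R / n_across
  grid <- channel_grid(n_across, ceiling(channel_length / h), h)
  bc <- boundary_conditions(inlet_speed = 0, contact_angle_theta = theta,
                            contact_angle_bone = theta,
                            inlet_type = "pressure", inlet_pressure = 0)
  settings <- solver_settings(t_end = 1, pressure_tolerance = 1e-8)
  phase <- phase_field(grid, initial_fill = "air")
  species <- species_field(grid, phase)
  coef <- sqrt(props$sigma * R * max(cos(theta * pi / 180), 0) / (2 * props$mu_blood))
  new_fixture("capillary", grid, props, bc, settings, phase, species,
              expectation = list(washburn_coefficient = coef, tolerance = 0.2,
                                 R = R, theta = theta))
}

#' Run the capillary fixture and fit the Washburn coefficient
#'
#' The front position is the blood-filled volume divided by the channel
#' width. The coefficient is fitted as the slope of `L^2` against `t` over
#' the window (past the inertial transient), `L = sqrt(slope * t)`.
#'
#' @param case A [make_capillary()] fixture.
#' @param t_end Horizon (s).
#' @param fit_window Length-2 times (s) bounding the fit.
#' @param n_samples Front-position samples.
#' @return List: `coefficient`, `front` tibble (`time`, `L`), `sim`.
#' @export
run_capillary <- function(case, t_end, fit_window = c(t_end / 3, t_end),
                          n_samples = 24L) {
  grid <- case$grid
  width <- sum(grid$cell_class[, 2] != CLASS_BONE) * grid$cell_size
  sim <- new_simulation(grid, case$props, case$bc, case$settings,
                        case$phase, case$species)
  times <- seq(0, t_end, length.out = n_samples + 1L)[-1]
  L <- numeric(length(times))
  interior <- !is_solid_class(grid$cell_class) &
    grid$cell_class != CLASS_INLET_APEX
  for (k in seq_along(times)) {
    sim <- advance_simulation(sim, times[k])
    L[k] <- sum(sim$phase$alpha * interior) * grid$cell_size^2 / width
  }
  inwin <- times >= fit_window[1] & times <= fit_window[2]
  fit <- stats::lm(I(L[inwin]^2) ~ times[inwin])
  slope <- unname(coef(fit)[2])
  list(coefficient = sqrt(max(slope, 0)),
       front = tibble::tibble(time = times, L = L), sim = sim)
}

#' Static droplet fixture (Young-Laplace)
#'
#' A stationary blood disc of radius `R` in air inside a closed box; the
#' equilibrium pressure jump across the interface is `sigma / R` in 2-D.
#'
#' @param R Droplet radius (m).
#' @param props [fluid_properties()].
#' @param n Interior cells per side.
#' @param domain_size Box side (m); default `4 R`.
#' @return A `fixture_case`.
#' @export
make_static_droplet <- function(R = 5e-4, props = fluid_properties(),
                                n = 48L, domain_size = 4 * R) {
  h <- domain_size / n
  grid <- box_grid(n, n, h)
  bc <- boundary_conditions(inlet_speed = 0, contact_angle_theta = 90,
                            contact_angle_bone = 90)
  settings <- solver_settings(pressure_tolerance = 1e-8,
                              curvature_smoothing = 6)
  phase <- phase_field(grid, initial_fill = "air")
  cx <- grid$width / 2; cy <- grid$height / 2
  phase$alpha <- disc_alpha(grid, cx, cy, R)
  species <- species_field(grid, phase)
  new_fixture("static_droplet", grid, props, bc, settings, phase, species,
              expectation = list(pressure_jump = props$sigma / R,
                                 tolerance = 0.10, R = R))
}

# Sub-cell-accurate volume fraction of a disc on the grid (supersampling).
disc_alpha <- function(grid, cx, cy, R, nsub = 4L) {
  h <- grid$cell_size
  alpha <- matrix(0, grid$nx, grid$ny)
  off <- (seq_len(nsub) - 0.5) / nsub
  for (i in seq_len(grid$nx)) {
    x0 <- (i - 1) * h
    for (j in seq_len(grid$ny)) {
      if (is_solid_class(grid$cell_class[i, j])) next
      y0 <- (j - 1) * h
      xs <- x0 + off * h
      ys <- y0 + off * h
      d2 <- outer(xs - cx, ys - cy, function(a, b) a^2 + b^2)
      alpha[i, j] <- mean(d2 <= R^2)
    }
  }
  alpha
}

#' Run the static droplet fixture
#'
#' @param case A [make_static_droplet()] fixture.
#' @param t_end Relaxation horizon (s).
#' @return List: `pressure_jump` (mean inside minus mean outside),
#'   `max_spurious_speed`, `sim`.
#' @export
run_static_droplet <- function(case, t_end = 2e-3) {
  sim <- new_simulation(case$grid, case$props, case$bc, case$settings,
                        case$phase, case$species)
  sim <- advance_simulation(sim, t_end)
  a <- sim$phase$alpha
  p <- sim$state$p
  fl <- sim$grid$cell_class == CLASS_FLUID
  inside <- fl & a > 0.95
  outside <- fl & a < 0.05
  list(pressure_jump = mean(p[inside]) - mean(p[outside]),
       max_spurious_speed = max(abs(sim$state$u), abs(sim$state$v)),
       sim = sim)
}

#' Sessile droplet fixture (contact-angle check)
#'
#' A half-disc of blood on the floor of a closed box relaxes toward a
#' circular cap meeting the wall at the imposed contact angle. The measured
#' angle comes from a circle fit to the `alpha = 0.5` contour:
#' `theta = acos(-yc / R)` with the wall at `y = 0`.
#'
#' @param theta Imposed contact angle (degrees).
#' @param R0 Initial half-disc radius (m).
#' @param props [fluid_properties()].
#' @param n_x,n_y Interior cells.
#' @return A `fixture_case`.
#' @export
make_sessile_droplet <- function(theta = 70, R0 = 4e-4,
                                 props = fluid_properties(),
                                 n_x = 72L, n_y = 36L) {
  h <- 4 * R0 / n_x
  grid <- box_grid(n_x, n_y, h)
  bc <- boundary_conditions(inlet_speed = 0, contact_angle_theta = theta,
                            contact_angle_bone = theta)
  settings <- solver_settings(pressure_tolerance = 1e-8,
                              curvature_smoothing = 6)
  phase <- phase_field(grid, initial_fill = "air")
  cx <- grid$width / 2
  phase$alpha <- disc_alpha(grid, cx, grid$cell_size, R0)
  phase$alpha[is_solid_class(grid$cell_class)] <- 0
  species <- species_field(grid, phase)
  new_fixture("sessile_droplet", grid, props, bc, settings, phase, species,
              expectation = list(theta = theta, tolerance_deg = 5))
}

#' Run the sessile droplet fixture and measure the contact angle
#'
#' @param case A [make_sessile_droplet()] fixture.
#' @param t_end Relaxation horizon (s).
#' @return List: `theta_measured` (degrees), `fit` (circle parameters),
#'   `sim`.
#' @export
run_sessile_droplet <- function(case, t_end = 5e-3) {
  sim <- new_simulation(case$grid, case$props, case$bc, case$settings,
                        case$phase, case$species)
  sim <- advance_simulation(sim, t_end)
  measure_sessile_angle(sim)
}

measure_sessile_angle <- function(sim) {
  grid <- sim$grid
  h <- grid$cell_size
  pts <- interface_points(sim$phase$alpha, h)
  # wall plane: top of the bottom solid row
  y_wall <- h
  keep <- pts$y > y_wall + 1.0 * h    # exclude the contact-line cells
  pts <- pts[keep, ]
  fit <- fit_circle(pts$x, pts$y - y_wall)
  ratio <- pmin(pmax(-fit$yc / fit$R, -1), 1)
  list(theta_measured = acos(ratio) * 180 / pi, fit = fit, sim = sim,
       points = pts)
}

#' Synthetic zone snapshot with exactly known statistics
#'
#' Builds piecewise-constant per-zone fields on a grid and computes the
#' expected zone statistics by direct, independent summation over the
#' constructed arrays (no calls into the statistics module).
#'
#' @param zone_mask A [compute_zone_masks()] result.
#' @param grid Matching grid.
#' @param alpha,Y,speed Named numeric vectors over
#'   `c(interface, thread, outer)` (recycled if scalar).
#' @param rho_blood Blood density used for the expected masses.
#' @return List: `phase`, `species`, `state` plus `expected` (tibble with
#'   per-zone mass, blood volume, mean speed).
#' @export
make_zone_snapshot <- function(zone_mask, grid, alpha = 1, Y = 0.0029,
                               speed = 1e-4, rho_blood = 1060) {
  av <- rep_len(alpha, 3); yv <- rep_len(Y, 3); sv <- rep_len(speed, 3)
  z <- zone_mask$zone
  A <- matrix(0, grid$nx, grid$ny)
  Ym <- matrix(0, grid$nx, grid$ny)
  S <- matrix(0, grid$nx, grid$ny)
  for (k in 1:3) {
    A[z == k] <- av[k]; Ym[z == k] <- yv[k]; S[z == k] <- sv[k]
  }
  state <- flow_state(grid)
  # vertical speed; both faces of a cell carry its zone speed (later
  # assignments win on shared faces)
  for (j in seq_len(grid$ny)) for (i in seq_len(grid$nx)) {
    if (z[i, j] == 0) next
    state$v[i, j] <- S[i, j]; state$v[i, j + 1] <- S[i, j]
  }
  phase <- phase_field(grid)
  phase$alpha <- A
  species <- species_field(grid, phase)
  species$C <- A * Ym
  # independent direct-arithmetic expectation from the realized fields
  uc <- (state$u[1:grid$nx, , drop = FALSE] +
           state$u[2:(grid$nx + 1), , drop = FALSE]) / 2
  vc <- (state$v[, 1:grid$ny, drop = FALSE] +
           state$v[, 2:(grid$ny + 1), drop = FALSE]) / 2
  spd <- sqrt(uc^2 + vc^2)
  h2 <- grid$cell_size^2
  expected <- purrr::map_dfr(1:3, function(k) {
    sel <- z == k
    blood <- sel & A > 0.5
    tibble::tibble(zone = zone_labels[k],
                   mass = sum(A[sel] * Ym[sel]) * rho_blood * h2,
                   blood_volume = sum(A[sel]) * h2,
                   mean_speed = if (any(blood)) mean(spd[blood]) else 0)
  })
  list(phase = phase, species = species, state = state, expected = expected)
}

#' Divergence-free single-vortex velocity field
#'
#' Face velocities derived from a stream function sampled at grid nodes,
#' hence exactly discretely divergence-free; used by the interface
#' reversibility fixture.
#'
#' @param grid Domain grid.
#' @param strength Peak stream-function amplitude (m^2/s).
#' @return A [flow_state()] carrying the vortex.
#' @export
vortex_state <- function(grid, strength = 1e-4) {
  h <- grid$cell_size
  W <- grid$width; H <- grid$height
  psi <- function(x, y) strength * sin(pi * x / W)^2 * sin(pi * y / H)^2
  state <- flow_state(grid)
  # u = dpsi/dy on vertical faces, v = -dpsi/dx on horizontal faces
  for (i in 0:grid$nx) for (j in seq_len(grid$ny)) {
    x <- i * h
    state$u[i + 1, j] <- (psi(x, j * h) - psi(x, (j - 1) * h)) / h
  }
  for (i in seq_len(grid$nx)) for (j in 0:grid$ny) {
    y <- j * h
    state$v[i, j + 1] <- -(psi(i * h, y) - psi((i - 1) * h, y)) / h
  }
  state
}

#' Run all fixture benchmarks
#'
#' Executes the analytic benchmark suite (Poiseuille ratio, Young-Laplace
#' jump, sessile contact angle, Lucas-Washburn coefficient) and reports
#' measured versus expected values; this is the `bench` entry point.
#'
#' @param quick Use reduced horizons/resolutions.
#' @return Tibble: `fixture`, `measured`, `expected`, `tolerance`, `pass`.
#' @export
run_all_fixtures <- function(quick = TRUE) {
  rows <- list()
  po <- make_poiseuille(n_across = if (quick) 15L else 31L)
  rp <- run_poiseuille(po)
  rows$poiseuille <- tibble::tibble(
    fixture = "poiseuille_ratio", measured = rp$ratio, expected = 1.5,
    tolerance = 0.02 * 1.5)
  dr <- make_static_droplet(n = if (quick) 48L else 96L)
  rd <- run_static_droplet(dr)
  rows$droplet <- tibble::tibble(
    fixture = "young_laplace_jump", measured = rd$pressure_jump,
    expected = dr$expectation$pressure_jump,
    tolerance = 0.10 * dr$expectation$pressure_jump)
  se <- make_sessile_droplet(theta = 70)
  rs <- run_sessile_droplet(se)
  rows$sessile <- tibble::tibble(
    fixture = "sessile_contact_angle", measured = rs$theta_measured,
    expected = 70, tolerance = 5)
  props_lw <- fluid_properties(mu_blood = 3.5e-2)
  ca <- make_capillary(theta = 0, props = props_lw, n_across = 16L,
                       channel_length = 2.8e-3)
  rc <- run_capillary(ca, t_end = 0.035, fit_window = c(0.015, 0.035),
                      n_samples = 12L)
  rows$capillary <- tibble::tibble(
    fixture = "washburn_coefficient", measured = rc$coefficient,
    expected = ca$expectation$washburn_coefficient,
    tolerance = 0.2 * ca$expectation$washburn_coefficient)
  dplyr::bind_rows(rows) |>
    dplyr::mutate(pass = abs(.data$measured - .data$expected) <= .data$tolerance)
}
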