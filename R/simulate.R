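# Shared time-marching driver over the compiled kernels. Fixtures and the
# scenario pipeline both advance through this single code path.

#' Assemble a simulation
#'
#' Bundles grid, fields, and parameters into one advanceable object.
#'
#' @param grid [rasterize_domain()] grid.
#' @param props,bc,settings Parameter objects.
#' @param phase [phase_field()]; a default air-filled field when omitted.
#' @param species [species_field()]; a default physiological field when
#'   omitted.
#' @param roughness Optional [roughness_spec()] used to derive the
#'   Wenzel-effective momentum sink when the phase runs in effective mode.
#' @return Object of class `implant_sim`.
#' @export
new_simulation <- function(grid, props = fluid_properties(),
                           bc = boundary_conditions(),
                           settings = solver_settings(),
                           phase = NULL, species = NULL, roughness = NULL) {
  if (is.null(phase)) phase <- phase_field(grid)
  if (is.null(species)) species <- species_field(grid, phase)
  sink <- sink_matrix(grid, props, roughness, phase$wetting_mode)
  structure(list(grid = grid, props = props, bc = bc, settings = settings,
                 phase = phase, species = species, state = flow_state(grid),
                 sink = sink,
                 budget = c(alpha_in = 0, alpha_out = 0, C_in = 0, C_out = 0),
                 convergence = numeric(0)),
            class = "implant_sim")
}

#' Advance a simulation to a target time
#'
#' Runs the fused compiled loop (surface tension, momentum predictor,
#' pressure projection, VOF + species advection, species diffusion) with
#' stability-limited time steps until `t_target`.
#'
#' @param sim [new_simulation()] object.
#' @param t_target Target time (s).
#' @param max_steps Safety cap on steps for this call.
#' @return Updated `implant_sim`; diagnostic scalars of the last step are
#'   stored in `sim$diag`.
#' @export
advance_simulation <- function(sim, t_target, max_steps = 2000000L) {
  if (t_target <= sim$state$time) return(sim)
  par <- solver_par(sim$grid, sim$props, sim$bc, sim$settings,
                    sim$phase$wetting_mode, sim$phase$roughness_ratio)
  par$Y0 <- sim$species$Y0
  out <- cpp_advance(sim$state$u, sim$state$v, sim$state$p,
                     sim$phase$alpha, sim$species$C,
                     sim$grid$cell_class, sim$sink, par,
                     sim$state$time, t_target,
                     sim$settings$dt_reference, sim$settings$cfl_cap,
                     sim$species$D, sim$budget, as.integer(max_steps))
  sim$state$u <- out$u; sim$state$v <- out$v; sim$state$p <- out$p
  sim$state$time <- out$t
  sim$state$step <- sim$state$step + out$steps
  sim$phase$alpha <- out$alpha
  sim$species$C <- out$C
  sim$budget <- setNames(out$budget, names(sim$budget))
  sim$diag <- list(iterations = out$iterations, residual = out$residual,
                   max_divergence = out$max_divergence,
                   convergence_metric = out$convergence_metric,
                   max_speed = out$max_speed)
  sim$convergence <- c(sim$convergence, out$convergence_metric)
  sim
}

#' Global volume and fibrinogen budgets of a simulation
#'
#' Compares the blood volume and fibrinogen mass present in the domain with
#' the cumulative boundary fluxes; the relative closure errors are the
#' sharpest correctness check of the transport scheme.
#'
#' @param sim [new_simulation()] object (advanced).
#' @return Tibble with one row: volumes, masses, cumulative fluxes, and
#'   relative closure errors.
#' @export
budget_report <- function(sim) {
  grid <- sim$grid
  cls <- grid$cell_class
  interior <- !is_solid_class(cls) & cls != CLASS_INLET_APEX &
    cls != CLASS_INLET_BONE
  vol <- sum(sim$phase$alpha * interior) * grid$cell_size^2
  mass <- total_fibrinogen_mass(sim$species, grid, sim$props)
  b <- sim$budget
  rho <- sim$props$rho_blood
  vol_err <- if (b[["alpha_in"]] > 0) {
    abs(vol - (b[["alpha_in"]] - b[["alpha_out"]])) / b[["alpha_in"]]
  } else 0
  mass_err <- if (b[["C_in"]] > 0) {
    abs(mass - rho * (b[["C_in"]] - b[["C_out"]])) / (rho * b[["C_in"]])
  } else 0
  tibble::tibble(time = sim$state$time, blood_volume = vol,
                 fibrinogen_mass = mass,
                 volume_in = b[["alpha_in"]], volume_out = b[["alpha_out"]],
                 fib_in = rho * b[["C_in"]], fib_out = rho * b[["C_out"]],
                 volume_closure_error = vol_err,
                 fibrinogen_closure_error = mass_err)
}

#' Construct a rectangular channel grid on the production type stack
#'
#' A vertical channel with solid wall columns on both sides, an inlet strip
#' at the bottom and an outlet at the top; used by the analytic fixtures.
#'
#' @param n_across Fluid cells across the channel.
#' @param n_along Fluid cells along the channel.
#' @param cell_size Grid spacing (m).
#' @param wall_cells Solid wall thickness in cells per side.
#' @return A `domain_grid`.
#' @export
channel_grid <- function(n_across, n_along, cell_size, wall_cells = 1L) {
  nx <- n_across + 2L * wall_cells
  ny <- n_along + 2L
  cls <- matrix(CLASS_FLUID, nx, ny)
  cls[seq_len(wall_cells), ] <- CLASS_BONE
  cls[nx - seq_len(wall_cells) + 1L, ] <- CLASS_BONE
  mid <- (wall_cells + 1L):(nx - wall_cells)
  cls[mid, 1] <- CLASS_INLET_APEX
  cls[mid, ny] <- CLASS_OUTLET
  structure(list(cell_size = cell_size, nx = nx, ny = ny, cell_class = cls,
                 width = nx * cell_size, height = ny * cell_size,
                 params = NULL, profile = NULL),
            class = "domain_grid")
}

#' Construct a closed box grid (no inlets or outlets)
#'
#' All-fluid interior enclosed by solid walls; used by droplet and
#' translation fixtures.
#'
#' @param n_x,n_y Interior fluid cells.
#' @param cell_size Grid spacing (m).
#' @param open_top Replace the top wall by an outlet strip.
#' @return A `domain_grid`.
#' @export
box_grid <- function(n_x, n_y, cell_size, open_top = FALSE) {
  nx <- n_x + 2L; ny <- n_y + 2L
  cls <- matrix(CLASS_FLUID, nx, ny)
  cls[1, ] <- CLASS_BONE; cls[nx, ] <- CLASS_BONE
  cls[, 1] <- CLASS_BONE
  cls[, ny] <- if (open_top) CLASS_BONE else CLASS_BONE
  if (open_top) cls[2:(nx - 1L), ny] <- CLASS_OUTLET
  structure(list(cell_size = cell_size, nx = nx, ny = ny, cell_class = cls,
                 width = nx * cell_size, height = ny * cell_size,
                 params = NULL, profile = NULL),
            class = "domain_grid")
}
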