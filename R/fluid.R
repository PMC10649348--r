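# Transient incompressible laminar flow: properties, boundary conditions,
# solver settings, the staggered flow state, and the projection step.

#' Fluid properties of the blood/air system
#'
#' Whole blood is treated as a single Newtonian phase with effective
#' properties; the hematocrit is carried as a composition constant, not a
#' separate phase. The serum density is used only to derive the inlet
#' fibrinogen mass fraction.
#'
#' @param rho_blood Blood density (kg/m^3).
#' @param mu_blood Blood dynamic viscosity (Pa s).
#' @param rho_air,mu_air Density and viscosity of the displaced gas phase.
#' @param rho_serum Blood serum density (kg/m^3), fixed physiological 1024.
#' @param sigma Blood-air surface tension (N/m).
#' @param hematocrit Red-cell volume fraction at the inlet (composition
#'   bookkeeping only).
#' @return Object of class `fluid_properties`.
#' @export
fluid_properties <- function(rho_blood = 1060, mu_blood = 3.5e-3,
                             rho_air = 1.2, mu_air = 1.8e-5,
                             rho_serum = 1024, sigma = 0.058,
                             hematocrit = 0.45) {
  stopifnot(rho_blood > 0, mu_blood > 0, rho_air > 0, mu_air > 0,
            rho_serum > 0, sigma >= 0, hematocrit > 0, hematocrit < 1)
  structure(list(rho_blood = rho_blood, mu_blood = mu_blood,
                 rho_air = rho_air, mu_air = mu_air, rho_serum = rho_serum,
                 sigma = sigma, hematocrit = hematocrit),
            class = "fluid_properties")
}

#' Boundary conditions
#'
#' Blood enters at the apical inlet and through the lateral bone wall at
#' `inlet_speed` (capillary-scale 0.001 m/s); the top of the gap is a
#' zero-pressure free outflow; walls are no-slip. The implant wall contact
#' angle encodes the wettability scenario (0 superhydrophilic, 70
#' hydrophobic); the bone wall is wet tissue and is fully wetting.
#'
#' @param inlet_speed Inlet velocity (m/s), >= 0.
#' @param contact_angle_theta Implant-wall contact angle (degrees, 0..180).
#' @param contact_angle_bone Bone-wall contact angle (degrees).
#' @param inlet_type `"velocity"` (prescribed speed) or `"pressure"`
#'   (reservoir at `inlet_pressure`, used by the capillary fixture).
#' @param inlet_pressure Reservoir pressure (Pa) for pressure inlets.
#' @return Object of class `boundary_conditions`.
#' @export
boundary_conditions <- function(inlet_speed = 0.001,
                                contact_angle_theta = 70,
                                contact_angle_bone = 0,
                                inlet_type = c("velocity", "pressure"),
                                inlet_pressure = 0) {
  inlet_type <- match.arg(inlet_type)
  stopifnot(inlet_speed >= 0,
            contact_angle_theta >= 0, contact_angle_theta <= 180,
            contact_angle_bone >= 0, contact_angle_bone <= 180)
  structure(list(inlet_speed = inlet_speed,
                 contact_angle_theta = contact_angle_theta,
                 contact_angle_bone = contact_angle_bone,
                 inlet_type = inlet_type, inlet_pressure = inlet_pressure),
            class = "boundary_conditions")
}

#' Solver settings
#'
#' @param dt_reference Reference time step (s); the actual step is the
#'   minimum of this and the CFL / capillary / diffusive stability limits.
#' @param cfl_cap Courant number cap (0, 1).
#' @param t_end Simulated horizon (s).
#' @param pressure_tolerance Relative residual target of the pressure solve.
#' @param pressure_maxit Iteration cap of the pressure solve.
#' @param convergence_metric_tol Relative per-step change of the total
#'   fibrinogen inflow rate below which a step counts as converged (logged,
#'   mirroring a mass-flow convergence rule).
#' @param curvature_smoothing Laplacian smoothing passes used before
#'   curvature evaluation.
#' @param sigma_scale Multiplier applied to the surface tension for
#'   numerical robustness on coarse grids; recorded in run metadata.
#' @return Object of class `solver_settings`.
#' @export
solver_settings <- function(dt_reference = 1e-4, cfl_cap = 0.4, t_end = 3.0,
                            pressure_tolerance = 1e-6, pressure_maxit = 3000,
                            convergence_metric_tol = 1e-3,
                            curvature_smoothing = 4, sigma_scale = 1) {
  stopifnot(dt_reference > 0, cfl_cap > 0, cfl_cap < 1, t_end > 0,
            pressure_tolerance > 0, pressure_maxit >= 1,
            curvature_smoothing >= 0, sigma_scale > 0, sigma_scale <= 1)
  structure(list(dt_reference = dt_reference, cfl_cap = cfl_cap, t_end = t_end,
                 pressure_tolerance = pressure_tolerance,
                 pressure_maxit = as.integer(pressure_maxit),
                 convergence_metric_tol = convergence_metric_tol,
                 curvature_smoothing = as.integer(curvature_smoothing),
                 sigma_scale = sigma_scale),
            class = "solver_settings")
}

#' Initial flow state on a grid
#'
#' Staggered arrangement: `u` on vertical faces (`(nx+1) x ny`), `v` on
#' horizontal faces (`nx x (ny+1)`), cell-centered pressure, a simulation
#' clock and a step counter.
#'
#' @param grid A [rasterize_domain()] grid.
#' @return Object of class `flow_state`.
#' @export
flow_state <- function(grid) {
  stopifnot(inherits(grid, "domain_grid"))
  structure(list(u = matrix(0, grid$nx + 1, grid$ny),
                 v = matrix(0, grid$nx, grid$ny + 1),
                 p = matrix(0, grid$nx, grid$ny),
                 time = 0, step = 0L),
            class = "flow_state")
}

#' Reynolds number of the inlet flow
#'
#' `Re = rho_blood * inlet_speed * L / mu_blood`; the laminar assumption is
#' asserted against the transition threshold 2800 before every scenario run.
#'
#' @param props [fluid_properties()].
#' @param bc [boundary_conditions()].
#' @param characteristic_length Length scale (m); the outer gap width by
#'   convention.
#' @return Dimensionless Reynolds number.
#' @export
reynolds_number <- function(props, bc, characteristic_length) {
  stopifnot(characteristic_length > 0)
  props$rho_blood * bc$inlet_speed * characteristic_length / props$mu_blood
}

#' Stability-limited time step
#'
#' `dt = min(dt_reference, cfl_cap * h / max_speed, capillary limit)` with
#' the capillary limit `sqrt(rho_blood h^3 / (2 pi sigma))` (denser-phase
#' density) active when `sigma > 0`. The solver additionally enforces its
#' explicit-diffusion limit internally.
#'
#' @param state A [flow_state()].
#' @param settings [solver_settings()].
#' @param props [fluid_properties()].
#' @param cell_size Grid spacing (m).
#' @return Time step (s), strictly positive.
#' @export
adaptive_dt <- function(state, settings, props, cell_size) {
  um <- max(abs(state$u), abs(state$v))
  if (!is.finite(um)) stop("non-finite maximum speed")
  dt <- settings$dt_reference
  if (um > 0) dt <- min(dt, settings$cfl_cap * cell_size / um)
  sig <- props$sigma * settings$sigma_scale
  if (sig > 0) {
    dt <- min(dt, sqrt(props$rho_blood * cell_size^3 / (2 * pi * sig)))
  }
  stopifnot(dt > 0)
  dt
}

# Parameter list handed to the C++ kernels. The implant contact angle is
# replaced by its Wenzel-effective value when the phase runs in effective
# wetting mode.
solver_par <- function(grid, props, bc, settings, wetting_mode = "explicit_contact_angle",
                       roughness_ratio = 1) {
  theta_imp <- bc$contact_angle_theta
  if (identical(wetting_mode, "wenzel_effective")) {
    theta_imp <- effective_contact_angle(theta_imp, roughness_ratio)
  }
  list(h = grid$cell_size,
       rho_b = props$rho_blood, mu_b = props$mu_blood,
       rho_g = props$rho_air, mu_g = props$mu_air,
       sigma = props$sigma * settings$sigma_scale,
       theta_imp = theta_imp * pi / 180,
       theta_bone = bc$contact_angle_bone * pi / 180,
       inlet_speed = bc$inlet_speed,
       Y0 = inlet_mass_fraction(3, props$rho_serum),
       p_tol = settings$pressure_tolerance,
       p_maxit = settings$pressure_maxit,
       smooth_passes = settings$curvature_smoothing,
       pressure_inlet = identical(bc$inlet_type, "pressure"),
       p_inlet = bc$inlet_pressure)
}

# Near-wall momentum sink (1/s) in the first fluid layer along the implant,
# used by the Wenzel-effective roughness mode. Porous-layer estimate: the
# texture acts as a Darcy layer of permeability (a_mean/2)^2 and thickness
# a_mean, rescaled to the cell size h:
# lambda = 4 mu_b / (rho_b * a_mean * h).
sink_matrix <- function(grid, props, roughness = NULL,
                        wetting_mode = "explicit_contact_angle") {
  sink <- matrix(0, grid$nx, grid$ny)
  if (!identical(wetting_mode, "wenzel_effective") || is.null(roughness)) {
    return(sink)
  }
  a_mean <- (roughness$amplitude_min + roughness$amplitude_max) / 2
  if (a_mean <= 0) return(sink)
  lam <- 4 * props$mu_blood / (props$rho_blood * a_mean * grid$cell_size)
  imp <- grid$cell_class == CLASS_IMPLANT
  layer <- (shift_mat(imp, 1, 0) | shift_mat(imp, -1, 0) |
            shift_mat(imp, 0, 1) | shift_mat(imp, 0, -1)) &
           grid$cell_class == CLASS_FLUID
  sink[layer] <- lam
  sink
}

#' Advance the flow field one time step
#'
#' Explicit upwind advection and diffusion of momentum with variable
#' density/viscosity mixed by the phase field, addition of the
#' surface-tension body force, and projection to a discretely
#' divergence-free field. No-slip, inlet, and outflow conditions are
#' enforced.
#'
#' @param state [flow_state()].
#' @param phase [phase_field()].
#' @param props,bc,settings Property, boundary, and solver objects.
#' @param grid The domain grid.
#' @param body_force Optional list with face force matrices `Fx`, `Fy`
#'   (N/m^3); computed from the phase field via [surface_tension_force()]
#'   when omitted.
#' @param dt Time step (s); the stability-limited step when omitted.
#' @param sink Optional per-cell momentum sink matrix (1/s).
#' @return Updated `flow_state`, with attributes `iterations`, `residual`,
#'   and `max_divergence` of the pressure solve.
#' @export
step_flow <- function(state, phase, props, bc, settings, grid,
                      body_force = NULL, dt = NULL, sink = NULL) {
  par <- solver_par(grid, props, bc, settings, phase$wetting_mode,
                    phase$roughness_ratio)
  if (is.null(dt)) dt <- cpp_stable_dt(state$u, state$v, par,
                                       settings$dt_reference, settings$cfl_cap)
  if (is.null(body_force)) {
    body_force <- if (par$sigma > 0) {
      cf <- cpp_curvature_force(phase$alpha, grid$cell_class, par)
      list(Fx = cf$Fx, Fy = cf$Fy)
    } else {
      list(Fx = matrix(0, grid$nx + 1, grid$ny),
           Fy = matrix(0, grid$nx, grid$ny + 1))
    }
  }
  if (is.null(sink)) sink <- matrix(0, grid$nx, grid$ny)
  out <- cpp_step_flow(state$u, state$v, state$p, phase$alpha,
                       grid$cell_class, sink, par, dt,
                       body_force$Fx, body_force$Fy)
  if (out$iterations >= settings$pressure_maxit && out$residual > 0.1) {
    stop("pressure solve failed to converge: relative residual ",
         signif(out$residual, 3))
  }
  new_state <- structure(list(u = out$u, v = out$v, p = out$p,
                              time = state$time + dt,
                              step = state$step + 1L),
                         class = "flow_state")
  attr(new_state, "iterations") <- out$iterations
  attr(new_state, "residual") <- out$residual
  attr(new_state, "max_divergence") <- out$max_divergence
  new_state
}

#' Cell-centered speed magnitude
#'
#' @param state [flow_state()].
#' @return `nx x ny` matrix of |u| at cell centers (m/s).
#' @export
cell_speed <- function(state) {
  u <- state$u; v <- state$v
  nx <- nrow(u) - 1L; ny <- ncol(u)
  uc <- (u[1:nx, , drop = FALSE] + u[2:(nx + 1), , drop = FALSE]) / 2
  vc <- (v[, 1:ny, drop = FALSE] + v[, 2:(ny + 1), drop = FALSE]) / 2
  sqrt(uc^2 + vc^2)
}
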