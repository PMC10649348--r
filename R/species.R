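# Fibrinogen transport within the blood phase.

#' Inlet fibrinogen mass fraction
#'
#' The physiological inlet composition: normal adult fibrinogen
#' concentration (300 mg/dL = 3 kg/m^3) divided by the blood serum density
#' (1024 kg/m^3), giving 0.29%.
#'
#' @param concentration Fibrinogen concentration (kg/m^3).
#' @param rho_serum Serum density (kg/m^3).
#' @return Dimensionless mass fraction.
#' @examples
#' inlet_mass_fraction(3, 1024)  # 0.0029...
#' @export
inlet_mass_fraction <- function(concentration = 3, rho_serum = 1024) {
  stopifnot(concentration >= 0, rho_serum > 0)
  concentration / rho_serum
}

#' Fibrinogen species field
#'
#' Internally the conserved load `C = alpha * Y` is stored (so fibrinogen
#' exists only within blood); the mass fraction `Y` is recovered per cell as
#' `C / alpha` via [species_Y()].
#'
#' @param grid A [rasterize_domain()] grid.
#' @param phase The [phase_field()] providing the initial blood
#'   distribution; where blood is present initially, `Y` is set to 0 unless
#'   `initial_Y0` is `TRUE`.
#' @param D Fibrinogen diffusivity in blood (m^2/s); macromolecule-scale
#'   default.
#' @param Y0 Inlet mass fraction; physiological default from
#'   [inlet_mass_fraction()].
#' @param initial_Y0 Fill initially present blood with `Y0`?
#' @param wall_uptake First-order uptake rate (1/s) applied to fibrinogen in
#'   the fluid layer touching the implant wall; 0 (off) by default and
#'   excluded from all reported study runs.
#' @return Object of class `species_field`.
#' @export
species_field <- function(grid, phase, D = 2e-11,
                          Y0 = inlet_mass_fraction(), initial_Y0 = FALSE,
                          wall_uptake = 0) {
  stopifnot(D >= 0, Y0 >= 0, Y0 <= 1, wall_uptake >= 0)
  C <- matrix(0, grid$nx, grid$ny)
  if (initial_Y0) C <- phase$alpha * Y0
  cls <- grid$cell_class
  C[cls == CLASS_INLET_APEX | cls == CLASS_INLET_BONE] <- Y0
  C[is_solid_class(cls)] <- 0
  structure(list(C = C, D = D, Y0 = Y0, wall_uptake = wall_uptake),
            class = "species_field")
}

#' Fibrinogen mass fraction per cell
#'
#' @param species [species_field()].
#' @param phase [phase_field()].
#' @param eps Phase floor below which `Y` is reported as 0.
#' @return Matrix of `Y` (dimensionless).
#' @export
species_Y <- function(species, phase, eps = 1e-10) {
  Y <- matrix(0, nrow(species$C), ncol(species$C))
  wet <- phase$alpha > eps
  Y[wet] <- species$C[wet] / phase$alpha[wet]
  Y
}

#' Advect and diffuse the fibrinogen field
#'
#' Phase-weighted conservative advection — fibrinogen is carried only by
#' blood-phase fluxes, using the same donor-acceptor face fluxes as the
#' volume fraction — followed by explicit diffusion within blood. Inlet
#' cells are held at `Y0`; the outlet is zero-gradient; walls and the
#' blood-air interface are zero-flux.
#'
#' @param species [species_field()].
#' @param phase [phase_field()] at the start of the step.
#' @param state [flow_state()] with a divergence-free velocity.
#' @param grid,props,bc,settings Domain and parameter objects.
#' @param dt Time step (s).
#' @return Updated `species_field` with attribute `"budget"` (inlet/outlet
#'   fibrinogen volume-load fluxes) and attribute `"alpha"` (the phase
#'   matrix advanced consistently with the species fluxes).
#' @export
advect_diffuse_species <- function(species, phase, state, grid, props, bc,
                                   settings, dt) {
  par <- solver_par(grid, props, bc, settings, phase$wetting_mode,
                    phase$roughness_ratio)
  par$Y0 <- species$Y0
  out <- cpp_advect_vof(phase$alpha, species$C, state$u, state$v,
                        grid$cell_class, par, dt)
  C <- cpp_diffuse_species(out$C, out$alpha, grid$cell_class, par,
                           species$D, dt)
  if (!is.null(species$wall_uptake) && species$wall_uptake > 0) {
    imp <- grid$cell_class == CLASS_IMPLANT
    layer <- (shift_mat(imp, 1, 0) | shift_mat(imp, -1, 0) |
              shift_mat(imp, 0, 1) | shift_mat(imp, 0, -1)) &
             grid$cell_class == CLASS_FLUID
    C[layer] <- C[layer] / (1 + species$wall_uptake * dt)
  }
  if (min(C) < -1e-12) stop("negative fibrinogen load beyond tolerance: limiter defect")
  new_species <- species
  new_species$C <- C
  attr(new_species, "budget") <- c(C_in = out$C_in, C_out = out$C_out)
  attr(new_species, "alpha") <- out$alpha
  new_species
}

#' Total fibrinogen mass in the domain
#'
#' `sum(alpha * rho_blood * Y * cell_area)` over all cells, i.e.
#' `rho_blood * sum(C) * h^2`.
#'
#' @param species [species_field()].
#' @param grid Domain grid.
#' @param props [fluid_properties()].
#' @param where Optional logical matrix restricting the sum.
#' @return Mass (kg per unit depth).
#' @export
total_fibrinogen_mass <- function(species, grid, props, where = NULL) {
  C <- species$C
  cls <- grid$cell_class
  interior <- !is_solid_class(cls) & cls != CLASS_INLET_APEX &
    cls != CLASS_INLET_BONE
  C <- C * interior
  if (!is.null(where)) C <- C * where
  props$rho_blood * sum(C) * grid$cell_size^2
}
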