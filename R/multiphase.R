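# Volume-of-fluid interface tracking, surface tension, and wall wetting.

#' Phase (volume-of-fluid) field
#'
#' Tracks the blood volume fraction `alpha` per cell. The gap starts filled
#' with air by default (blood enters from the apical and bone inlets at
#' t = 0); an initially-filled variant is available. Wetting is imposed
#' either as an explicit contact angle at the resolved wall, or through the
#' Wenzel-effective mode where the roughness ratio of the microtopography
#' amplifies the intrinsic wetting and a near-wall momentum sink represents
#' flow retardation by the unresolved texture.
#'
#' @param grid A [rasterize_domain()] grid.
#' @param initial_fill `"air"` (default) or `"blood"`.
#' @param wetting_mode `"explicit_contact_angle"` or `"wenzel_effective"`.
#' @param roughness_ratio Wenzel ratio `r >= 1` used by the effective mode
#'   (see [roughness_ratio_physical()]).
#' @return Object of class `phase_field`.
#' @export
phase_field <- function(grid, initial_fill = c("air", "blood"),
                        wetting_mode = c("explicit_contact_angle", "wenzel_effective"),
                        roughness_ratio = 1) {
  initial_fill <- match.arg(initial_fill)
  wetting_mode <- match.arg(wetting_mode)
  stopifnot(roughness_ratio >= 1)
  cls <- grid$cell_class
  alpha <- matrix(0, grid$nx, grid$ny)
  if (initial_fill == "blood") alpha[!is_solid_class(cls)] <- 1
  alpha[cls == CLASS_INLET_APEX | cls == CLASS_INLET_BONE] <- 1
  alpha[is_solid_class(cls)] <- 0
  structure(list(alpha = alpha, wetting_mode = wetting_mode,
                 roughness_ratio = roughness_ratio),
            class = "phase_field")
}

#' Advect the phase field
#'
#' Donor-acceptor (orientation-switched, compressive) transport of the
#' blood volume fraction under a divergence-free velocity field, with flux
#' limiting enforcing boundedness; inlet cells are held at `alpha = 1`.
#' A species field may ride along: its load is carried by the same phase
#' fluxes so fibrinogen moves only with blood.
#'
#' @param phase [phase_field()].
#' @param state [flow_state()] with a projected (divergence-free) field.
#' @param grid,props,bc,settings Domain and parameter objects.
#' @param dt Time step (s); must satisfy the CFL condition.
#' @param species Optional [species_field()] advected with the phase.
#' @return Updated `phase_field`; when `species` is given the updated
#'   species field is attached as attribute `"species"`. Boundary-flux
#'   bookkeeping (inflow/outflow volume and fibrinogen load) is attached
#'   as attribute `"budget"`.
#' @export
advect_vof <- function(phase, state, grid, props, bc, settings, dt,
                       species = NULL) {
  par <- solver_par(grid, props, bc, settings, phase$wetting_mode,
                    phase$roughness_ratio)
  C <- if (is.null(species)) matrix(0, grid$nx, grid$ny) else species$C
  out <- cpp_advect_vof(phase$alpha, C, state$u, state$v,
                        grid$cell_class, par, dt)
  new_phase <- phase
  new_phase$alpha <- out$alpha
  attr(new_phase, "budget") <- c(alpha_in = out$alpha_in, alpha_out = out$alpha_out,
                                 C_in = out$C_in, C_out = out$C_out)
  if (!is.null(species)) {
    species$C <- out$C
    attr(new_phase, "species") <- species
  }
  new_phase
}

#' Surface-tension body force (continuum surface force)
#'
#' Curvature is evaluated from smoothed volume-fraction normals; in
#' wall-adjacent interface cells the normal is re-oriented to satisfy the
#' imposed contact angle (explicit mode) or its Wenzel-corrected value
#' (effective mode). The force density is `sigma * kappa * grad(alpha)`
#' evaluated on faces.
#'
#' @param phase [phase_field()].
#' @param props,bc,settings Parameter objects (`sigma >= 0` enforced).
#' @param grid Domain grid.
#' @param theta Implant contact angle (degrees); defaults to the boundary
#'   condition value.
#' @return List with `Fx` (`(nx+1) x ny`), `Fy` (`nx x (ny+1)`) face force
#'   densities (N/m^3) and the cell curvature matrix `kappa` (1/m).
#' @export
surface_tension_force <- function(phase, props, bc, settings, grid,
                                  theta = NULL) {
  if (props$sigma < 0) stop("sigma must be non-negative")
  if (!is.null(theta)) {
    bc$contact_angle_theta <- theta
  }
  par <- solver_par(grid, props, bc, settings, phase$wetting_mode,
                    phase$roughness_ratio)
  cpp_curvature_force(phase$alpha, grid$cell_class, par)
}

#' Wenzel-effective contact angle
#'
#' `theta_eff = arccos(clamp(r cos(theta), -1, 1))`: surface roughness of
#' ratio `r` amplifies the intrinsic wetting.
#'
#' @param theta Intrinsic contact angle (degrees, 0..180).
#' @param roughness_ratio Wenzel ratio `r >= 1`.
#' @return Effective contact angle (degrees).
#' @export
effective_contact_angle <- function(theta, roughness_ratio) {
  stopifnot(roughness_ratio >= 1, theta >= 0, theta <= 180)
  c_eff <- pmin(pmax(roughness_ratio * cos(theta * pi / 180), -1), 1)
  acos(c_eff) * 180 / pi
}

#' Total blood volume of the phase field
#'
#' @param phase [phase_field()].
#' @param grid Domain grid.
#' @param where Optional logical matrix restricting the sum.
#' @return Blood volume (m^2 per unit depth).
#' @export
blood_volume <- function(phase, grid, where = NULL) {
  a <- phase$alpha
  if (!is.null(where)) a <- a * where
  sum(a) * grid$cell_size^2
}

#' Extract interface points at the alpha = 0.5 level
#'
#' Linear interpolation along grid lines; used by the droplet fixtures to
#' fit circles to the interface.
#'
#' @param alpha Volume fraction matrix.
#' @param cell_size Grid spacing (m).
#' @param level Contour level.
#' @return Tibble of interface point coordinates `x`, `y` (m).
#' @export
interface_points <- function(alpha, cell_size, level = 0.5) {
  nx <- nrow(alpha); ny <- ncol(alpha)
  xs <- (seq_len(nx) - 0.5) * cell_size
  ys <- (seq_len(ny) - 0.5) * cell_size
  px <- numeric(0); py <- numeric(0)
  for (j in seq_len(ny)) {
    a <- alpha[, j]
    cross <- which((a[-nx] - level) * (a[-1] - level) < 0)
    for (i in cross) {
      t <- (level - a[i]) / (a[i + 1] - a[i])
      px <- c(px, xs[i] + t * cell_size); py <- c(py, ys[j])
    }
  }
  for (i in seq_len(nx)) {
    a <- alpha[i, ]
    cross <- which((a[-ny] - level) * (a[-1] - level) < 0)
    for (j in cross) {
      t <- (level - a[j]) / (a[j + 1] - a[j])
      px <- c(px, xs[i]); py <- c(py, ys[j] + t * cell_size)
    }
  }
  tibble::tibble(x = px, y = py)
}

#' Least-squares circle fit (Kasa method)
#'
#' @param x,y Point coordinates.
#' @return List with `xc`, `yc`, `R`.
#' @export
fit_circle <- function(x, y) {
  stopifnot(length(x) >= 3)
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- qr.solve(A, b)
  list(xc = sol[1], yc = sol[2],
       R = sqrt(max(sol[3] + sol[1]^2 + sol[2]^2, 0)))
}
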