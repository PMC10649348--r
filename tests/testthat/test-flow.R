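# Laminar projection solver: analytic profile, stability, conservation.

test_that("Reynolds number follows its definition and the laminar regime holds", {
  props <- fluid_properties()
  expect_equal(reynolds_number(props, boundary_conditions(inlet_speed = 0), 8e-4), 0)
  Re <- reynolds_number(props, boundary_conditions(), 8e-4)
  expect_equal(Re, 1060 * 0.001 * 8e-4 / 3.5e-3, tolerance = 1e-12)
  expect_equal(Re, 0.2423, tolerance = 1e-3)
  expect_lt(Re, 2800)
})

test_that("stability-limited time step follows the stated minima", {
  grid <- channel_grid(8L, 8L, 5e-5)
  st <- flow_state(grid)
  props <- fluid_properties(sigma = 0)
  settings <- solver_settings()
  # zero velocity, sigma = 0: the reference step
  expect_equal(adaptive_dt(st, settings, props, 5e-5), 1e-4)
  # CFL term above the reference step does not bind
  st$u[2, 2] <- 0.01
  expect_equal(adaptive_dt(st, settings, props, 5e-5),
               min(1e-4, 0.4 * 5e-5 / 0.01))
  # capillary limit governs with full surface tension
  props2 <- fluid_properties(sigma = 0.058)
  dt <- adaptive_dt(flow_state(grid), settings, props2, 5e-5)
  expect_equal(dt, sqrt(1060 * (5e-5)^3 / (2 * pi * 0.058)), tolerance = 1e-9)
  expect_equal(dt, 1.9e-5, tolerance = 0.05)
})

test_that("zero inlet, zero force leaves the velocity identically zero", {
  grid <- channel_grid(8L, 12L, 1e-4)
  props <- fluid_properties(sigma = 0)
  bc <- boundary_conditions(inlet_speed = 0)
  phase <- phase_field(grid, initial_fill = "blood")
  st <- flow_state(grid)
  for (k in 1:5) {
    st <- step_flow(st, phase, props, bc, solver_settings(), grid)
  }
  expect_equal(max(abs(st$u)), 0)
  expect_equal(max(abs(st$v)), 0)
})

test_that("developed channel flow reaches the plane-Poiseuille profile", {
  rp <- run_poiseuille(make_poiseuille())
  expect_rel_equal(rp$ratio, 1.5, 0.02)
  # discrete divergence invariant after projection (velocity-scaled)
  grid <- rp$sim$grid
  scaled_div <- rp$sim$diag$max_divergence * grid$cell_size / 1e-3
  expect_lt(scaled_div, 1e-8)
})

test_that("grid refinement reduces the Poiseuille profile error", {
  e <- vapply(c(7L, 15L), function(n) {
    run_poiseuille(make_poiseuille(n_across = n))$rel_error
  }, numeric(1))
  expect_lt(e[2], e[1])
  # observed order of accuracy at least one
  expect_gt(log2(e[1] / e[2]), 1)
})

test_that("kinetic energy decays in an unforced closed box", {
  grid <- box_grid(24L, 24L, 1e-4)
  props <- fluid_properties(sigma = 0)
  bc <- boundary_conditions(inlet_speed = 0)
  phase <- phase_field(grid, initial_fill = "blood")
  sim <- new_simulation(grid, props, bc, solver_settings(), phase,
                        species_field(grid, phase))
  sim$state <- vortex_state(grid, strength = 2e-7)
  ke <- function(s) sum(s$u^2) + sum(s$v^2)
  k0 <- ke(sim$state)
  ks <- numeric(5)
  for (i in 1:5) {
    sim <- advance_simulation(sim, sim$state$time + 2e-3)
    ks[i] <- ke(sim$state)
  }
  expect_true(all(diff(c(k0, ks)) <= 1e-12 * k0))
  expect_lt(ks[5], k0)
})

test_that("the solver trajectory is deterministic", {
  run_once <- function() {
    po <- make_poiseuille(n_across = 9L)
    sim <- new_simulation(po$grid, po$props, po$bc, po$settings, po$phase,
                          po$species)
    sim <- advance_simulation(sim, 5e-3)
    list(u = sim$state$u, v = sim$state$v, p = sim$state$p)
  }
  a <- run_once(); b <- run_once()
  expect_identical(a$u, b$u)
  expect_identical(a$v, b$v)
  expect_identical(a$p, b$p)
})

test_that("global volume balance closes against boundary fluxes", {
  po <- make_poiseuille(n_across = 9L)
  sim <- new_simulation(po$grid, po$props, po$bc, po$settings, po$phase,
                        po$species)
  sim <- advance_simulation(sim, 0.05)
  b <- budget_report(sim)
  # domain starts full: net in minus out stays near zero, and the
  # fibrinogen budget closes within 0.5%
  expect_lt(abs(b$volume_in - b$volume_out) / b$volume_in, 0.005)
  expect_lt(b$fibrinogen_closure_error, 0.005)
})

test_that("a failed pressure solve raises an error with diagnostics", {
  po <- make_poiseuille(n_across = 9L)
  set <- po$settings
  set$pressure_maxit <- 1L
  set$pressure_tolerance <- 1e-14
  st <- flow_state(po$grid)
  expect_error(
    step_flow(st, po$phase, po$props, po$bc, set, po$grid),
    "pressure solve")
})
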