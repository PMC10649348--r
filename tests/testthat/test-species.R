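# Fibrinogen inlet composition, transport, conservation, extrema.

test_that("the inlet mass fraction is the physiological concentration ratio", {
  expect_equal(inlet_mass_fraction(3, 1024), 3 / 1024)
  expect_lt(abs(100 * inlet_mass_fraction(3, 1024) - 0.29), 0.005)
  expect_equal(inlet_mass_fraction(0, 1024), 0)
  expect_equal(inlet_mass_fraction(1024, 1024), 1)
  expect_error(inlet_mass_fraction(3, 0))
})

test_that("fibrinogen exists only inside blood", {
  grid <- test_grid()
  phase <- phase_field(grid)           # gap starts as air
  species <- species_field(grid, phase)
  Y <- species_Y(species, phase)
  expect_true(all(Y[phase$alpha == 0] == 0))
  sim <- new_simulation(grid, fluid_properties(rho_air = 10),
                        boundary_conditions(),
                        solver_settings(sigma_scale = 0.02), phase, species)
  sim <- advance_simulation(sim, 0.02)
  Y <- species_Y(sim$species, sim$phase)
  expect_true(all(Y[sim$phase$alpha < 1e-10] == 0))
  expect_true(all(Y >= -1e-12))
  expect_lte(max(Y), sim$species$Y0 * (1 + 1e-6))
})

test_that("pure advection conserves the fibrinogen load exactly", {
  grid <- box_grid(40L, 20L, 1e-4)
  phase <- phase_field(grid, initial_fill = "blood")
  species <- species_field(grid, phase, D = 0)
  blob <- implantflow:::disc_alpha(grid, 1.2e-3, 1.1e-3, 5e-4)
  species$C <- blob * 0.0029
  c0 <- sum(species$C)
  st <- translation_state(grid, ux = 5e-3)
  props <- fluid_properties(sigma = 0)
  bc <- boundary_conditions(inlet_speed = 0)
  sp <- species
  ph <- phase
  for (k in 1:200) {
    sp <- advect_diffuse_species(sp, ph, st, grid, props, bc,
                                 solver_settings(), 1e-4)
    ph$alpha <- attr(sp, "alpha")
  }
  expect_rel_equal(sum(sp$C), c0, 1e-10)
})

test_that("diffusion spreads a Gaussian with variance 2 D t", {
  grid <- box_grid(60L, 9L, 1e-4)
  phase <- phase_field(grid, initial_fill = "blood")
  D <- 1e-6
  species <- species_field(grid, phase, D = D)
  h <- grid$cell_size
  xc <- (seq_len(grid$nx) - 0.5) * h
  s0 <- 4e-4
  x0 <- grid$width / 2
  prof <- exp(-(xc - x0)^2 / (2 * s0^2))
  species$C <- matrix(prof, grid$nx, grid$ny) * 1e-3
  species$C[implantflow:::is_solid_class(grid$cell_class)] <- 0
  st <- flow_state(grid)   # no flow
  props <- fluid_properties(sigma = 0)
  bc <- boundary_conditions(inlet_speed = 0)
  variance <- function(C) {
    m <- rowSums(C)
    mu <- sum(xc * m) / sum(m)
    sum((xc - mu)^2 * m) / sum(m)
  }
  v0 <- variance(species$C)
  t_end <- 0.04; dt <- 1e-4
  sp <- species
  for (k in seq_len(t_end / dt)) {
    sp <- advect_diffuse_species(sp, phase, st, grid, props, bc,
                                 solver_settings(), dt)
  }
  expect_rel_equal(variance(sp$C) - v0, 2 * D * t_end, 0.03)
})

test_that("a channel held at the inlet composition stays at Y0", {
  po <- make_poiseuille(n_across = 9L)
  phase <- phase_field(po$grid, initial_fill = "blood")
  species <- species_field(po$grid, phase, initial_Y0 = TRUE)
  sim <- new_simulation(po$grid, po$props, po$bc, po$settings, phase, species)
  sim <- advance_simulation(sim, 0.05)
  Y <- species_Y(sim$species, sim$phase)
  blood <- sim$phase$alpha > 0.5 & po$grid$cell_class == 0L
  expect_true(all(abs(Y[blood] - 0.0029296875) < 1e-6))
})

test_that("an inflow-fed channel flushes toward the inlet composition", {
  po <- make_poiseuille(n_across = 9L, U_mean = 5e-3)
  phase <- phase_field(po$grid, initial_fill = "blood")
  species <- species_field(po$grid, phase)   # starts fibrinogen-free
  sim <- new_simulation(po$grid, po$props, po$bc, po$settings, phase, species)
  mids <- integer(0)
  centre <- ceiling(po$grid$nx / 2)
  ys <- numeric(0)
  for (tt in c(0.05, 0.1, 0.2)) {
    sim <- advance_simulation(sim, tt)
    Y <- species_Y(sim$species, sim$phase)
    ys <- c(ys, Y[centre, 3])
  }
  expect_true(all(diff(ys) >= -1e-12))
  expect_gt(tail(ys, 1), 0.9 * sim$species$Y0)
})

test_that("without sources the extrema of Y contract", {
  grid <- box_grid(30L, 30L, 1e-4)
  phase <- phase_field(grid, initial_fill = "blood")
  species <- species_field(grid, phase, D = 1e-7)
  blob <- implantflow:::disc_alpha(grid, 1.5e-3, 1.5e-3, 6e-4)
  species$C <- blob * 0.0029
  st <- vortex_state(grid, strength = 2e-6)
  props <- fluid_properties(sigma = 0)
  bc <- boundary_conditions(inlet_speed = 0)
  sp <- species; ph <- phase
  mx <- max(sp$C); mn <- min(sp$C)
  for (k in 1:100) {
    sp <- advect_diffuse_species(sp, ph, st, grid, props, bc,
                                 solver_settings(), 5e-4)
    ph$alpha <- attr(sp, "alpha")
    expect_lte(max(sp$C), mx + 1e-12)
    expect_gte(min(sp$C), mn - 1e-12)
    mx <- max(sp$C); mn <- min(sp$C)
  }
})

test_that("the domain fibrinogen budget closes against boundary fluxes", {
  cfg <- quick_config(t_end = 0.1)
  res <- run_scenario(cfg)
  expect_lt(res$budget$fibrinogen_closure_error, 0.005)
  expect_lt(res$budget$volume_closure_error, 0.005)
})
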