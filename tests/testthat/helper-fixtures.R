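# Shared small fixtures for fast tests.

test_geometry <- function() implant_geometry()

# coarse grid of the default implant (test preset resolution)
test_grid <- function(cell_size = 1e-4) {
  geo <- test_geometry()
  rasterize_domain(build_implant_profile(geo), geo, cell_size)
}

# quick scenario config on the coarse preset with a short horizon
quick_config <- function(surface = "smooth", theta = 70, t_end = 0.05, ...) {
  scenario_config(surface = surface, theta = theta, resolution = "test",
                  settings = solver_settings(t_end = t_end, sigma_scale = 0.02),
                  output_every = t_end / 2, ...)
}

# uniform divergence-free translation state far from boundaries
translation_state <- function(grid, ux = 0, vy = 0) {
  st <- flow_state(grid)
  st$u[] <- ux
  st$v[] <- vy
  st
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-300), tol)
}
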