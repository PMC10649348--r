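# Zone statistics: masses, speeds, ratios, index, fold changes.

make_masked_grid <- function() {
  grid <- test_grid()
  list(grid = grid, mask = compute_zone_masks(grid, delta = grid$cell_size))
}

test_that("zone fibrinogen mass follows its definition", {
  mg <- make_masked_grid()
  grid <- mg$grid; mask <- mg$mask
  n0 <- matrix(0, grid$nx, grid$ny)
  # no fibrinogen, no mass
  m0 <- zone_fibrinogen_mass(n0 + 1, n0, 1060, mask, grid$cell_size)
  expect_true(all(m0$mass == 0))
  # uniform fill: masses proportional to zone areas
  Y0 <- 0.0029
  m1 <- zone_fibrinogen_mass(n0 + 1, n0 + Y0, 1060, mask, grid$cell_size)
  za <- zone_areas(mask, grid)
  for (z in c("interface", "thread", "outer")) {
    expect_equal(m1$mass[m1$zone == z],
                 1060 * Y0 * za$area[za$zone == z], tolerance = 1e-12)
  }
  # checkerboard alpha against a direct hand summation
  chk <- matrix(rep_len(c(1, 0), grid$nx * grid$ny), grid$nx, grid$ny)
  m2 <- zone_fibrinogen_mass(chk, n0 + Y0, 1060, mask, grid$cell_size)
  hand <- sum(chk[mask$zone == 2L]) * Y0 * 1060 * grid$cell_size^2
  expect_equal(m2$mass[m2$zone == "thread"], hand, tolerance = 1e-12)
  # shape mismatch is an error
  expect_error(zone_fibrinogen_mass(chk[, -1], n0 + Y0, 1060, mask,
                                    grid$cell_size), "match")
})

test_that("uniform fill reproduces the quarter thread-to-outer mass ratio", {
  geo <- test_geometry()
  grid <- rasterize_domain(build_implant_profile(geo), geo, 2e-5)
  mask <- compute_zone_masks(grid, delta = 2e-5)
  n1 <- matrix(1, grid$nx, grid$ny)
  m <- zone_fibrinogen_mass(n1, n1 * 0.0029, 1060, mask, grid$cell_size)
  ratio <- m$mass[m$zone == "thread"] / m$mass[m$zone == "outer"]
  expect_gte(ratio, 0.20)
  expect_lte(ratio, 0.30)
})

test_that("zone mean speed averages the cell speeds of blood cells", {
  mg <- make_masked_grid()
  grid <- mg$grid; mask <- mg$mask
  st <- flow_state(grid)
  alpha <- matrix(1, grid$nx, grid$ny)
  # all-zero velocity
  v0 <- zone_mean_speed(st, alpha, mask)
  expect_true(all(v0$mean_speed == 0))
  # uniform vertical speed
  st$v[] <- 3e-3
  v1 <- zone_mean_speed(st, alpha, mask)
  expect_true(all(abs(v1$mean_speed - 3e-3) < 1e-12))
  # empty zones report zero and a flag
  v2 <- zone_mean_speed(st, alpha * 0, mask)
  expect_true(all(v2$mean_speed == 0))
  expect_true(all(v2$empty))
})

test_that("band means of a parabolic profile match analytic averages", {
  n <- 32L
  grid <- channel_grid(n, 8L, 1e-4)
  fluid_cols <- 2:(n + 1)
  half <- n / 2 * 1e-4
  xc <- ((fluid_cols - 1) - 0.5) * 1e-4 - half   # centered coordinates
  st <- flow_state(grid)
  umax <- 1e-3
  prof <- umax * (1 - (xc / half)^2)
  for (k in seq_along(fluid_cols)) {
    st$v[fluid_cols[k], ] <- prof[k]
  }
  zone <- matrix(0L, grid$nx, grid$ny)
  zone[fluid_cols[xc < 0], ] <- 2L   # thread: inner half
  zone[fluid_cols[xc >= 0], ] <- 3L  # outer: outer half
  mask <- structure(list(zone = zone, delta = 0, cell_size = 1e-4),
                    class = "zone_mask")
  v <- zone_mean_speed(st, matrix(1, grid$nx, grid$ny), mask)
  # analytic band average of umax (1 - (x/h)^2) over half the channel: 2/3 umax
  expect_rel_equal(v$mean_speed[v$zone == "thread"], 2 / 3 * umax, 0.01)
  expect_rel_equal(v$mean_speed[v$zone == "outer"], 2 / 3 * umax, 0.01)
})

test_that("infiltration ratio reproduces its defining arithmetic", {
  expect_equal(infiltration_ratio(1.7e-6, 1.7e-6), 100)
  expect_equal(infiltration_ratio(0, 2e-6), 0)
  expect_equal(infiltration_ratio(0.23, 1.0), 23)
  und <- infiltration_ratio(1e-9, 0)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
})

test_that("the recruitment/retention index is linear with a velocity floor", {
  expect_equal(recruitment_retention_index(2e-9, 4e-5), 5e-5)
  expect_equal(recruitment_retention_index(4e-9, 4e-5),
               2 * recruitment_retention_index(2e-9, 4e-5))
  fl <- recruitment_retention_index(1e-9, 1e-12, epsilon_v = 1e-9)
  expect_equal(as.numeric(fl), 1e-9 / 1e-9)
  expect_true(attr(fl, "floored"))
})

test_that("synthetic zone snapshots reproduce their direct-arithmetic stats", {
  mg <- make_masked_grid()
  snap <- make_zone_snapshot(mg$mask, mg$grid,
                             alpha = c(1, 0.5, 1), Y = c(0.003, 0.001, 0.002),
                             speed = c(1e-5, 5e-5, 2e-4), rho_blood = 1060)
  got <- zone_snapshot_stats(snap$state, snap$phase, snap$species, mg$mask,
                             mg$grid, fluid_properties())
  for (z in c("interface", "thread", "outer")) {
    expect_equal(got$mass[got$zone == z],
                 snap$expected$mass[snap$expected$zone == z], tolerance = 1e-12)
    expect_equal(got$blood_volume[got$zone == z],
                 snap$expected$blood_volume[snap$expected$zone == z],
                 tolerance = 1e-12)
    expect_equal(got$mean_speed[got$zone == z],
                 snap$expected$mean_speed[snap$expected$zone == z],
                 tolerance = 1e-12)
  }
  # all-zero snapshot
  zs <- make_zone_snapshot(mg$mask, mg$grid, alpha = 0, Y = 0, speed = 0)
  expect_true(all(zs$expected$mass == 0))
  # uniform conditions: I_z = rho Y0 area_z / speed exactly
  Y0 <- 0.0029
  us <- make_zone_snapshot(mg$mask, mg$grid, alpha = 1, Y = Y0, speed = 1e-4)
  za <- zone_areas(mg$mask, mg$grid)
  got_u <- zone_snapshot_stats(us$state, us$phase, us$species, mg$mask,
                               mg$grid, fluid_properties())
  idx <- recruitment_retention_index(got_u$mass, got_u$mean_speed)
  for (z in c("interface", "thread", "outer")) {
    expect_rel_equal(idx[got_u$zone == z],
                     1060 * Y0 * za$area[za$zone == z] / 1e-4, 1e-9)
  }
  # two-zone contrast in Y scales mass by concentration times area
  cs <- make_zone_snapshot(mg$mask, mg$grid, alpha = 1,
                           Y = c(0.002, 0.002, 0.001), speed = 1e-4)
  gc <- zone_snapshot_stats(cs$state, cs$phase, cs$species, mg$mask, mg$grid,
                            fluid_properties())
  a_t <- za$area[za$zone == "thread"]; a_o <- za$area[za$zone == "outer"]
  expect_rel_equal(gc$mass[gc$zone == "thread"] / gc$mass[gc$zone == "outer"],
                   2 * a_t / a_o, 1e-9)
})

test_that("zone masses are additive against the domain total", {
  mg <- make_masked_grid()
  grid <- mg$grid
  set.seed(7)
  alpha <- matrix(runif(grid$nx * grid$ny), grid$nx, grid$ny)
  Y <- matrix(runif(grid$nx * grid$ny, 0, 0.003), grid$nx, grid$ny)
  sol <- implantflow:::is_solid_class(grid$cell_class)
  alpha[sol] <- 0; Y[sol] <- 0
  m <- zone_fibrinogen_mass(alpha, Y, 1060, mg$mask, grid$cell_size)
  outside <- mg$mask$zone == 0L
  m_out <- sum((alpha * Y)[outside]) * 1060 * grid$cell_size^2
  total <- sum(alpha * Y) * 1060 * grid$cell_size^2
  expect_rel_equal(sum(m$mass) + m_out, total, 1e-12)
})

test_that("fold-change tables report exact ratios with provenance", {
  mk_series <- function(masses, speeds) {
    tibble::tibble(
      scenario = "x", time = rep(c(1, 2, 3), each = 3),
      zone = rep(c("interface", "thread", "outer"), 3),
      mass = rep(masses, 3), blood_volume = 1,
      mean_speed = rep(speeds, 3), blood_cells = 10L, empty = FALSE)
  }
  a <- mk_series(c(2e-9, 4e-9, 8e-9), c(1e-5, 2e-5, 4e-5))
  b <- mk_series(c(1e-9, 1e-9, 8e-9), c(2e-5, 2e-5, 4e-5))
  same <- fold_change_table(list(s1 = a, s2 = a))
  expect_true(all(abs(
    same$value[same$comparison == "scenario_vs_scenario"] - 1) < 1e-12))
  fc <- fold_change_table(list(s1 = a, s2 = b))
  expect_equal(fold_change(fc, "mass", "interface", "s1", "s2"), 2)
  expect_equal(fold_change(fc, "mean_speed", "interface", "s2", "s1"), 2)
  expect_equal(fold_change(fc, "index", "interface", "s1", "s2"), 4)
  # zone-vs-zone speed ratios within one scenario
  zz <- fc[fc$comparison == "zone_vs_zone" & fc$numerator == "s1" &
             fc$zone == "outer over interface", ]
  expect_equal(zz$value, 4)
  expect_error(fold_change_table(list(a)), "named")
})

test_that("window statistics average mass and speed before forming the index", {
  series <- tibble::tibble(
    scenario = "x", time = rep(1:3, each = 3),
    zone = rep(c("interface", "thread", "outer"), 3),
    mass = c(1, 1, 1, 2, 2, 2, 3, 3, 3) * 1e-9,
    blood_volume = 1,
    mean_speed = c(1, 1, 1, 2, 2, 2, 3, 3, 3) * 1e-5,
    blood_cells = 5L, empty = FALSE)
  ws <- zone_window_stats(series, 1, 3)
  expect_true(all(abs(ws$mass - 2e-9) < 1e-18))
  expect_true(all(abs(ws$index - 2e-9 / 2e-5) < 1e-12))
})
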