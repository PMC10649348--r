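# Implant profile construction, roughness, rasterization, and zone masks.

test_that("smooth profile traces whole symmetric triangular threads", {
  geo <- test_geometry()
  prof <- build_implant_profile(geo)
  tips <- which(prof$x == geo$tip_radius_offset)
  expect_length(tips, geo$threaded_length / geo$thread_pitch)
  # tips sit mid-pitch and reach full thread depth
  r_root <- geo$tip_radius_offset - geo$thread_depth
  expect_equal(prof$y[tips], (seq_along(tips) - 0.5) * geo$thread_pitch)
  expect_equal(min(prof$x[-1]), r_root)
  # simple polyline, monotone in y after the apex face
  expect_false(implantflow:::segments_self_intersect(as.matrix(prof)))
})

test_that("geometry parameter invariants are enforced", {
  expect_error(implant_geometry(thread_depth = 1e-3), "outer_gap_width")
  expect_error(implant_geometry(threaded_length = 8.3e-3), "integer multiple")
  expect_error(implant_geometry(thread_fill_fraction = 0), "strictly")
  expect_error(roughness_spec(amplitude_min = 2e-6, amplitude_max = 1e-6))
  expect_error(roughness_spec(coarsening_factor = 0.5), "coarsening")
})

test_that("zero-amplitude roughness reproduces the smooth profile", {
  geo <- test_geometry()
  rough0 <- roughness_spec(amplitude_min = 0, amplitude_max = 0, seed = 1L)
  prof <- build_implant_profile(geo, rough0)
  sm <- build_implant_profile(geo)
  m <- roughness_metrics(prof, sm)
  expect_equal(m$mean_abs_deviation, 0, tolerance = 1e-12)
  expect_equal(m$roughness_ratio, 1, tolerance = 1e-12)
})

test_that("seeded roughness keeps peak-to-valley excursions in the drawn range", {
  geo <- test_geometry()
  rs <- roughness_spec(amplitude_min = 0.5e-6, amplitude_max = 3.0e-6,
                       coarsening_factor = 20, seed = 42L)
  prof <- build_implant_profile(geo, rs)
  off <- attr(prof, "offsets")$offset
  # local extrema are the sawtooth nodes (+-P/2); consecutive-extremum
  # excursions are (P_i + P_{i+1})/2 with P ~ U[1e-5, 6e-5] after coarsening
  loc <- which(diff(sign(diff(off))) != 0) + 1L
  p2v <- abs(diff(off[loc]))
  p2v <- p2v[p2v > 1e-12]
  expect_gt(length(p2v), 50)
  expect_true(all(p2v >= 1.0e-5 - 1e-12))
  expect_true(all(p2v <= 6.0e-5 + 1e-12))
  m <- roughness_metrics(prof, build_implant_profile(geo))
  expect_lte(m$peak_to_valley_max, 6.0e-5 + 1e-9)
  expect_gt(m$roughness_ratio, 1)
})

test_that("roughness generation is deterministic in the seed", {
  geo <- test_geometry()
  a <- build_implant_profile(geo, roughness_spec(seed = 42L))
  b <- build_implant_profile(geo, roughness_spec(seed = 42L))
  c <- build_implant_profile(geo, roughness_spec(seed = 43L))
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_false(identical(a$x, c$x))
})

test_that("oversized or unresolvable roughness is rejected", {
  geo <- test_geometry()
  big <- roughness_spec(amplitude_min = 3e-4, amplitude_max = 4e-4,
                        feature_width_range = c(1e-4, 2e-4),
                        coarsening_factor = 1, seed = 7L)
  expect_error(build_implant_profile(geo, big), "self-intersecting")
  fine <- roughness_spec(seed = 7L)   # coarsened widths 1e-5..6e-5
  expect_error(build_implant_profile(geo, fine, cell_size = 1e-4),
               "unresolvable")
})

test_that("rasterized implant area matches the shoelace area and converges", {
  geo <- test_geometry()
  prof <- build_implant_profile(geo)
  analytic <- implant_polygon_area(prof, geo)
  g8 <- rasterize_domain(prof, geo, geo$thread_depth / 8)
  a8 <- sum(g8$cell_class == cell_class_codes()[["implant_solid"]]) *
    g8$cell_size^2
  expect_rel_equal(a8, analytic, 0.05)
  g16 <- rasterize_domain(prof, geo, geo$thread_depth / 16)
  solid <- cell_class_codes()[c("implant_solid", "bone_solid")]
  open8 <- sum(!g8$cell_class %in% solid) * g8$cell_size^2
  open16 <- sum(!g16$cell_class %in% solid) * g16$cell_size^2
  expect_rel_equal(open16, open8, 0.02)
})

test_that("rasterization is deterministic and boundary strips exist", {
  geo <- test_geometry()
  prof <- build_implant_profile(geo)
  g1 <- rasterize_domain(prof, geo, 1e-4)
  g2 <- rasterize_domain(prof, geo, 1e-4)
  expect_identical(g1$cell_class, g2$cell_class)
  codes <- cell_class_codes()
  for (k in c("inlet_apex", "inlet_bone", "outlet")) {
    expect_gt(sum(g1$cell_class == codes[[k]]), 0)
  }
  m1 <- compute_zone_masks(g1)
  m2 <- compute_zone_masks(g2)
  expect_identical(m1$zone, m2$zone)
})

test_that("zone masks partition the peri-implant gap", {
  grid <- test_grid()
  mask <- compute_zone_masks(grid, delta = grid$cell_size)
  geo <- grid$params
  h <- grid$cell_size
  yc <- matrix((seq_len(grid$ny) - 0.5) * h, grid$nx, grid$ny, byrow = TRUE)
  span <- yc >= geo$apex_clearance &
    yc <= geo$apex_clearance + geo$threaded_length
  fluid <- grid$cell_class == 0L
  # every span fluid cell carries exactly one zone label
  expect_true(all(mask$zone[fluid & span] %in% 1:3))
  expect_true(all(mask$zone[!fluid] == 0L))
  za <- zone_areas(mask, grid)
  gap_area <- sum(fluid & span) * h^2
  expect_equal(sum(za$area[za$zone != "none"]),
               sum(fluid & (mask$zone > 0)) * h^2, tolerance = 1e-12)
  expect_lte(sum(za$area[za$zone != "none"]), gap_area + 200 * h^2)
})

test_that("a vanishing interface band assigns its cells to the thread zone", {
  grid <- test_grid()
  mask0 <- compute_zone_masks(grid, delta = 0.5 * grid$cell_size)
  expect_equal(sum(mask0$zone == zone_codes()[["interface"]]), 0)
  mask1 <- compute_zone_masks(grid, delta = grid$cell_size)
  moved <- mask1$zone == zone_codes()[["interface"]] &
    mask0$zone == zone_codes()[["thread"]]
  expect_gt(sum(moved), 0)
})

test_that("thread zone area is one quarter of the outer zone on the default geometry", {
  geo <- test_geometry()
  prof <- build_implant_profile(geo)
  grid <- rasterize_domain(prof, geo, 1e-5)
  mask <- compute_zone_masks(grid)   # default delta = 2 cell widths
  za <- zone_areas(mask, grid)
  ratio <- za$area[za$zone == "thread"] / za$area[za$zone == "outer"]
  expect_gte(ratio, 0.20)
  expect_lte(ratio, 0.30)
})

test_that("roughness metrics match closed forms", {
  # smooth versus itself
  geo <- test_geometry()
  sm <- build_implant_profile(geo)
  m0 <- roughness_metrics(sm, sm)
  expect_equal(m0$mean_abs_deviation, 0)
  expect_equal(m0$roughness_ratio, 1)
  # square wave of amplitude a and period p on a straight line:
  # levels alternate 0 / a with two vertical jumps per period
  a <- 2e-6; p <- 8e-6; N <- 40L
  sqx <- numeric(0); sqy <- numeric(0)
  for (k in seq_len(N) - 1L) {
    sqx <- c(sqx, k * p, k * p + p / 2, k * p + p / 2, (k + 1) * p)
    sqy <- c(sqy, 0, 0, a, a)
  }
  sqx <- c(sqx, N * p); sqy <- c(sqy, 0)
  ref <- cbind(x = c(0, N * p), y = c(0, 0))
  m1 <- roughness_metrics(cbind(x = sqx, y = sqy), ref)
  expect_rel_equal(m1$roughness_ratio, (p + 2 * a) / p, 1e-9)
  expect_equal(m1$peak_to_valley_max, a, tolerance = 1e-9)
  # seeded profile: op equals an independent arc-length quotient
  rough <- build_implant_profile(geo, roughness_spec(seed = 11L))
  v <- as.matrix(rough[, c("x", "y")])
  s <- as.matrix(sm[, c("x", "y")])
  arc <- function(m) sum(sqrt(diff(m[, 1])^2 + diff(m[, 2])^2))
  m2 <- roughness_metrics(rough, sm)
  expect_equal(m2$roughness_ratio, arc(v) / arc(s), tolerance = 1e-12)
})

test_that("physical-scale Wenzel ratio is reproducible and above one", {
  rs <- roughness_spec(seed = 42L)
  r1 <- roughness_ratio_physical(rs)
  r2 <- roughness_ratio_physical(rs)
  expect_identical(r1, r2)
  expect_gt(r1, 1)
  expect_lt(r1, 3)
})
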