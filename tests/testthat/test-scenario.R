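# Scenario pipeline: smoke, determinism, budgets, wetting response, outputs.

test_that("a short scenario run completes with monotone fibrinogen inflow", {
  out_dir <- file.path(tempdir(), "implantflow-smoke")
  cfg <- quick_config(t_end = 0.05, out_dir = out_dir)
  res <- run_scenario(cfg)
  expect_s3_class(res, "scenario_result")
  expect_gte(length(unique(res$series$time)), 2)
  # domain fibrinogen mass (zones plus remainder) grows under pure inflow
  tot <- res$series |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(m = sum(.data$mass), .groups = "drop")
  expect_true(all(diff(tot$m) >= -1e-18))
  # manifest lists the emitted files, which exist
  expect_gt(length(res$manifest$files), 0)
  expect_true(all(file.exists(file.path(out_dir, res$manifest$files))))
  # laminar assertion was evaluated
  expect_lt(res$reynolds, 2800)
})

test_that("identical configurations reproduce byte-identical series", {
  cfg <- quick_config(t_end = 0.03)
  r1 <- run_scenario(cfg)
  r2 <- run_scenario(cfg)
  expect_identical(r1$series$mass, r2$series$mass)
  expect_identical(r1$series$mean_speed, r2$series$mean_speed)
  expect_identical(r1$sim$state$u, r2$sim$state$u)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(r1$series, f1, row.names = FALSE)
  write.csv(r2$series, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("superhydrophilic walls draw at least as much blood as hydrophobic", {
  vol <- vapply(c(0, 70), function(th) {
    res <- run_scenario(quick_config(theta = th, t_end = 0.3))
    sum(res$sim$phase$alpha[res$grid$cell_class == 0L]) *
      res$grid$cell_size^2
  }, numeric(1))
  expect_gte(vol[1], vol[2])
})

test_that("scenario configs serialize to YAML and back", {
  cfg <- quick_config(t_end = 0.05)
  f <- tempfile(fileext = ".yaml")
  write_scenario_config(cfg, f)
  back <- read_scenario_config(f)
  expect_equal(back$surface, cfg$surface)
  expect_equal(back$theta, cfg$theta)
  expect_equal(back$cell_size, cfg$cell_size)
  expect_equal(unclass(back$geometry), unclass(cfg$geometry))
  expect_equal(back$settings$sigma_scale, cfg$settings$sigma_scale)
})

test_that("wenzel mode amplifies wetting and installs a wall momentum sink", {
  cfg <- scenario_config(surface = "microrough", theta = 70,
                         resolution = "test",
                         settings = solver_settings(t_end = 0.02,
                                                    sigma_scale = 0.02))
  expect_equal(cfg$wetting_mode, "wenzel_effective")
  r <- roughness_ratio_physical(cfg$roughness)
  expect_lt(effective_contact_angle(70, r), 70)
  grid <- rasterize_domain(build_implant_profile(cfg$geometry), cfg$geometry,
                           cfg$cell_size)
  sink <- implantflow:::sink_matrix(grid, cfg$props, cfg$roughness,
                                    "wenzel_effective")
  expect_gt(max(sink), 0)
  # the sink sits exactly on the first fluid layer along the implant
  imp <- grid$cell_class == 1L
  layer <- (implantflow:::shift_mat(imp, 1, 0) |
            implantflow:::shift_mat(imp, -1, 0) |
            implantflow:::shift_mat(imp, 0, 1) |
            implantflow:::shift_mat(imp, 0, -1)) & grid$cell_class == 0L
  expect_true(all((sink > 0) == layer))
})

test_that("VTK output round-trips grid dimensions and arrays", {
  grid <- test_grid()
  mask <- compute_zone_masks(grid)
  f <- tempfile(fileext = ".vtk")
  write_grid_vtk(grid, mask, f)
  lines <- readLines(f)
  expect_true(any(grepl(sprintf("DIMENSIONS %d %d 1", grid$nx + 1, grid$ny + 1),
                        lines)))
  expect_true(any(grepl("SCALARS cell_class int", lines)))
  expect_true(any(grepl("SCALARS zone int", lines)))
  ncell_line <- grep("CELL_DATA", lines, value = TRUE)
  expect_equal(as.integer(sub("CELL_DATA ", "", ncell_line)),
               grid$nx * grid$ny)
})

test_that("tidiers and plots expose the scenario surface", {
  res <- run_scenario(quick_config(t_end = 0.04))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("scenario", "time", "zone", "mass", "mean_speed") %in%
                    names(td)))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$fibrinogen_closure_error, 0.005)
  p1 <- autoplot(res, type = "density")
  expect_s3_class(p1, "ggplot")
  p2 <- autoplot(res, type = "vectors")
  expect_s3_class(p2, "ggplot")
  p3 <- plot_zone_series(res$series)
  expect_s3_class(p3, "ggplot")
})

test_that("identical scenarios give unit fold changes in a study table", {
  res <- run_scenario(quick_config(t_end = 0.04))
  fc <- fold_change_table(list(a = res, b = res),
                          t_min = 0, t_max = 0.04)
  sv <- fc[fc$comparison == "scenario_vs_scenario", ]
  expect_true(all(abs(sv$value - 1) < 1e-12 | is.na(sv$value)))
})
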