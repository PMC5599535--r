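test_that("number concentration reproduces the d^-3 mass scaling", {
  cc <- number_concentration(suspension_spec())
  expect_equal(unname(cc$ratio), c(100, 34, 10))
  expect_equal(cc$total, 7700, tolerance = 0.01)
  # hand-computed single-class example: 0.1% w/w, d = 10 um, rho = 1.05
  one <- number_concentration(suspension_spec(
    diameters_um = 10, mass_fraction_percent = 0.1, n_stocks_mixed = 1))
  expect_equal(unname(one$per_class), 1819, tolerance = 0.001)
  # pure scaling law
  sc <- number_concentration(suspension_spec(diameters_um = c(5, 10)))
  expect_equal(unname(sc$per_class[1] / sc$per_class[2]), 8)
  expect_error(number_concentration(suspension_spec(diameters_um = c(5, 5))))
})

test_that("throughput is flow rate times concentration", {
  expect_equal(estimated_throughput(10, 7700), 1283)
  expect_equal(estimated_throughput(6, 7700), 770)
  expect_equal(estimated_throughput(0, 7700), 0)
})

test_that("the velocity profile is parabolic with no-slip walls", {
  cfg <- flow_config(flow_rate_ul_per_min = 6)
  expect_equal(axial_velocity(50, 25, cfg), 45000)  # 2.25 x Q/A at center
  expect_lt(axial_velocity(1, 25, cfg), axial_velocity(50, 25, cfg))
  expect_equal(axial_velocity(30, 10, cfg), axial_velocity(70, 40, cfg))
  expect_error(axial_velocity(0, 25, cfg), "inside")
  expect_error(axial_velocity(50, 50, cfg), "inside")
  # wall limit
  expect_lt(axial_velocity(0.01, 25, cfg) / axial_velocity(50, 25, cfg), 1e-3)
})

test_that("the cross-sectional mean of the profile equals Q/A", {
  cfg <- flow_config(flow_rate_ul_per_min = 6)
  y <- seq(0.5, 99.5, by = 1); z <- seq(0.5, 49.5, by = 1)
  u <- outer(y, z, function(a, b) axial_velocity(a, b, cfg))
  expect_equal(mean(u), 20000, tolerance = 0.001)  # 6 uL/min over 5000 um^2
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_sequence(n_frames = 8, seed = 3)
  b <- simulate_sequence(n_frames = 8, seed = 3)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)
})

test_that("trajectories have constant axial velocity and zero lateral drift", {
  sim <- simulate_sequence(n_frames = 40, seed = 6)
  for (id in unique(sim$truth$object_id)) {
    tr <- sim$truth[sim$truth$object_id == id, ]
    if (nrow(tr) < 3) next
    expect_equal(sd(diff(tr$col)), 0, tolerance = 1e-9)
    expect_equal(sd(tr$row), 0, tolerance = 1e-12)
  }
})

test_that("arrival counts follow the configured rate", {
  cfg <- flow_config()
  sim <- simulate_sequence(cfg, n_frames = 100, seed = 12,
                           rate_per_s = 250)  # expect 50 arrivals
  n <- nrow(sim$objects)
  expect_gt(n, 50 - 3 * sqrt(50))
  expect_lt(n, 50 + 3 * sqrt(50))
})

test_that("zero concentration gives blank frames and empty truth", {
  sim <- simulate_sequence(n_frames = 5, seed = 1, rate_per_s = 0)
  expect_equal(nrow(sim$truth), 0)
  f <- sim$frames[[3]]
  expect_equal(median(f), 200, tolerance = 2)
  expect_lt(sd(as.numeric(f)), 4)
})

test_that("rendering darkens particle centers and blurs motion", {
  cfg <- flow_config()
  still <- render_frame(data.frame(row = 50, col = 250, radius_px = 5,
                                   depth_um = 25, velocity_px = 0),
                        cfg, render_params(noise_sd = 0.01))
  dk <- which(still == min(still))[1]
  dk_row <- (dk - 1) %% 100; dk_col <- (dk - 1) %/% 100
  # flat-bottomed disk: the darkest pixel lies inside the particle
  expect_lte(sqrt((dk_row - 50)^2 + (dk_col - 250)^2), 5)
  expect_lt(min(still), 130)
  # a particle at 40 px/frame smears ~2 px along the flow axis
  moving <- render_frame(data.frame(row = 50, col = 250, radius_px = 5,
                                    depth_um = 25, velocity_px = 40),
                         cfg, render_params(noise_sd = 0.01))
  col_extent_still <- sum(still[51, ] < 190)
  col_extent_moving <- sum(moving[51, ] < 190)
  row_extent_moving <- sum(moving[, 251] < 190)
  expect_gte(col_extent_moving, col_extent_still + 1)
  expect_gt(col_extent_moving, row_extent_moving)
})

test_that("occlusion pairs overlap briefly and are flagged", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_occlusion_pair(seed = s)
    expect_equal(nrow(sim$objects), 2)
    occ <- sim$truth[sim$truth$occluded, ]
    if (nrow(occ) > 0) {
      hits <- hits + 1
      expect_lte(length(unique(occ$frame)), 6)
    }
  }
  expect_gte(hits, 4)  # the construction reliably produces an overlap
})
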