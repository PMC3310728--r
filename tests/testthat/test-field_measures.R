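fp <- field_params()

test_that("the density kernel sums Gaussian weights with 1/(pi R^2) mass", {
  expect_equal(local_density_at_point(matrix(c(1, 1), 1), c(1, 1), 0.7),
               1 / (pi * 0.49))
  expect_equal(local_density_at_point(matrix(numeric(0), 0, 2), c(0, 0), 0.7), 0)
  pos <- rbind(c(1, 1), c(1, 1.7)) # distances 0 and 0.7 from x
  expect_equal(local_density_at_point(pos, c(1, 1), 0.7),
               (1 + exp(-1)) / (pi * 0.49))
})

test_that("the kernel integrates to one pedestrian over the plane", {
  pos <- rbind(c(3, 0), c(-2, 1), c(0, -3))
  g <- seq(-12, 12, by = 0.1)
  grid <- as.matrix(expand.grid(g, g))
  rho <- vapply(seq_len(nrow(grid)), function(k) {
    local_density_at_point(pos, grid[k, ], 0.7)
  }, numeric(1))
  expect_equal(sum(rho) * 0.1^2, 3, tolerance = 0.01)
})

test_that("density profiles reflect rotational symmetry and localisation", {
  geom <- corridor_geometry()
  # 48 equally spaced pedestrians on the mid circle (spacing well below the
  # kernel scale): flat profile
  th <- seq(0, 2 * pi, length.out = 49)[-49]
  prof <- density_profile(from_polar(rep(3.25, 48), th), geom, fp)
  expect_lt(diff(range(prof)) / mean(prof), 0.01)
  # everyone bunched at theta = 0: that bin dominates
  prof2 <- density_profile(from_polar(rep(3.25, 12), rep(0.01, 12)), geom, fp)
  expect_equal(which.max(prof2), 1)
  expect_equal(density_profile(matrix(numeric(0), 0, 2), geom, fp),
               rep(0, fp$n_theta))
})

test_that("radial speed is the sector mean of |dr/dt|, NA when empty", {
  # tangential circular motion: zero radial speed everywhere occupied
  traj <- make_lane_fixture(n_lanes = 1, peds_per_lane = 6, lane_radii = 3.25,
                            gap_along_lane = 1, duration = 5)
  vr <- radial_speed_profile(traj, 2, fp)
  expect_true(all(abs(vr[!is.na(vr)]) < 1e-3))
  expect_true(any(is.na(vr)))
  # purely radial motion at 0.5 m/s
  times <- seq(0, 2, by = 0.1)
  pos <- array(NA_real_, c(length(times), 1, 2))
  pos[, 1, 1] <- 2.5 + 0.5 * times
  pos[, 1, 2] <- 0.1
  traj2 <- trajectory_set(times, pos, 1L)
  vr2 <- radial_speed_profile(traj2, 1, fp)
  expect_equal(vr2[1], 0.5, tolerance = 1e-3)
  expect_true(all(is.na(vr2[-1])))
})

test_that("field maps are rotation invariant and direction-sign invariant", {
  traj <- simulate_crowd(n = 20, sigma = 0.16, duration = 6, seed = 21)
  maps <- build_field_maps(traj, fp)
  expect_equal(dim(maps$density), c(61, 72))
  expect_true(all(maps$density >= 0))
  # rotate all positions by one sector width: maps roll by one bin
  dth <- 2 * pi / fp$n_theta
  rot <- traj
  x <- traj$positions[, , 1]; y <- traj$positions[, , 2]
  rot$positions[, , 1] <- cos(dth) * x - sin(dth) * y
  rot$positions[, , 2] <- sin(dth) * x + cos(dth) * y
  maps_rot <- build_field_maps(rot, fp)
  expect_equal(maps_rot$density[, c(2:72, 1)], maps$density, tolerance = 1e-9)
  expect_equal(maps_rot$radial_speed[, c(2:72, 1)], maps$radial_speed,
               tolerance = 1e-9)
  # reversing every circulation sign leaves both maps untouched
  rev <- traj; rev$directions <- -traj$directions
  maps_rev <- build_field_maps(rev, fp)
  expect_identical(maps_rev$density, maps$density)
  expect_identical(maps_rev$radial_speed, maps$radial_speed)
})

test_that("constructed monotone couplings give correlation +/- 1", {
  maps <- structure(list(
    theta = (1:4 - 0.5) * pi / 2, times = seq(0, 20, by = 0.5),
    density = NULL, radial_speed = NULL, params = field_params(n_theta = 4)),
    class = "field_maps")
  set.seed(5)
  rho <- matrix(runif(41 * 4), 41, 4)
  maps$density <- rho
  maps$radial_speed <- 2 * rho + 1 # increasing affine function
  expect_equal(density_speed_correlation(maps)$estimate, 1)
  maps$radial_speed <- 3 - 2 * rho # decreasing affine function
  corr <- density_speed_correlation(maps)
  expect_equal(corr$estimate, -1)
  expect_lt(corr$p_value, 0.01)
  # undefined cells are excluded, not imputed
  vr <- 3 - 2 * rho; vr[, 4] <- NA
  maps$radial_speed <- vr
  expect_equal(density_speed_correlation(maps)$n,
               sum(maps$times > 10) * 3)
  maps$radial_speed[] <- NA
  expect_error(density_speed_correlation(maps), "fewer than 10")
})
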