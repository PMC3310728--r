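geom <- corridor_geometry()
par0 <- model_params()
par_rigid <- model_params(steering_slack = 0) # strict rigid-disc anticipation

test_that("collision distance matches analytic ray-circle cases", {
  # lone pedestrian at radius 3.25 heading radially outward
  pos <- matrix(c(3.25, 0), 1, 2)
  vel <- matrix(0, 1, 2)
  f <- collision_distance(pos, vel, 0.2, 1, 0, 1.2, par_rigid, geom)
  expect_equal(f, 4.5 - 3.25 - 0.2, tolerance = 1e-9)
  # touching the inner wall, heading tangentially: chord to the outer
  # contact circle of radius 4.5 - 0.2
  pos <- matrix(c(2.2, 0), 1, 2)
  f <- collision_distance(pos, vel, 0.2, 1, pi / 2, 1.2, par_rigid, geom)
  expect_equal(f, sqrt(4.3^2 - 2.2^2), tolerance = 1e-9)
  # stationary neighbour dead ahead at centre distance 1 m
  pos <- rbind(c(3.25, 0), c(3.25, 1))
  vel <- matrix(0, 2, 2)
  f <- collision_distance(pos, vel, 0.2, 1, pi / 2, 1.2, par_rigid, geom)
  expect_equal(f, 1 - 0.4, tolerance = 1e-9)
  # the anticipation slack extends the free path by exactly its own size
  f_slack <- collision_distance(pos, vel, 0.2, 1, pi / 2, 1.2, par0, geom)
  expect_equal(f_slack, 1 - 0.4 + par0$steering_slack, tolerance = 1e-9)
  # free path in open space is capped at the horizon
  sc <- free_space_scene()
  f <- collision_distance(matrix(sc$position, 1), vel[1, , drop = FALSE],
                          0.2, 1, 0.3, 1.2, par0, sc$geometry)
  expect_equal(f, par0$d_max)
})

test_that("moving obstacles are extrapolated linearly", {
  # neighbour 2 m ahead walking away at 0.6 m/s; i closes at 1.2 m/s:
  # gap (2 - 0.4) closes at 0.6 m/s -> contact after t = 8/3 s, f = v0 t
  pos <- rbind(c(3.25, 0), c(3.25, 2))
  vel <- rbind(c(0, 0), c(0, 0.6))
  f <- collision_distance(pos, vel, 0.2, 1, pi / 2, 1.2, par_rigid,
                          corridor_geometry(0.1, 1000))
  expect_equal(f, 1.2 * (2 - 0.4) / 0.6, tolerance = 1e-9)
})

test_that("collision distance agrees with the 1 mm stepping oracle on random scenes", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(2:5, 1)
    pol <- list(r = runif(n, 2.3, 4.2), theta = runif(n, 0, 2 * pi))
    pos <- from_polar(pol$r, pol$theta)
    # enforce initial gaps so touching-while-separating cases don't arise
    if (n > 1 && min(dist(pos)) < 0.45) next
    vel <- matrix(runif(2 * n, -1, 1), n, 2)
    i <- sample(n, 1)
    alpha <- runif(1, 0, 2 * pi)
    f <- collision_distance(pos, vel, 0.2, i, alpha, 1.2, par_rigid, geom)
    f_oracle <- stepping_collision_oracle(pos, vel, 0.2, i, alpha, 1.2,
                                          par_rigid, geom)
    expect_lt(abs(f - f_oracle), 5e-3)
  }
})

test_that("the speed heuristic caps at comfortable speed and scales with headway", {
  expect_equal(desired_speed(1.2, 10, 0.5), 1.2)
  expect_equal(desired_speed(1.2, 0, 0.5), 0)
  expect_equal(desired_speed(1.2, 0.3, 0.5), 0.6)
})

test_that("steering follows the looking direction in free space and dodges obstacles", {
  sc <- free_space_scene()
  pos <- matrix(sc$position, 1)
  vel <- matrix(0, 1, 2)
  dest <- sc$position + 5 * tangent_direction(sc$position, 1)
  dec <- desired_direction(pos, vel, 0.2, dest, 1, 1.2, par0, sc$geometry)
  expect_equal(dec$alpha_des, dec$alpha0)
  expect_equal(dec$v_des, 1.2)
  expect_true(all(dec$f_samples <= par0$d_max))

  # static obstacle exactly on the looking-direction ray, 1 m ahead
  e0 <- tangent_direction(sc$position, 1)
  pos2 <- rbind(sc$position, sc$position + 1 * e0)
  vel2 <- matrix(0, 2, 2)
  dec2 <- desired_direction(pos2, vel2, 0.2, dest, 1, 1.2, par0, sc$geometry)
  expect_false(isTRUE(all.equal(dec2$alpha_des, dec2$alpha0)))
  # the chosen heading attains the grid minimum of the distance proxy
  d_scores <- sqrt(par0$d_max^2 + dec2$f_samples^2 -
                   2 * par0$d_max * dec2$f_samples *
                     cos(dec2$alpha0 - dec2$alpha_samples))
  expect_equal(min(d_scores),
               d_scores[which.min(abs(dec2$alpha_samples - dec2$alpha_des))],
               tolerance = 1e-9)

  # obstacle offset to the left makes the pedestrian deviate rightward
  rot <- function(v, a) c(cos(a) * v[1] - sin(a) * v[2],
                          sin(a) * v[1] + cos(a) * v[2])
  pos3 <- rbind(sc$position, sc$position + 1 * rot(e0, 20 * pi / 180))
  dec3 <- desired_direction(pos3, vel2, 0.2, dest, 1, 1.2, par0, sc$geometry)
  dev <- (dec3$alpha_des - dec3$alpha0 + pi) %% (2 * pi) - pi
  expect_lt(dev, 0) # rightward = clockwise = negative deviation
})

test_that("contact forces vanish without overlap and follow k * overlap", {
  pos <- rbind(c(3, 0), c(3, 1))
  expect_equal(contact_forces(pos, 0.2, 1, par0, geom), c(0, 0))
  # two bodies overlapping by 1 cm
  pos <- rbind(c(3, 0), c(3, 0.39))
  f <- contact_forces(pos, 0.2, 1, par0, geom)
  expect_equal(f, c(0, -10), tolerance = 1e-9)
  expect_equal(contact_forces(pos, 0.2, 2, par0, geom), c(0, 10),
               tolerance = 1e-9)
  # body overlapping the outer wall by 2 cm: pushed straight inward
  pos <- matrix(c(4.32, 0), 1)
  f <- contact_forces(pos, 0.2, 1, par0, geom)
  expect_equal(f, c(-20, 0), tolerance = 1e-9)
})

test_that("the destination sits d_dest ahead along the tangent", {
  expect_equal(update_destination(c(3, 0), 1, 5), c(3, 5))
  expect_equal(update_destination(c(0, 3), 1, 5), c(-5, 3))
  expect_equal(update_destination(c(3, 0), -1, 5), c(3, -5))
})

test_that("free-flow speed follows the closed-form relaxation law", {
  sc <- free_space_scene()
  state <- list(positions = matrix(sc$position, 1),
                velocities = matrix(0, 1, 2))
  peds <- data.frame(v0 = 1.2, direction = 1)
  n_steps <- round(0.5 / par0$dt) # integrate to t = tau
  for (s in seq_len(n_steps)) state <- step_crowd(state, peds, par0, sc$geometry)
  speed <- sqrt(sum(state$velocities^2))
  expect_equal(speed, 1.2 * (1 - exp(-1)), tolerance = 0.01)
  # and settles at v0: zero acceleration fixed point
  for (s in seq_len(10 * n_steps)) state <- step_crowd(state, peds, par0, sc$geometry)
  expect_equal(sqrt(sum(state$velocities^2)), 1.2, tolerance = 1e-3)
})

test_that("a pedestrian already at its desired velocity keeps it", {
  sc <- free_space_scene()
  e0 <- tangent_direction(sc$position, 1)
  state <- list(positions = matrix(sc$position, 1),
                velocities = matrix(1.2 * e0, 1, 2))
  peds <- data.frame(v0 = 1.2, direction = 1)
  nxt <- step_crowd(state, peds, par0, sc$geometry)
  # the tangent rotates slightly as the agent advances; speed stays at v0
  expect_equal(sqrt(sum(nxt$velocities^2)), 1.2, tolerance = 1e-4)
})

test_that("overlapping agents are pushed apart along the line of centres", {
  state <- list(positions = rbind(c(3, 0), c(3.3, 0)),
                velocities = matrix(0, 2, 2))
  peds <- data.frame(v0 = c(1.2, 1.2), direction = c(1, -1))
  nxt <- step_crowd(state, peds, par0, geom)
  # the contact term dominates the first step: x-velocities separate
  expect_lt(nxt$velocities[1, 1], 0)
  expect_gt(nxt$velocities[2, 1], 0)
})

test_that("simulations are reproducible, contained, and respect the speed bound", {
  t1 <- simulate_crowd(n = 10, sigma = 0.16, duration = 5, seed = 99)
  t2 <- simulate_crowd(n = 10, sigma = 0.16, duration = 5, seed = 99)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$v0, t2$v0)
  t3 <- simulate_crowd(n = 10, sigma = 0.16, duration = 5, seed = 100)
  expect_false(identical(t1$positions, t3$positions))

  r <- sqrt(t1$positions[, , 1]^2 + t1$positions[, , 2]^2)
  expect_true(all(r > t1$geometry$r_inner - 0.05))
  expect_true(all(r < t1$geometry$r_outer + 0.05))

  # two free-flowing agents reach cruising speed
  tf <- simulate_crowd(n = 2, sigma = 0, duration = 10, seed = 5)
  vel <- finite_difference_velocities(tf)
  late <- tf$times > 8
  speeds <- sqrt(vel[late, , 1]^2 + vel[late, , 2]^2)
  expect_true(all(abs(speeds - 1.2) < 0.05))
})

test_that("refining dt leaves free-flow trajectories essentially unchanged", {
  sc <- free_space_scene()
  run <- function(dt) {
    state <- list(positions = matrix(sc$position, 1),
                  velocities = matrix(0, 1, 2))
    peds <- data.frame(v0 = 1.2, direction = 1)
    p <- model_params(dt = dt)
    for (s in seq_len(round(10 / dt))) state <- step_crowd(state, peds, p, sc$geometry)
    state$positions
  }
  # explicit Euler is first order: halving-by-five the step shifts a 10 s
  # free-flow path by O(v0 * dt)
  expect_lt(sqrt(sum((run(0.01) - run(0.002))^2)), 0.01)
})
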