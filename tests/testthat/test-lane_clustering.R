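cp_default <- clustering_params()

test_that("the follow relation thresholds the closest forward approach", {
  # static i, j approaching along a straight line 2 m behind at 1 m/s:
  # closest approach over 1 s is 1 m -> not following
  times <- seq(0, 2, by = 0.1)
  pos <- array(NA_real_, c(length(times), 2, 2))
  pos[, 1, 1] <- 0; pos[, 1, 2] <- 3
  pos[, 2, 1] <- -2 + 1.0 * times; pos[, 2, 2] <- 3
  traj <- trajectory_set(times, pos, c(1, 1))
  expect_false(is_following(traj, 2, 1, 0, cp_default))
  # a pedestrian currently within delta is following already at s = t
  pos[, 2, 1] <- -0.3 + 1.0 * times
  traj2 <- trajectory_set(times, pos, c(1, 1))
  expect_true(is_following(traj2, 2, 1, 0, cp_default))
  expect_error(is_following(traj2, 1, 1, 0, cp_default), "self-following")
  expect_error(is_following(traj2, 2, 1, 1.5, cp_default), "window")
})

test_that("single-file lanes cluster by transitive follow edges", {
  traj <- make_lane_fixture(n_lanes = 2, peds_per_lane = 5,
                            gap_along_lane = 0.8, duration = 10)
  parts <- clusters_at(traj, 3, cp_default)
  expect_equal(length(parts), 2)
  expect_equal(sort(lengths(parts)), c(5, 5))
  # a huge gap breaks every follow edge: all singletons
  traj2 <- make_lane_fixture(n_lanes = 1, peds_per_lane = 4,
                             gap_along_lane = 5, lane_radii = 3.5,
                             duration = 10)
  expect_equal(lengths(clusters_at(traj2, 3, cp_default)), rep(1L, 4))
})

test_that("opposite-direction files near-passing stay separate clusters", {
  # two dense lanes only 0.5 m apart radially, opposite circulation signs:
  # members of the two streams constantly pass within delta of each other
  traj <- make_lane_fixture(n_lanes = 2, peds_per_lane = 5,
                            lane_radii = c(3.0, 3.5), gap_along_lane = 0.8,
                            duration = 10)
  cs <- cluster_count_series(traj, cp_default)
  expect_true(all(cs$n_clusters == 2))
  # with the direction restriction lifted, near-passes chain both streams
  cp_any <- clustering_params(same_direction_only = FALSE)
  cs_any <- cluster_count_series(traj, cp_any)
  expect_true(any(cs_any$n_clusters == 1))
})

test_that("clusters_at agrees with an independent union-find oracle", {
  for (seed in 1:4) {
    traj <- simulate_crowd(n = 10, sigma = 0.2, duration = 8, seed = seed)
    for (t in c(0, 3.5, 6)) {
      expect_identical(clusters_at(traj, t, cp_default),
                       union_find_clusters_oracle(traj, t, cp_default))
    }
  }
})

test_that("every evaluation yields a true partition and counts behave", {
  traj <- simulate_crowd(n = 20, sigma = 0.16, duration = 12, seed = 3)
  cs <- cluster_count_series(traj, cp_default)
  expect_equal(max(cs$time), 12 - cp_default$window)
  ks <- c(1, nrow(cs) %/% 2, nrow(cs))
  for (k in ks) {
    parts <- clusters_at(traj, cs$time[k], cp_default)
    all_ids <- sort(unlist(parts))
    expect_identical(all_ids, sort(traj$ids))          # disjoint cover
    expect_equal(length(parts), cs$n_clusters[k])
  }
})

test_that("growing delta or window never increases the cluster count", {
  traj <- simulate_crowd(n = 16, sigma = 0.2, duration = 10, seed = 8)
  t <- 4
  for (w in c(0.5, 1)) {
    counts <- vapply(c(0.3, 0.6, 0.9, 1.2), function(d) {
      length(clusters_at(traj, t, clustering_params(delta = d, window = w)))
    }, integer(1))
    expect_true(all(diff(counts) <= 0))
  }
  counts_w <- vapply(c(0.5, 1, 1.5, 2), function(w) {
    length(clusters_at(traj, t, clustering_params(window = w)))
  }, integer(1))
  expect_true(all(diff(counts_w) <= 0))
})

test_that("phase classification uses the five/ten cluster bands", {
  expect_equal(as.character(classify_phase(c(1, 4, 5))), rep("order", 3))
  expect_equal(as.character(classify_phase(c(10, 12, 30))), rep("disorder", 3))
  expect_equal(as.character(classify_phase(c(6, 7, 9))), rep("intermediate", 3))
  expect_error(classify_phase(0))
})

test_that("lifetimes follow the composition-change death rule", {
  # static dispersed crowd: nothing ever changes, everything censored
  traj <- make_switching_fixture(list(1:2, 3:4), list(1:2, 3:4),
                                 period = 5, duration = 30)
  tl <- track_lifetimes(traj, cp_default)
  expect_length(tl$lifetimes, 0)
  expect_equal(tl$censored, c(29, 29)) # last evaluation at 30 - window
  # alternating partitions: every completed lifetime equals the period
  traj2 <- make_switching_fixture(list(1:2, 3L), list(1:3),
                                  period = 2, duration = 20)
  tl2 <- track_lifetimes(traj2, cp_default)
  expect_true(length(tl2$lifetimes) > 0)
  expect_true(all(tl2$lifetimes == 2))
})

test_that("the survival curve is the Kaplan-Meier product-limit estimator", {
  # no censoring: empirical survival
  sv <- survival_curve(data.frame(time = c(1, 2, 3), event = 1))
  expect_equal(sv$surv[sv$time == 0], 1)
  expect_equal(sv$surv[sv$time == 2], 1 / 3) # p just after t = 2
  expect_equal(approx(sv$time, sv$surv, 1.5, method = "constant")$y, 2 / 3)
  expect_true(all(diff(sv$surv) <= 0))
  # censoring: check against the hand-computed product-limit table
  df <- data.frame(time = c(2, 2, 3), event = c(1, 1, 0))
  sv2 <- survival_curve(df)
  oracle <- km_oracle(df$time, df$event)
  expect_equal(sv2$surv[match(oracle$time, sv2$time)], oracle$surv)
  # pooled lifetimes against a direct empirical survival (no censoring)
  set.seed(2)
  lt <- round(rexp(200, 1), 1) + 0.1
  sv3 <- survival_curve(data.frame(time = lt, event = 1))
  emp <- vapply(sv3$time, function(t) mean(lt > t), numeric(1))
  expect_equal(sv3$surv, emp, tolerance = 1e-12)
  expect_error(survival_curve(data.frame(time = numeric(0), event = numeric(0))),
               "no cluster lifetimes")
})

test_that("the sensitivity scan is consistent and robust on the lane fixture", {
  traj <- make_lane_fixture(n_lanes = 2, peds_per_lane = 5,
                            gap_along_lane = 0.8, duration = 10)
  m <- sensitivity_scan(traj, 0.6, 1.0)
  cs <- cluster_count_series(traj, cp_default)
  expect_equal(m[1, 1], mean(cs$n_clusters))
  grid <- sensitivity_scan(traj, c(0.4, 0.6, 0.8), c(0.5, 1, 1.5))
  expect_true(all(grid == 2)) # stable band around the defaults
  # delta -> 0 dissolves every edge
  m0 <- sensitivity_scan(traj, 1e-6, 1.0)
  expect_equal(m0[1, 1], 10)
})
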