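# Independent oracles, deliberately brute-force and separate from the
# implementation paths they check.

# Collision distance by advancing the body along the ray in 1 mm steps until
# first contact with a neighbour (moved linearly at its velocity) or a wall.
stepping_collision_oracle <- function(positions, velocities, body_radii, i,
                                      alpha, v0, params, geometry,
                                      step = 0.001) {
  e <- c(cos(alpha), sin(alpha))
  n <- nrow(positions)
  radii <- rep_len(body_radii, n)
  ss <- seq(step, params$d_max, by = step)
  for (s in ss) {
    p <- positions[i, ] + s * e
    t <- s / v0
    for (j in seq_len(n)[-i]) {
      q <- positions[j, ] + t * velocities[j, ]
      if (sqrt(sum((p - q)^2)) <= radii[i] + radii[j]) return(s)
    }
    r <- sqrt(sum(p^2))
    if (r >= geometry$r_outer - radii[i]) return(s)
    if (r <= geometry$r_inner + radii[i]) return(s)
  }
  params$d_max
}

# Connected components of the follow graph by an explicit union-find over
# R-level pairwise checks (no shared code with clusters_at).
union_find_clusters_oracle <- function(traj, t, params) {
  n <- n_pedestrians(traj)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  k <- round((t - traj$times[1]) / traj_dt(traj)) + 1
  w <- round(params$window / traj_dt(traj))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (params$same_direction_only &&
          traj$directions[i] != traj$directions[j]) next
      seg_j <- traj$positions[k:(k + w), j, , drop = FALSE]
      seg_i <- traj$positions[k:(k + w), i, , drop = FALSE]
      xi <- traj$positions[k, i, ]; xj <- traj$positions[k, j, ]
      dj <- min(sqrt((seg_j[, 1, 1] - xi[1])^2 + (seg_j[, 1, 2] - xi[2])^2))
      di <- min(sqrt((seg_i[, 1, 1] - xj[1])^2 + (seg_i[, 1, 2] - xj[2])^2))
      if (min(di, dj) < params$delta) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  parts <- split(traj$ids, roots)
  parts <- lapply(parts, function(v) sort(as.integer(v)))
  names(parts) <- NULL
  parts[order(vapply(parts, `[`, integer(1), 1L))]
}

# Kaplan-Meier product-limit estimator computed by hand.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# A two-agent free-flow scene in a huge ring (no walls within the horizon).
free_space_scene <- function() {
  list(geometry = corridor_geometry(0.1, 1000),
       params = model_params(),
       position = c(500, 0))
}
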