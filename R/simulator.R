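#' Distance to first collision along a heading
#'
#' Centre travel distance at which pedestrian `i`, moving at speed `v0`
#' along heading `alpha`, first comes into body contact with another
#' pedestrian (extrapolated linearly at its current velocity; bodies are
#' discs) or with a corridor wall. Returns `d_max` when the path is free
#' within the horizon.
#'
#' @param positions N x 2 matrix of agent positions (m).
#' @param velocities N x 2 matrix of agent velocities (m/s).
#' @param body_radii Body disc radii (m), scalar or one per agent.
#' @param i Index of the moving pedestrian.
#' @param alpha Candidate heading (radians).
#' @param v0 Walking speed of pedestrian `i` along the candidate (m/s).
#' @param params A [model_params()].
#' @param geometry A [corridor_geometry()].
#' @return Collision distance in metres, in `[0, d_max]`.
#' @export
collision_distance <- function(positions, velocities, body_radii, i, alpha,
                               v0, params = model_params(),
                               geometry = corridor_geometry()) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  body_radii <- rep_len(body_radii, n)
  cpp_collision_distance(positions, velocities, body_radii, i - 1L, alpha,
                         v0, params$d_max, geometry$r_inner, geometry$r_outer,
                         params$steering_slack)
}

#' Steering decision: desired heading and speed
#'
#' Evaluates candidate headings on a uniform grid spanning the vision field
#' around the looking direction (toward the destination), scores each by the
#' distance-to-destination proxy
#' \eqn{d(\alpha) = \sqrt{d_{max}^2 + f(\alpha)^2 -
#'   2 d_{max} f(\alpha)\cos(\alpha_0 - \alpha)}}
#' where \eqn{f(\alpha)} is the collision distance, and returns the
#' minimising heading. Ties go to the heading closest to the looking
#' direction; exact symmetric ties are broken by a seeded coin flip.
#'
#' @inheritParams collision_distance
#' @param destination Length-2 destination point of pedestrian `i` (m).
#' @return A list (class `steering_decision`) with `alpha_des`, `alpha0`,
#'   `d_h` (collision distance along `alpha_des`), `v_des`, and the sampled
#'   `alpha_samples` / `f_samples` grids.
#' @export
desired_direction <- function(positions, velocities, body_radii, destination,
                              i, v0, params = model_params(),
                              geometry = corridor_geometry()) {
  positions <- as.matrix(positions)
  velocities <- as.matrix(velocities)
  n <- nrow(positions)
  body_radii <- rep_len(body_radii, n)
  if (sum((destination - positions[i, ])^2) < 1e-20) {
    stop("degenerate destination at the pedestrian's current position")
  }
  dec <- cpp_desired_direction(positions, velocities, body_radii,
                               as.numeric(destination), i - 1L, v0,
                               params$d_max,
                               params$vision_half_angle * pi / 180,
                               params$n_directions,
                               geometry$r_inner, geometry$r_outer,
                               params$steering_slack)
  dec$v_des <- desired_speed(v0, dec$d_h, params$tau)
  class(dec) <- "steering_decision"
  dec
}

#' Speed heuristic
#'
#' The desired speed is the comfortable speed capped so that the pedestrian
#' can stop within its relaxation time before the first obstacle:
#' `v_des = min(v0, d_h / tau)`.
#'
#' @param v0 Comfortable speed (m/s).
#' @param d_h Distance to the first obstacle along the desired heading (m).
#' @param tau Relaxation time (s).
#' @return Desired speed (m/s).
#' @export
desired_speed <- function(v0, d_h, tau) {
  stopifnot(v0 >= 0, d_h >= 0, tau > 0)
  pmin(v0, d_h / tau)
}

#' Body and wall contact forces
#'
#' Sum over neighbours of `k_contact * g(r_i + r_j - d_ij) * n_ij` with
#' `g(x) = max(x, 0)` and `n_ij` the unit vector from j to i, plus the
#' analogous wall terms. Zero when nothing overlaps.
#'
#' @inheritParams collision_distance
#' @return Length-2 contact acceleration vector.
#' @export
contact_forces <- function(positions, body_radii, i, params = model_params(),
                           geometry = corridor_geometry()) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  body_radii <- rep_len(body_radii, n)
  cpp_contact_force(positions, body_radii, i - 1L, params$k_contact,
                    geometry$r_inner, geometry$r_outer)
}

#' Destination update
#'
#' The moving destination of a circulating pedestrian: `d_dest` metres away
#' from the current position along the tangent in the attributed sense,
#' refreshed at every integration step.
#'
#' @param position Length-2 position (m).
#' @param direction Circulation sign, +1 or -1.
#' @param d_dest Destination look-ahead distance (m).
#' @return Length-2 destination point.
#' @export
update_destination <- function(position, direction, d_dest = 5) {
  as.numeric(position) + d_dest * tangent_direction(position, direction)
}

#' One integration step of the crowd
#'
#' Synchronous explicit Euler step: accelerations
#' `(v_des e(alpha_des) - v) / tau + F_contact` are computed for all
#' pedestrians from the current state (the contact term vanishes without
#' body or wall overlap), then velocities and positions are updated.
#'
#' @param state List with `positions` and `velocities` (N x 2 matrices).
#' @param pedestrians Data frame with columns `v0`, `direction` and
#'   optionally `body_radius`.
#' @param params A [model_params()].
#' @param geometry A [corridor_geometry()].
#' @return Updated state list.
#' @export
step_crowd <- function(state, pedestrians, params = model_params(),
                       geometry = corridor_geometry()) {
  pos <- as.matrix(state$positions)
  vel <- as.matrix(state$velocities)
  n <- nrow(pos)
  radii <- if (is.null(pedestrians$body_radius)) rep(params$body_radius, n)
           else rep_len(pedestrians$body_radius, n)
  cpp_step(pos, vel, as.integer(pedestrians$direction),
           as.numeric(pedestrians$v0), radii, params$tau,
           params$vision_half_angle * pi / 180, params$d_max,
           params$k_contact, params$d_dest, params$dt, params$n_directions,
           geometry$r_inner, geometry$r_outer, params$steering_slack)
}

# Rejection-sample non-overlapping start positions uniform over the annulus.
sample_start_positions <- function(n, geometry, body_radius,
                                   max_attempts = 2000L * n) {
  lo <- geometry$r_inner + body_radius
  hi <- geometry$r_outer - body_radius
  if (lo >= hi) stop("corridor too narrow for the body radius")
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (a in seq_len(max_attempts)) {
    r <- sqrt(runif(1, lo^2, hi^2))
    th <- runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th))
    ok <- placed == 0L ||
      min(sqrt((pos[seq_len(placed), 1] - p[1])^2 +
               (pos[seq_len(placed), 2] - p[2])^2)) >= 2 * body_radius
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- p
      if (placed == n) return(pos)
    }
  }
  stop("could not place ", n, " non-overlapping pedestrians: corridor too crowded")
}

#' Run a crowd simulation
#'
#' Simulates `n` pedestrians on the ring for `duration` seconds under the
#' heuristic walking model. Half the crowd is attributed each circulation
#' sign (all one sign when `unidirectional = TRUE`); start positions are
#' uniform in the annulus without body overlaps; comfortable speeds are
#' drawn from a truncated Gaussian with mean 1.2 m/s and standard deviation
#' `sigma` (floor 0.3 m/s). Agents start at rest. Fully reproducible from
#' `seed`.
#'
#' @param n Number of pedestrians.
#' @param sigma Standard deviation of comfortable speeds (m/s).
#' @param duration Simulated time (s).
#' @param seed Integer RNG seed.
#' @param params A [model_params()].
#' @param geometry A [corridor_geometry()].
#' @param unidirectional All pedestrians share one circulation sign.
#' @param output_rate Trajectory recording rate (Hz); must divide `1 / dt`.
#' @param mu Mean comfortable speed (m/s).
#' @return A [trajectory_set()].
#' @export
simulate_crowd <- function(n = 60, sigma = 0.16, duration = 60, seed = 1,
                           params = model_params(),
                           geometry = corridor_geometry(),
                           unidirectional = FALSE, output_rate = 10,
                           mu = 1.2) {
  stopifnot(n >= 1, duration > 0)
  set.seed(seed)
  thin <- round(1 / (output_rate * params$dt))
  if (abs(thin * params$dt - 1 / output_rate) > 1e-9) {
    stop("output_rate must be an integer divisor of 1/dt")
  }
  dirs <- if (unidirectional) rep(1L, n) else
    rep_len(c(1L, -1L), n) # alternate signs: floor(n/2)/ceiling(n/2) split
  v0 <- sample_comfortable_speeds(n, mu = mu, sigma = sigma)
  pos0 <- sample_start_positions(n, geometry, params$body_radius)
  n_steps <- round(duration / params$dt)
  arr <- cpp_simulate(pos0, dirs, v0, rep(params$body_radius, n), params$tau,
                      params$vision_half_angle * pi / 180, params$d_max,
                      params$k_contact, params$d_dest, params$dt,
                      params$n_directions, geometry$r_inner,
                      geometry$r_outer, params$steering_slack, n_steps, thin)
  times <- seq(0, by = thin * params$dt, length.out = dim(arr)[1])
  trajectory_set(times, arr, dirs, v0 = v0, geometry = geometry)
}
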