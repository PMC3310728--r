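#' Gaussian-kernel local density at a point
#'
#' \eqn{\rho(x) = \sum_j \exp(-d_{jx}^2 / R^2) / (\pi R^2)}, where
#' \eqn{d_{jx}} is the distance from pedestrian j to `x`. The
#' \eqn{1/(\pi R^2)} normalisation makes the kernel integrate to one, so the
#' plane integral of \eqn{\rho} equals the number of pedestrians.
#'
#' @param positions N x 2 matrix of pedestrian positions (m).
#' @param x Length-2 evaluation point (m).
#' @param kernel_R Gaussian weight scale (m).
#' @return Local density (pedestrians per square metre).
#' @export
local_density_at_point <- function(positions, x, kernel_R = 0.7) {
  stopifnot(kernel_R > 0)
  if (is.null(dim(positions)) || nrow(positions) == 0) return(0)
  positions <- as.matrix(positions)
  d2 <- (positions[, 1] - x[1])^2 + (positions[, 2] - x[2])^2
  sum(exp(-d2 / kernel_R^2)) / (pi * kernel_R^2)
}

# Angular bin centres for n_theta sectors of width 2*pi/n_theta starting at 0.
theta_centres <- function(n_theta) (seq_len(n_theta) - 0.5) * 2 * pi / n_theta

#' Angular density profile of a frame
#'
#' For each angular bin, the mean local density over `n_radial_samples`
#' points evenly spaced across the corridor width along the bin's direction.
#'
#' @param positions N x 2 matrix of pedestrian positions (m).
#' @param geometry A [corridor_geometry()].
#' @param params A [field_params()].
#' @return Numeric vector of length `n_theta`.
#' @export
density_profile <- function(positions, geometry = corridor_geometry(),
                            params = field_params()) {
  thetas <- theta_centres(params$n_theta)
  rs <- seq(geometry$r_inner, geometry$r_outer,
            length.out = params$n_radial_samples)
  vapply(thetas, function(th) {
    pts <- from_polar(rs, th)
    mean(vapply(seq_len(nrow(pts)), function(k) {
      local_density_at_point(positions, pts[k, ], params$kernel_R)
    }, numeric(1)))
  }, numeric(1))
}

#' Radial-speed profile of a frame
#'
#' Mean absolute radial speed |dr/dt| of the pedestrians in each angular
#' sector at time `t`, with velocities obtained by finite-differencing
#' adjacent frames. Empty sectors are `NA` (absence of value, not zero).
#' Radial speed measures lane-leaving (overtaking) manoeuvres: it is near
#' zero when pedestrians walk single file along the ring.
#'
#' @param traj A [trajectory_set()] with at least two frames.
#' @param t Evaluation time on the sampling grid (s).
#' @param params A [field_params()].
#' @return Numeric vector of length `n_theta` (m/s), `NA` where empty.
#' @export
radial_speed_profile <- function(traj, t, params = field_params()) {
  k <- frame_index(traj, t)
  vel <- finite_difference_velocities(traj)[k, , , drop = FALSE]
  radial_speed_from_frame(matrix(traj$positions[k, , ], ncol = 2),
                          matrix(vel[1, , ], ncol = 2), params)
}

radial_speed_from_frame <- function(pos, vel, params) {
  pol <- to_polar(pos)
  u <- abs((pos[, 1] * vel[, 1] + pos[, 2] * vel[, 2]) / pol$r) # |dr/dt|
  sector <- pmin(floor(pol$theta / (2 * pi / params$n_theta)) + 1L,
                 params$n_theta)
  out <- rep(NA_real_, params$n_theta)
  agg <- tapply(u, sector, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Local density and radial-speed maps over angle and time
#'
#' Evaluates \eqn{\rho(\theta, t)} and \eqn{v_r(\theta, t)} on an
#' `n_theta` x time grid at `time_step` spacing.
#'
#' @param traj A [trajectory_set()].
#' @param params A [field_params()].
#' @param geometry Corridor geometry; defaults to the trajectory's own.
#' @return An object of class `field_maps`: list with `theta` (bin centres),
#'   `times`, `density` and `radial_speed` (time x theta matrices, `NA`
#'   marking empty sectors), and `params`.
#' @export
build_field_maps <- function(traj, params = field_params(),
                             geometry = traj$geometry) {
  dt <- traj_dt(traj)
  stride <- round(params$time_step / dt)
  if (stride < 1 || abs(stride * dt - params$time_step) > 1e-6) {
    stop("time_step must be a multiple of the trajectory sampling interval")
  }
  frames <- seq.int(1L, n_frames(traj), by = stride)
  thetas <- theta_centres(params$n_theta)
  rs <- seq(geometry$r_inner, geometry$r_outer,
            length.out = params$n_radial_samples)
  dens <- cpp_density_map(traj$positions, as.integer(frames), thetas, rs,
                          params$kernel_R)
  vel <- finite_difference_velocities(traj)
  vr <- t(vapply(frames, function(k) {
    radial_speed_from_frame(matrix(traj$positions[k, , ], ncol = 2),
                            matrix(vel[k, , ], ncol = 2), params)
  }, numeric(params$n_theta)))
  structure(list(theta = thetas, times = traj$times[frames], density = dens,
                 radial_speed = vr, params = params),
            class = "field_maps")
}

#' @export
print.field_maps <- function(x, ...) {
  cat(sprintf(
    "<field_maps> %d x %d (time x theta) grid over [%.1f, %.1f] s; mean density %.2f / m^2\n",
    nrow(x$density), ncol(x$density), min(x$times), max(x$times),
    mean(x$density)))
  invisible(x)
}

#' Correlation between local density and local radial speed
#'
#' Pearson correlation over all (theta, t) grid cells with `t > t_skip` and
#' a defined radial speed, pairing \eqn{\rho(\theta, t)} with
#' \eqn{v_r(\theta, t)}. A negative coefficient means lane-leaving
#' manoeuvres concentrate in low-density regions (density gaps).
#'
#' @param maps A `field_maps` object.
#' @param t_skip Initial transient to discard (s); defaults to the maps'
#'   field parameters.
#' @return List with `estimate`, `p_value` and `n` (cells used).
#' @export
density_speed_correlation <- function(maps, t_skip = maps$params$t_skip) {
  keep_t <- maps$times > t_skip
  rho <- maps$density[keep_t, , drop = FALSE]
  vr <- maps$radial_speed[keep_t, , drop = FALSE]
  ok <- !is.na(vr)
  if (sum(ok) < 10) stop("fewer than 10 valid (theta, t) cells after t_skip")
  ct <- stats::cor.test(rho[ok], vr[ok], method = "pearson")
  list(estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(ok))
}
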