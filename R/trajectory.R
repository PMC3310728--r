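#' Trajectory container
#'
#' Time-indexed positions of N labelled pedestrians with attributed
#' circulation directions. This is the interchange object between the
#' simulator, the synthetic fixtures and every analysis stage.
#'
#' @param times Strictly increasing, uniformly spaced sampling instants (s).
#' @param positions Numeric array `[frame, pedestrian, 2]` of (x, y) metres.
#' @param directions Integer vector of circulation signs (+1 anti-clockwise,
#'   -1 clockwise), one per pedestrian.
#' @param v0 Optional comfortable speeds (m/s), one per pedestrian.
#' @param geometry A [corridor_geometry()].
#' @param ids Optional integer pedestrian labels (default `1:N`).
#' @return An object of class `trajectory_set`.
#' @export
trajectory_set <- function(times, positions, directions, v0 = NULL,
                           geometry = corridor_geometry(), ids = NULL) {
  times <- as.numeric(times)
  if (length(times) < 1) stop("trajectory_set needs at least one frame")
  if (length(dim(positions)) != 3 || dim(positions)[3] != 2) {
    stop("positions must be a [frame, pedestrian, 2] array")
  }
  if (dim(positions)[1] != length(times)) {
    stop("positions has ", dim(positions)[1], " frames but times has ",
         length(times))
  }
  n <- dim(positions)[2]
  if (length(directions) != n) stop("one direction per pedestrian required")
  if (!all(directions %in% c(-1L, 1L))) stop("directions must be +1 or -1")
  if (!all(is.finite(positions))) stop("positions must be finite")
  if (length(times) > 1) {
    dts <- diff(times)
    if (any(dts <= 0)) stop("times must be strictly increasing")
    if (max(dts) - min(dts) > 1e-6 * max(dts)) {
      stop("non-uniform sampling interval: trajectories must be sampled on ",
           "a regular grid")
    }
  }
  if (!is.null(v0)) {
    if (length(v0) != n || any(v0 <= 0)) stop("v0 must be positive, one per pedestrian")
  }
  if (is.null(ids)) ids <- seq_len(n)
  if (length(ids) != n || anyDuplicated(ids)) stop("ids must be unique, one per pedestrian")
  structure(list(times = times, positions = positions,
                 directions = as.integer(directions), v0 = v0,
                 geometry = geometry, ids = as.integer(ids)),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf(
    "<trajectory_set> %d pedestrians (%d acw / %d cw), %d frames over %.1f s at %.3g Hz\n",
    n_pedestrians(x), sum(x$directions == 1), sum(x$directions == -1),
    n_frames(x), diff(range(x$times)), 1 / traj_dt(x)))
  invisible(x)
}

#' @rdname trajectory_set
#' @param traj A `trajectory_set`.
#' @export
n_frames <- function(traj) dim(traj$positions)[1]

#' @rdname trajectory_set
#' @export
n_pedestrians <- function(traj) dim(traj$positions)[2]

#' @rdname trajectory_set
#' @export
traj_dt <- function(traj) {
  if (length(traj$times) < 2) stop("single-frame trajectory has no sampling interval")
  (traj$times[length(traj$times)] - traj$times[1]) / (length(traj$times) - 1)
}

# Index of the frame at (or nearest to) time t; errors if t is off-grid.
frame_index <- function(traj, t) {
  dt <- if (length(traj$times) > 1) traj_dt(traj) else 1
  k <- round((t - traj$times[1]) / dt) + 1
  if (k < 1 || k > n_frames(traj) || abs(traj$times[k] - t) > 1e-6 + 1e-9 * abs(t)) {
    stop(sprintf("time %g is not on the trajectory sampling grid", t))
  }
  as.integer(k)
}

#' Pedestrian velocities by finite differences
#'
#' Central differences at interior frames, one-sided at the ends.
#'
#' @param traj A [trajectory_set()].
#' @return Array `[frame, pedestrian, 2]` of velocities (m/s).
#' @export
finite_difference_velocities <- function(traj) {
  nt <- n_frames(traj)
  if (nt < 2) stop("cannot differentiate a single-frame trajectory")
  dt <- traj_dt(traj)
  p <- traj$positions
  v <- array(NA_real_, dim = dim(p))
  if (nt > 2) {
    v[2:(nt - 1), , ] <- (p[3:nt, , , drop = FALSE] -
                          p[1:(nt - 2), , , drop = FALSE]) / (2 * dt)
  }
  v[1, , ] <- (p[2, , ] - p[1, , ]) / dt
  v[nt, , ] <- (p[nt, , ] - p[nt - 1, , ]) / dt
  v
}
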