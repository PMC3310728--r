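#' Sample comfortable walking speeds
#'
#' I.i.d. draws from a Gaussian with mean `mu` and standard deviation
#' `sigma`, truncated below at `floor` by resampling. The truncation guards
#' against non-physical near-zero or negative draws at large heterogeneity;
#' at sigma = 0.16 it is essentially never active.
#'
#' @param n Number of draws.
#' @param mu Mean comfortable speed (m/s).
#' @param sigma Standard deviation (m/s); 0 gives a homogeneous crowd.
#' @param floor Lower truncation bound (m/s).
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` speeds, all `>= floor`.
#' @export
sample_comfortable_speeds <- function(n, mu = 1.2, sigma = 0.16, floor = 0.3,
                                      seed = NULL) {
  stopifnot(n >= 1, sigma >= 0, mu > floor, floor >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma == 0) return(rep(mu, n))
  v <- rnorm(n, mu, sigma)
  while (any(bad <- v < floor)) v[bad] <- rnorm(sum(bad), mu, sigma)
  v
}

#' Concentric-lane trajectory fixture
#'
#' Perfectly circular single-file lanes with alternating circulation signs:
#' the ground-truth ordered end-member for the clustering stage. Consecutive
#' members of a lane are `gap_along_lane` metres apart along the lane, so
#' the follow relation holds whenever `gap_along_lane < v * window + delta`.
#'
#' @param n_lanes Number of lanes.
#' @param peds_per_lane Pedestrians per lane.
#' @param lane_radii Lane radii (m); default spreads lanes across the
#'   corridor width with at least 1.2 m radial separation.
#' @param gap_along_lane Arc distance between consecutive lane members (m).
#' @param speed Walking speed of every pedestrian (m/s).
#' @param duration Recording length (s).
#' @param sample_rate Sampling rate (Hz).
#' @param geometry A [corridor_geometry()].
#' @return A [trajectory_set()].
#' @export
make_lane_fixture <- function(n_lanes = 2, peds_per_lane = 5,
                              lane_radii = NULL, gap_along_lane = 0.8,
                              speed = 1.2, duration = 30, sample_rate = 10,
                              geometry = corridor_geometry()) {
  stopifnot(n_lanes >= 1, peds_per_lane >= 1, gap_along_lane > 0, speed > 0)
  if (is.null(lane_radii)) {
    lane_radii <- seq(geometry$r_inner + 0.6, geometry$r_outer - 0.6,
                      length.out = max(n_lanes, 2))[seq_len(n_lanes)]
  }
  stopifnot(length(lane_radii) == n_lanes,
            all(lane_radii > geometry$r_inner),
            all(lane_radii < geometry$r_outer))
  arc_span <- gap_along_lane * peds_per_lane
  if (any(arc_span > 2 * pi * lane_radii)) {
    stop("lane members do not fit on the lane circumference")
  }
  times <- seq(0, duration, by = 1 / sample_rate)
  n <- n_lanes * peds_per_lane
  pos <- array(NA_real_, c(length(times), n, 2))
  dirs <- integer(n)
  idx <- 0L
  for (l in seq_len(n_lanes)) {
    r <- lane_radii[l]
    d <- if (l %% 2 == 1) 1L else -1L
    omega <- d * speed / r
    for (p in seq_len(peds_per_lane)) {
      idx <- idx + 1L
      dirs[idx] <- d
      theta0 <- -d * (p - 1) * gap_along_lane / r # followers trail the leader
      th <- theta0 + omega * times
      pos[, idx, 1] <- r * cos(th)
      pos[, idx, 2] <- r * sin(th)
    }
  }
  trajectory_set(times, pos, dirs, v0 = rep(speed, n), geometry = geometry)
}

#' Dispersed random-walk fixture
#'
#' Independent slow random walks with reflecting walls and uncorrelated
#' headings, alternating circulation labels: the disordered end-member in
#' which follow edges are rare and the cluster count stays high.
#'
#' @param n Number of pedestrians.
#' @param duration Recording length (s).
#' @param seed Integer seed.
#' @param geometry A [corridor_geometry()].
#' @param speed Random-walk step speed (m/s).
#' @param min_separation Minimum initial pairwise distance (m).
#' @param sample_rate Sampling rate (Hz).
#' @return A [trajectory_set()].
#' @export
make_disordered_fixture <- function(n, duration = 30, seed = 1,
                                    geometry = corridor_geometry(),
                                    speed = 0.25, min_separation = 1.2,
                                    sample_rate = 10) {
  set.seed(seed)
  lo <- geometry$r_inner + 0.2
  hi <- geometry$r_outer - 0.2
  pos0 <- matrix(NA_real_, n, 2)
  placed <- 0L
  for (a in seq_len(5000L * n)) {
    r <- sqrt(runif(1, lo^2, hi^2)); th <- runif(1, 0, 2 * pi)
    p <- c(r * cos(th), r * sin(th))
    if (placed == 0L ||
        min(sqrt((pos0[seq_len(placed), 1] - p[1])^2 +
                 (pos0[seq_len(placed), 2] - p[2])^2)) >= min_separation) {
      placed <- placed + 1L
      pos0[placed, ] <- p
      if (placed == n) break
    }
  }
  if (placed < n) stop("packing failure: cannot place ", n,
                       " walkers at separation ", min_separation)
  times <- seq(0, duration, by = 1 / sample_rate)
  pos <- array(NA_real_, c(length(times), n, 2))
  pos[1, , ] <- pos0
  step_len <- speed / sample_rate
  cur <- pos0
  for (f in seq_along(times)[-1]) {
    for (j in seq_len(n)) {
      for (try in 1:25) { # reflecting walls by rejection
        h <- runif(1, 0, 2 * pi)
        cand <- cur[j, ] + step_len * c(cos(h), sin(h))
        rr <- sqrt(sum(cand^2))
        if (rr >= lo && rr <= hi) { cur[j, ] <- cand; break }
      }
    }
    pos[f, , ] <- cur
  }
  trajectory_set(times, pos, rep_len(c(1L, -1L), n), geometry = geometry)
}

#' Switching fixture with known cluster lifetimes
#'
#' Alternates every `period` seconds between two static geometric
#' configurations whose follow-relation partitions are exactly
#' `partition_a` and `partition_b`. Groups are tight arcs around anchors
#' spread along the corridor mid-circle, with anchors of different groups
#' (and of the two phases) separated by well over the clustering threshold,
#' so the partition flips exactly at the switching instants and every
#' completed cluster lifetime equals `period`. A group whose member set
#' appears in both partitions keeps the same anchor and never dies.
#'
#' Designed for follow thresholds `delta <= 1` m and windows up to `period`.
#'
#' @param partition_a,partition_b Lists of integer id vectors; both must
#'   partition the same id set.
#' @param period Switching period (s); a multiple of the sampling interval.
#' @param duration Recording length (s).
#' @param sample_rate Sampling rate (Hz).
#' @param geometry A [corridor_geometry()].
#' @param chain_gap Arc spacing of members within a group (m); must be
#'   below the clustering `delta`.
#' @return A [trajectory_set()].
#' @export
make_switching_fixture <- function(partition_a, partition_b, period = 2,
                                   duration = 20, sample_rate = 10,
                                   geometry = corridor_geometry(),
                                   chain_gap = 0.25) {
  ids <- sort(unlist(partition_a))
  if (!identical(ids, sort(unlist(partition_b)))) {
    stop("the two partitions must cover the same pedestrian ids")
  }
  if (anyDuplicated(unlist(partition_a)) || anyDuplicated(unlist(partition_b))) {
    stop("partitions must be disjoint covers")
  }
  if (abs(period * sample_rate - round(period * sample_rate)) > 1e-9) {
    stop("period must be a multiple of the sampling interval")
  }
  key <- function(g) paste(sort(g), collapse = " ")
  keys_a <- vapply(partition_a, key, character(1))
  keys_b <- vapply(partition_b, key, character(1))
  shared <- intersect(keys_a, keys_b)
  # one anchor per shared group, plus one per phase-specific group
  anchor_keys <- c(shared, paste0("a:", setdiff(keys_a, shared)),
                   paste0("b:", setdiff(keys_b, shared)))
  rm_mid <- (geometry$r_inner + geometry$r_outer) / 2
  spread <- chain_gap * (max(lengths(c(partition_a, partition_b))) - 1)
  needed <- length(anchor_keys) * (spread + 2.0)
  if (needed > 2 * pi * rm_mid) {
    stop("unrealizable partitions: too many groups for the corridor")
  }
  anchor_angle <- setNames((seq_along(anchor_keys) - 1) * 2 * pi /
                             length(anchor_keys), anchor_keys)
  place <- function(group, akey) {
    th <- anchor_angle[[akey]] + (seq_along(group) - 1) * chain_gap / rm_mid
    cbind(rm_mid * cos(th), rm_mid * sin(th))
  }
  spots <- function(partition, keys, tag) {
    out <- matrix(NA_real_, length(ids), 2)
    for (g in seq_along(partition)) {
      k <- keys[g]
      akey <- if (k %in% shared) k else paste0(tag, ":", k)
      out[match(sort(partition[[g]]), ids), ] <- place(sort(partition[[g]]), akey)
    }
    out
  }
  spots_a <- spots(partition_a, keys_a, "a")
  spots_b <- spots(partition_b, keys_b, "b")
  times <- seq(0, duration, by = 1 / sample_rate)
  phase_b <- (floor(times / period + 1e-9) %% 2) == 1
  pos <- array(NA_real_, c(length(times), length(ids), 2))
  for (f in seq_along(times)) {
    pos[f, , ] <- if (phase_b[f]) spots_b else spots_a
  }
  trajectory_set(times, pos, rep(1L, length(ids)), geometry = geometry,
                 ids = ids)
}

#' Add synthetic tracking noise
#'
#' I.i.d. zero-mean Gaussian jitter on every recorded position, emulating
#' motion-capture reconstruction error.
#'
#' @param traj A [trajectory_set()].
#' @param amplitude Jitter standard deviation (m).
#' @param seed Optional integer seed.
#' @return A jittered [trajectory_set()].
#' @export
add_tracking_noise <- function(traj, amplitude, seed = NULL) {
  stopifnot(amplitude >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (amplitude == 0) return(traj)
  traj$positions <- traj$positions +
    array(rnorm(length(traj$positions), 0, amplitude), dim(traj$positions))
  traj
}
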