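#' Follow relation between two pedestrians
#'
#' Pedestrian `j` follows pedestrian `i` at time `t` when j's sampled
#' trajectory over `[t, t + window]` passes at a distance smaller than
#' `delta` from i's position at `t`.
#'
#' @param traj A [trajectory_set()].
#' @param j,i Pedestrian ids (distinct).
#' @param t Evaluation time (s); `t + window` must lie within the recording.
#' @param params A [clustering_params()].
#' @return Logical.
#' @export
is_following <- function(traj, j, i, t, params = clustering_params()) {
  if (i == j) stop("self-following is undefined")
  ci <- match(i, traj$ids)
  cj <- match(j, traj$ids)
  if (is.na(ci) || is.na(cj)) stop("unknown pedestrian id")
  k <- frame_index(traj, t)
  w <- window_frames(traj, params)
  if (k + w > n_frames(traj)) {
    stop("look-ahead window extends past the recording end; skip this frame")
  }
  xi <- traj$positions[k, ci, ]
  seg <- traj$positions[k:(k + w), cj, , drop = FALSE]
  min(sqrt((seg[, 1, 1] - xi[1])^2 + (seg[, 1, 2] - xi[2])^2)) < params$delta
}

window_frames <- function(traj, params) {
  dt <- traj_dt(traj)
  w <- round(params$window / dt)
  if (abs(w * dt - params$window) > 1e-6) {
    stop("clustering window must be a multiple of the trajectory sampling interval")
  }
  as.integer(w)
}

# Connected components of a logical adjacency matrix; returns an integer
# label per node.
component_labels <- function(adj) {
  n <- nrow(adj)
  labels <- integer(n)
  comp <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    comp <- comp + 1L
    stack <- s
    labels[s] <- comp
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- comp
      stack <- c(stack, nb)
    }
  }
  labels
}

# Partition (list of sorted id vectors) at trajectory frame k.
partition_at_frame <- function(traj, k, params) {
  w <- window_frames(traj, params)
  M <- cpp_pairwise_min_dist(traj$positions, k, w)
  adj <- (M < params$delta) | (t(M) < params$delta)
  if (params$same_direction_only) {
    same <- outer(traj$directions, traj$directions, "==")
    adj <- adj & same
  }
  diag(adj) <- FALSE
  labels <- component_labels(adj)
  parts <- split(traj$ids, labels)
  parts <- lapply(parts, function(v) sort(as.integer(v)))
  names(parts) <- NULL
  parts[order(vapply(parts, `[`, integer(1), 1L))]
}

#' Cluster partition at a time
#'
#' Builds the undirected follow graph at time `t` (an edge joins `i` and `j`
#' when either follows the other; by default restricted to pedestrians with
#' the same circulation sign) and returns its connected components. Isolated
#' pedestrians are singleton clusters.
#'
#' @inheritParams is_following
#' @return A list of sorted id vectors forming a partition of all ids.
#' @export
clusters_at <- function(traj, t, params = clustering_params()) {
  k <- frame_index(traj, t)
  if (k + window_frames(traj, params) > n_frames(traj)) {
    stop("look-ahead window extends past the recording end")
  }
  partition_at_frame(traj, k, params)
}

# Frames at which partitions are evaluated: every (sample_rate/eval_rate)-th
# frame from the start, stopping `window` before the recording end.
eval_frames <- function(traj, params) {
  dt <- traj_dt(traj)
  stride <- round(1 / (params$eval_rate * dt))
  if (stride < 1 || abs(stride * dt - 1 / params$eval_rate) > 1e-6) {
    stop("eval_rate must be an integer divisor of the trajectory sampling rate")
  }
  w <- window_frames(traj, params)
  last <- n_frames(traj) - w
  if (last < 1) stop("recording shorter than the clustering window")
  seq.int(1L, last, by = stride)
}

#' Cluster-count time series
#'
#' Number of clusters at every admissible evaluation time. Frames within
#' `window` of the recording end are excluded (no forward trajectory).
#'
#' @inheritParams is_following
#' @return Data frame with columns `time` and `n_clusters`.
#' @export
cluster_count_series <- function(traj, params = clustering_params()) {
  ks <- eval_frames(traj, params)
  counts <- vapply(ks, function(k) length(partition_at_frame(traj, k, params)),
                   integer(1))
  data.frame(time = traj$times[ks], n_clusters = counts)
}

#' Order/disorder phase of a cluster count
#'
#' Five clusters or fewer is an ordered (well-segregated) state; ten or more
#' is disordered; counts in between are intermediate.
#'
#' @param count Integer cluster count(s), >= 1.
#' @return Factor with levels `order`, `intermediate`, `disorder`.
#' @export
classify_phase <- function(count) {
  stopifnot(all(count >= 1))
  factor(ifelse(count <= 5, "order", ifelse(count >= 10, "disorder",
                                            "intermediate")),
         levels = c("order", "intermediate", "disorder"))
}

#' Track cluster identities and lifetimes
#'
#' A cluster's identity is its exact membership set: it is born at the first
#' evaluation time the set appears as a cluster and dies at the first
#' evaluation time it no longer does (any change of composition kills it).
#' Sets still alive at the last admissible evaluation time are right-censored.
#'
#' @inheritParams is_following
#' @return An object of class `cluster_timeline`: list with `eval_times`,
#'   `partitions` (list of partitions), `lifetimes` (completed, s) and
#'   `censored` (right-censored, s).
#' @export
track_lifetimes <- function(traj, params = clustering_params()) {
  ks <- eval_frames(traj, params)
  times <- traj$times[ks]
  partitions <- lapply(ks, function(k) partition_at_frame(traj, k, params))
  birth <- new.env(parent = emptyenv())
  lifetimes <- numeric(0)
  for (f in seq_along(ks)) {
    keys <- vapply(partitions[[f]], paste, character(1), collapse = " ")
    alive <- ls(birth)
    for (key in setdiff(alive, keys)) {
      lifetimes <- c(lifetimes, times[f] - get(key, envir = birth))
      rm(list = key, envir = birth)
    }
    for (key in setdiff(keys, alive)) assign(key, times[f], envir = birth)
  }
  t_end <- times[length(times)]
  censored <- vapply(ls(birth), function(key) t_end - get(key, envir = birth),
                     numeric(1))
  structure(list(eval_times = times, partitions = partitions,
                 lifetimes = sort(lifetimes),
                 censored = sort(unname(censored))),
            class = "cluster_timeline")
}

#' @export
print.cluster_timeline <- function(x, ...) {
  cat(sprintf(
    "<cluster_timeline> %d evaluations over [%.1f, %.1f] s: %d completed lifetimes (median %.1f s), %d censored\n",
    length(x$eval_times), min(x$eval_times), max(x$eval_times),
    length(x$lifetimes),
    if (length(x$lifetimes)) stats::median(x$lifetimes) else NA_real_,
    length(x$censored)))
  invisible(x)
}

#' Kaplan-Meier survival curve of cluster lifetimes
#'
#' The probability p(t) that a cluster is still unchanged t seconds after
#' its birth, estimated by the product-limit estimator over completed and
#' right-censored lifetimes.
#'
#' @param x A `cluster_timeline`, or a data frame with columns `time` and
#'   `event` (1 = composition changed, 0 = censored). Timelines from several
#'   replications can be pooled with [pool_lifetimes()].
#' @return Data frame with columns `time`, `surv` and `n_risk`, starting at
#'   `(0, 1)`; `surv` is non-increasing.
#' @export
survival_curve <- function(x) {
  df <- if (inherits(x, "cluster_timeline")) pool_lifetimes(list(x)) else x
  stopifnot(is.data.frame(df), all(c("time", "event") %in% names(df)))
  if (nrow(df) == 0) stop("no cluster lifetimes observed")
  fit <- survival::survfit(survival::Surv(df$time, df$event) ~ 1)
  data.frame(time = c(0, fit$time), surv = c(1, fit$surv),
             n_risk = c(nrow(df), fit$n.risk),
             n_event = c(0, fit$n.event))
}

#' Pool lifetimes from several cluster timelines
#'
#' @param timelines List of `cluster_timeline` objects.
#' @return Data frame with columns `time` and `event` suitable for
#'   [survival_curve()].
#' @export
pool_lifetimes <- function(timelines) {
  stopifnot(all(vapply(timelines, inherits, TRUE, "cluster_timeline")))
  do.call(rbind, lapply(timelines, function(tl) {
    data.frame(time = c(tl$lifetimes, tl$censored),
               event = rep(c(1, 0), c(length(tl$lifetimes),
                                      length(tl$censored))))
  }))
}

#' Clustering-parameter sensitivity scan
#'
#' Time-averaged cluster count for every combination of distance threshold
#' and look-ahead window, to check that the clustering outcome is stable in
#' a reasonable parameter band.
#'
#' @param traj A [trajectory_set()].
#' @param delta_grid Distance thresholds (m).
#' @param window_grid Look-ahead windows (s).
#' @param params Base [clustering_params()] supplying `eval_rate` and the
#'   direction restriction.
#' @return Matrix of mean cluster counts, rows = `delta_grid`,
#'   columns = `window_grid`.
#' @export
sensitivity_scan <- function(traj, delta_grid, window_grid,
                             params = clustering_params()) {
  stopifnot(all(delta_grid > 0), all(window_grid > 0))
  out <- matrix(NA_real_, length(delta_grid), length(window_grid),
                dimnames = list(delta = format(delta_grid),
                                window = format(window_grid)))
  for (wi in seq_along(window_grid)) {
    p <- params
    p$window <- window_grid[wi]
    ks <- eval_frames(traj, p)
    w <- window_frames(traj, p)
    same <- outer(traj$directions, traj$directions, "==")
    counts <- matrix(0L, length(ks), length(delta_grid))
    for (fi in seq_along(ks)) {
      M <- cpp_pairwise_min_dist(traj$positions, ks[fi], w)
      Mm <- pmin(M, t(M))
      for (di in seq_along(delta_grid)) {
        adj <- Mm < delta_grid[di]
        if (p$same_direction_only) adj <- adj & same
        diag(adj) <- FALSE
        counts[fi, di] <- max(component_labels(adj))
      }
    }
    out[, wi] <- colMeans(counts)
  }
  out
}
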