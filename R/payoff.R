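#' Average directed flow through radial cross-sections
#'
#' Counts crossings of `n_sections` equally spaced radial cross-sections by
#' pedestrians of the given attributed circulation sign moving in that
#' sign's sense (wrong-way excursions do not add), divided by the measuring
#' duration and the number of sections. The first `t_skip` seconds are
#' discarded as transient.
#'
#' @param traj A [trajectory_set()].
#' @param direction_sign Attributed circulation sign, +1 or -1.
#' @param n_sections Number of radial cross-sections.
#' @param t_skip Initial transient to discard (s).
#' @return Flow in crossings per second per section.
#' @export
measure_flow <- function(traj, direction_sign, n_sections = 8, t_skip = 10) {
  stopifnot(direction_sign %in% c(-1, 1))
  keep_t <- traj$times >= t_skip
  if (sum(keep_t) < 2) stop("trajectory too short after discarding t_skip")
  duration <- max(traj$times) - traj$times[keep_t][1]
  if (duration <= 0) stop("zero measuring duration")
  peds <- which(traj$directions == direction_sign)
  if (length(peds) == 0) return(0)
  h <- 2 * pi / n_sections # sections sit at angles k * h
  total <- 0
  for (j in peds) {
    th <- atan2(traj$positions[keep_t, j, 2], traj$positions[keep_t, j, 1])
    dth <- diff(th)
    dth <- (dth + pi) %% (2 * pi) - pi # wrap step to (-pi, pi]
    unw <- cumsum(c(th[1], dth))
    a <- unw[-length(unw)]
    b <- unw[-1]
    if (direction_sign == 1) {
      up <- b > a
      total <- total + sum(floor(b[up] / h) - floor(a[up] / h))
    } else {
      dn <- b < a
      total <- total + sum(floor(a[dn] / h) - floor(b[dn] / h))
    }
  }
  total / duration / n_sections
}

#' Collective payoff of the bidirectional organization
#'
#' \eqn{C = (J_{cw} + J_{acw}) / J_{uni}}: the total bidirectional flow
#' normalised by the flow of a unidirectional crowd at the same density.
#' C = 1 means the two opposing streams organise so well that they match
#' the frictionless single-stream benchmark.
#'
#' @param traj Bidirectional [trajectory_set()].
#' @param j_uni Unidirectional baseline flow (crossings/s/section), e.g.
#'   from [unidirectional_baseline()].
#' @inheritParams measure_flow
#' @return List with `c_payoff`, `j_cw`, `j_acw`, `j_uni`.
#' @export
collective_payoff <- function(traj, j_uni, n_sections = 8, t_skip = 10) {
  if (j_uni <= 0) stop("j_uni must be positive")
  j_acw <- measure_flow(traj, 1, n_sections, t_skip)
  j_cw <- measure_flow(traj, -1, n_sections, t_skip)
  list(c_payoff = (j_cw + j_acw) / j_uni, j_cw = j_cw, j_acw = j_acw,
       j_uni = j_uni)
}

#' Unidirectional baseline flow
#'
#' Mean flow of simulated crowds in which all `n` pedestrians share one
#' circulation sign, at the same density (same `n`, geometry) and the same
#' speed heterogeneity as the bidirectional runs it benchmarks.
#'
#' @param n Number of pedestrians.
#' @param sigma Comfortable-speed standard deviation (m/s).
#' @param duration Simulated time (s).
#' @param seeds Integer seeds; one run per seed, flows averaged.
#' @param params,geometry Model parameters and corridor geometry.
#' @inheritParams measure_flow
#' @return Mean flow (crossings/s/section).
#' @export
unidirectional_baseline <- function(n, sigma, duration = 60,
                                    seeds = c(101, 102, 103),
                                    params = model_params(),
                                    geometry = corridor_geometry(),
                                    n_sections = 8, t_skip = 10) {
  flows <- vapply(seeds, function(s) {
    traj <- simulate_crowd(n = n, sigma = sigma, duration = duration,
                           seed = s, params = params, geometry = geometry,
                           unidirectional = TRUE)
    measure_flow(traj, 1, n_sections, t_skip)
  }, numeric(1))
  mean(flows)
}

#' Individual payoff
#'
#' \eqn{P_i}: the time-averaged projection of pedestrian i's actual velocity
#' on its desired direction (the tangent in its attributed sense),
#' normalised by its comfortable speed. 1 means the pedestrian walks exactly
#' as it wishes; 0 means it is stuck.
#'
#' @param traj A [trajectory_set()] carrying `v0`.
#' @param ids Pedestrian ids (default: all).
#' @param t_skip Initial transient to discard (s).
#' @return Data frame with columns `ped_id`, `v0`, `p_value`.
#' @export
individual_payoff <- function(traj, ids = traj$ids, t_skip = 10) {
  if (is.null(traj$v0)) stop("trajectory carries no comfortable speeds v0")
  keep_t <- traj$times > t_skip
  if (sum(keep_t) < 2) stop("trajectory too short after discarding t_skip")
  vel <- finite_difference_velocities(traj)
  cols <- match(ids, traj$ids)
  p <- vapply(cols, function(j) {
    pos <- traj$positions[keep_t, j, ]
    v <- vel[keep_t, j, ]
    e <- tangent_direction(pos, traj$directions[j])
    mean((v[, 1] * e[, 1] + v[, 2] * e[, 2]) / traj$v0[j])
  }, numeric(1))
  data.frame(ped_id = ids, v0 = traj$v0[cols], p_value = p)
}

#' Speed-heterogeneity sweep of payoffs and cluster stability
#'
#' For each speed heterogeneity level, runs seeded bidirectional
#' simulations, scores each against a sigma-matched unidirectional baseline,
#' bins individual payoffs by comfortable speed (0.1 m/s bins), and pools
#' cluster lifetimes across replications to fit the stretched-exponential
#' relaxation and its T95 lifetime.
#'
#' @param sigma_grid Heterogeneity levels (m/s), e.g. `c(0, 0.1, 0.2, 0.3)`.
#' @param n Number of pedestrians.
#' @param reps Bidirectional replications per level.
#' @param seed Base integer seed; per-run seeds are derived from it.
#' @param duration Simulated time per run (s).
#' @param params,geometry Model parameters and corridor geometry.
#' @param cluster_params A [clustering_params()] for the lifetime analysis
#'   (set to `NULL` to skip the T95 column).
#' @param baseline_reps Unidirectional runs per level.
#' @inheritParams measure_flow
#' @return List with data frames `collective` (sigma, rep, C and flows),
#'   `individual` (sigma, v0 bin, mean payoff, count), `relaxation`
#'   (sigma, kappa, t95) and `baselines` (sigma, j_uni).
#' @export
payoff_vs_sigma_sweep <- function(sigma_grid = c(0, 0.1, 0.2, 0.3), n = 60,
                                  reps = 5, seed = 1, duration = 60,
                                  params = model_params(),
                                  geometry = corridor_geometry(),
                                  cluster_params = clustering_params(),
                                  baseline_reps = 3, n_sections = 8,
                                  t_skip = 10) {
  stopifnot(all(sigma_grid >= 0), reps >= 1)
  collective <- list(); individual <- list(); relax <- list(); base <- list()
  for (si in seq_along(sigma_grid)) {
    sigma <- sigma_grid[si]
    j_uni <- unidirectional_baseline(
      n, sigma, duration,
      seeds = seed * 1000L + si * 100L + seq_len(baseline_reps),
      params = params, geometry = geometry, n_sections = n_sections,
      t_skip = t_skip)
    base[[si]] <- data.frame(sigma = sigma, j_uni = j_uni)
    timelines <- vector("list", reps)
    pay <- vector("list", reps)
    for (ri in seq_len(reps)) {
      traj <- simulate_crowd(n = n, sigma = sigma, duration = duration,
                             seed = seed * 1000L + si * 100L + 50L + ri,
                             params = params, geometry = geometry)
      cp <- collective_payoff(traj, j_uni, n_sections, t_skip)
      collective[[length(collective) + 1L]] <-
        data.frame(sigma = sigma, rep = ri, c_payoff = cp$c_payoff,
                   j_cw = cp$j_cw, j_acw = cp$j_acw)
      pay[[ri]] <- individual_payoff(traj, t_skip = t_skip)
      if (!is.null(cluster_params)) {
        timelines[[ri]] <- track_lifetimes(traj, cluster_params)
      }
    }
    allpay <- do.call(rbind, pay)
    bin <- floor(allpay$v0 / 0.1) * 0.1
    agg <- tapply(allpay$p_value, bin, mean)
    individual[[si]] <- data.frame(sigma = sigma,
                                   v0_bin = as.numeric(names(agg)),
                                   p_mean = as.numeric(agg),
                                   n_ped = as.integer(table(bin)))
    if (!is.null(cluster_params)) {
      fit <- fit_stretched_exponential(survival_curve(pool_lifetimes(timelines)))
      relax[[si]] <- data.frame(sigma = sigma, kappa = fit$kappa,
                                t95 = fit$t95)
    }
  }
  list(collective = do.call(rbind, collective),
       individual = do.call(rbind, individual),
       relaxation = if (length(relax)) do.call(rbind, relax) else NULL,
       baselines = do.call(rbind, base))
}
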