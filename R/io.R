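#' Write / read trajectories as CSV
#'
#' Long-format CSV with header `time_s,ped_id,x_m,y_m,direction` and an
#' optional `v0_mps` column: one row per pedestrian per frame. The corridor
#' geometry travels in two comment lines (`# r_inner_m=...`) at the top.
#'
#' @param traj A [trajectory_set()].
#' @param path Output file path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns a [trajectory_set()].
#' @export
write_trajectory_csv <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# r_inner_m=%.17g", traj$geometry$r_inner), con)
  writeLines(sprintf("# r_outer_m=%.17g", traj$geometry$r_outer), con)
  nt <- n_frames(traj); np <- n_pedestrians(traj)
  df <- data.frame(
    time_s = rep(traj$times, times = np),
    ped_id = rep(traj$ids, each = nt),
    x_m = as.vector(traj$positions[, , 1]),
    y_m = as.vector(traj$positions[, , 2]),
    direction = rep(traj$directions, each = nt))
  if (!is.null(traj$v0)) df$v0_mps <- rep(traj$v0, each = nt)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  header <- readLines(path, n = 10)
  geom_line <- function(key) {
    ln <- grep(paste0("^# ", key, "="), header, value = TRUE)
    if (length(ln)) as.numeric(sub(".*=", "", ln[1])) else NA_real_
  }
  ri <- geom_line("r_inner_m"); ro <- geom_line("r_outer_m")
  geometry <- if (is.finite(ri) && is.finite(ro)) corridor_geometry(ri, ro)
              else corridor_geometry()
  df <- read.csv(path, comment.char = "#")
  required <- c("time_s", "ped_id", "x_m", "y_m", "direction")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed trajectory CSV: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  times <- sort(unique(df$time_s))
  ids <- sort(unique(df$ped_id))
  if (nrow(df) != length(times) * length(ids)) {
    counts <- table(df$ped_id)
    bad <- names(counts)[counts != length(times)][1]
    tmiss <- setdiff(times, df$time_s[df$ped_id == as.numeric(bad)])[1]
    stop(sprintf("pedestrian %s is missing at frame t = %g s", bad, tmiss))
  }
  if (length(times) > 1) {
    dts <- diff(times)
    if (max(dts) - min(dts) > 1e-6 * max(dts)) {
      stop("non-uniform time step in trajectory CSV")
    }
  }
  ord <- order(df$ped_id, df$time_s)
  df <- df[ord, ]
  nt <- length(times); np <- length(ids)
  pos <- array(NA_real_, c(nt, np, 2))
  pos[, , 1] <- matrix(df$x_m, nt, np)
  pos[, , 2] <- matrix(df$y_m, nt, np)
  dirs <- df$direction[seq(1, nrow(df), by = nt)]
  v0 <- if ("v0_mps" %in% names(df)) df$v0_mps[seq(1, nrow(df), by = nt)]
        else NULL
  trajectory_set(times, pos, dirs, v0 = v0, geometry = geometry, ids = ids)
}

#' Read a pipeline configuration
#'
#' JSON file mirroring the parameter constructors field for field:
#' top-level `n`, `sigma`, `duration`, `seed`, and optional objects
#' `geometry`, `model`, `clustering`, `fields` whose entries are passed to
#' [corridor_geometry()], [model_params()], [clustering_params()] and
#' [field_params()].
#'
#' @param path JSON file path.
#' @return A validated config list for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  for (field in c("n", "sigma", "duration", "seed")) {
    if (is.null(cfg[[field]])) stop("pipeline config is missing '", field, "'")
  }
  cfg$geometry <- do.call(corridor_geometry, as.list(cfg$geometry))
  cfg$model <- do.call(model_params, as.list(cfg$model))
  cfg$clustering <- do.call(clustering_params, as.list(cfg$clustering))
  cfg$fields <- do.call(field_params, as.list(cfg$fields))
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate -> cluster -> survival/relaxation fit -> field maps ->
#' density/speed correlation -> payoff against a unidirectional baseline.
#' Deterministic given the config seed.
#'
#' @param config Config list (see [read_pipeline_config()]); entries
#'   missing from the file fall back to package defaults.
#' @param out_dir Optional directory; when given, the trajectory CSV and a
#'   JSON report (with the full config and seeds embedded for provenance)
#'   are written there.
#' @return Report list with cluster-count summary, relaxation fit,
#'   correlation, and payoff entries.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- validate_pipeline_config(config)
  traj <- simulate_crowd(n = cfg$n, sigma = cfg$sigma,
                         duration = cfg$duration, seed = cfg$seed,
                         params = cfg$model, geometry = cfg$geometry)
  tl <- track_lifetimes(traj, cfg$clustering)
  counts <- lengths(tl$partitions)
  fit <- fit_stretched_exponential(survival_curve(tl))
  maps <- build_field_maps(traj, cfg$fields)
  corr <- density_speed_correlation(maps)
  j_uni <- unidirectional_baseline(cfg$n, cfg$sigma, cfg$duration,
                                   seeds = cfg$seed * 1000L + 1:3,
                                   params = cfg$model,
                                   geometry = cfg$geometry)
  pay <- collective_payoff(traj, j_uni)
  plain_cfg <- lapply(cfg, function(x) if (is.object(x)) unclass(x) else x)
  report <- list(
    config = plain_cfg,
    cluster_counts = list(mean = mean(counts), min = min(counts),
                          max = max(counts),
                          phase_fractions = as.list(
                            table(classify_phase(counts)) / length(counts))),
    relaxation = list(a = fit$a, b = fit$b, kappa = fit$kappa,
                      r_squared = fit$r_squared, t95 = fit$t95),
    correlation = corr,
    payoff = pay)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(traj, file.path(out_dir, "trajectories.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
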