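#' Behavioural-model parameters
#'
#' Constants of the heuristic walking model. Defaults are the published
#' calibration of the model on ring-corridor experiments: relaxation time
#' \eqn{\tau} = 0.5 s, vision field of +/- 45 degrees, horizon distance
#' d_max = 10 m, contact stiffness k = 1000 (acceleration per metre of
#' overlap), body radius 0.2 m, destination look-ahead 5 m. `dt` (explicit
#' Euler step, 0.01 s) and `n_directions` (61 candidate headings across the
#' vision field) are discretisation choices of this implementation; the
#' default `dt` resolves the stiff contact spring (natural frequency
#' sqrt(k_contact) ~ 32 rad/s), which a coarser step cannot integrate
#' stably.
#'
#' @param tau Velocity relaxation time, seconds.
#' @param vision_half_angle Half-width of the vision field, degrees (<= 90).
#' @param d_max Horizon distance: collision distances are capped here, metres.
#' @param k_contact Body/wall contact stiffness (acceleration per metre overlap).
#' @param body_radius Pedestrian body disc radius, metres.
#' @param d_dest Distance of the moving tangent destination point, metres.
#' @param dt Integration time step, seconds (must satisfy dt <= tau / 2).
#' @param n_directions Number of candidate headings sampled in the vision field.
#' @param steering_slack Reduction of the combined body diameter used by the
#'   collision anticipation (m). Pedestrians brushing shoulders can rotate
#'   their torso a few centimetres, which rigid body discs cannot express;
#'   without this slack, dense head-on encounters lock into permanent plugs
#'   because a touching body blocks every anticipated path. Contact forces
#'   always act at the full radii. Set to 0 for strict rigid-disc
#'   anticipation.
#' @return An object of class `model_params`.
#' @export
model_params <- function(tau = 0.5, vision_half_angle = 45, d_max = 10,
                         k_contact = 1000, body_radius = 0.2, d_dest = 5,
                         dt = 0.01, n_directions = 61, steering_slack = 0.04) {
  p <- list(tau = tau, vision_half_angle = vision_half_angle, d_max = d_max,
            k_contact = k_contact, body_radius = body_radius, d_dest = d_dest,
            dt = dt, n_directions = as.integer(n_directions))
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && v > 0, TRUE))) {
    stop("all model parameters must be positive scalars")
  }
  stopifnot(is.numeric(steering_slack), steering_slack >= 0,
            steering_slack < 2 * body_radius)
  p$steering_slack <- steering_slack
  if (vision_half_angle > 90) stop("vision_half_angle must be <= 90 degrees")
  if (dt > tau / 2) stop("dt must be <= tau / 2 for a stable Euler update")
  structure(p, class = "model_params")
}

#' Follow-relation clustering parameters
#'
#' A pedestrian j follows pedestrian i at time t when j's trajectory over
#' the next `window` seconds passes within `delta` of i's position at t.
#' Defaults are delta = 0.6 m and window = 1 s; cluster partitions are
#' evaluated at `eval_rate` Hz.
#'
#' @param delta Distance threshold, metres.
#' @param window Forward look-ahead window, seconds.
#' @param eval_rate Cluster evaluation frequency, Hz.
#' @param same_direction_only Restrict follow edges to pedestrians sharing a
#'   circulation sign (default). Lanes are files of uniform walking
#'   direction; allowing cross-direction edges chains opposite streams
#'   through near-passes and erases the disorder signal.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(delta = 0.6, window = 1, eval_rate = 10,
                              same_direction_only = TRUE) {
  stopifnot(is.numeric(delta), delta > 0, is.numeric(window), window > 0,
            is.numeric(eval_rate), eval_rate > 0,
            is.logical(same_direction_only))
  structure(list(delta = delta, window = window, eval_rate = eval_rate,
                 same_direction_only = same_direction_only),
            class = "clustering_params")
}

#' Field-measure parameters
#'
#' Parameters of the local density and local radial speed maps over polar
#' angle and time. Density at a point is a Gaussian-kernel-weighted count,
#' kernel scale `kernel_R` = 0.7 m; the profile at angle theta averages the
#' point density over `n_radial_samples` points spanning the corridor width.
#' Radial speed is averaged per angular sector of width 2*pi/`n_theta`.
#'
#' @param kernel_R Gaussian weight scale, metres.
#' @param n_theta Number of angular bins (default 72, i.e. 5-degree sectors).
#' @param n_radial_samples Radial sample points per direction.
#' @param time_step Map time resolution, seconds.
#' @param t_skip Initial transient discarded before correlations, seconds.
#' @return An object of class `field_params`.
#' @export
field_params <- function(kernel_R = 0.7, n_theta = 72, n_radial_samples = 20,
                         time_step = 0.1, t_skip = 10) {
  stopifnot(kernel_R > 0, n_theta >= 1, n_radial_samples >= 2,
            time_step > 0, t_skip >= 0)
  structure(list(kernel_R = kernel_R, n_theta = as.integer(n_theta),
                 n_radial_samples = as.integer(n_radial_samples),
                 time_step = time_step, t_skip = t_skip),
            class = "field_params")
}
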