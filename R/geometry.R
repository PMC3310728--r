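#' Ring-corridor geometry
#'
#' The experimental arena is an annulus centred at the origin. All positions
#' in the package are Cartesian (x, y) in metres; angles are radians,
#' measured counter-clockwise from the +x axis.
#'
#' @param r_inner Inner wall radius in metres.
#' @param r_outer Outer wall radius in metres.
#' @return An object of class `corridor_geometry`.
#' @examples
#' geom <- corridor_geometry(2, 4.5)
#' corridor_area(geom) # 51.05 m^2
#' @export
corridor_geometry <- function(r_inner = 2, r_outer = 4.5) {
  stopifnot(is.numeric(r_inner), is.numeric(r_outer),
            length(r_inner) == 1, length(r_outer) == 1)
  if (!(r_inner > 0 && r_outer > r_inner)) {
    stop("corridor_geometry requires 0 < r_inner < r_outer")
  }
  structure(list(r_inner = r_inner, r_outer = r_outer),
            class = "corridor_geometry")
}

#' @export
print.corridor_geometry <- function(x, ...) {
  cat(sprintf("<corridor_geometry> annulus r_inner = %g m, r_outer = %g m, area = %.2f m^2\n",
              x$r_inner, x$r_outer, corridor_area(x)))
  invisible(x)
}

#' Walkable surface of the ring corridor
#'
#' @param geometry A [corridor_geometry()].
#' @return Annulus area \eqn{\pi (r_{out}^2 - r_{in}^2)} in square metres.
#' @export
corridor_area <- function(geometry) {
  stopifnot(inherits(geometry, "corridor_geometry"))
  pi * (geometry$r_outer^2 - geometry$r_inner^2)
}

#' Cartesian to polar coordinates
#'
#' @param xy Numeric vector of length 2, or an n x 2 matrix of positions.
#' @return A list with components `r` (radii) and `theta` (angles in
#'   \eqn{[0, 2\pi)}).
#' @export
to_polar <- function(xy) {
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  if (any(r == 0)) stop("to_polar is undefined at the origin")
  theta <- atan2(m[, 2], m[, 1]) %% (2 * pi)
  list(r = r, theta = theta)
}

#' Polar to Cartesian coordinates
#'
#' @param r Radii (metres).
#' @param theta Angles (radians).
#' @return An n x 2 matrix of (x, y) positions.
#' @export
from_polar <- function(r, theta) {
  cbind(x = r * cos(theta), y = r * sin(theta))
}

#' Tangent unit vector along a circulation sense
#'
#' Unit vector perpendicular to the radial direction at `xy`, oriented
#' counter-clockwise for `direction = +1` and clockwise for `direction = -1`.
#' This is the desired walking direction of a pedestrian circling the ring.
#'
#' @param xy Position, length-2 vector or n x 2 matrix.
#' @param direction Circulation sign, +1 (anti-clockwise) or -1 (clockwise);
#'   scalar or one per row.
#' @return Unit vector(s), same shape as `xy`.
#' @export
tangent_direction <- function(xy, direction) {
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  stopifnot(all(direction %in% c(-1, 1)))
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  if (any(r == 0)) stop("tangent_direction is undefined at the origin")
  out <- cbind(-m[, 2], m[, 1]) * direction / r
  if (!is.matrix(xy)) out <- drop(out)
  out
}
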