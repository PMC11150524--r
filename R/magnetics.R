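#' Permanent-magnet source
#'
#' A point-dipole stand-in for the external permanent magnet that steers the
#' drug-loaded nanocarriers. The dipole sits outside the vessel (typically a
#' few millimetres below the lower wall) and its moment vector lies in the
#' simulation plane.
#'
#' @param position numeric length-2, dipole location (m).
#' @param moment_magnitude dipole moment magnitude (A m^2), must be >= 0.
#' @param orientation_angle moment direction, radians from the +x axis.
#' @return an object of class `magnet_source`.
#' @export
magnet_source <- function(position, moment_magnitude, orientation_angle = pi / 2) {
  position <- as.numeric(position)
  if (length(position) != 2L || any(!is.finite(position)))
    stop_ff("magnet position must be a finite length-2 vector")
  if (!is.finite(moment_magnitude) || moment_magnitude < 0)
    stop_ff("moment_magnitude must be >= 0")
  structure(list(position = position,
                 moment_magnitude = as.numeric(moment_magnitude),
                 orientation_angle = as.numeric(orientation_angle)),
            class = "magnet_source")
}

#' Magnetizable carrier medium
#'
#' Constants of the linearly magnetizable blood/nanocarrier suspension:
#' vacuum permeability and the effective (dilute-suspension) volume
#' susceptibility chi. The Kelvin body force scales linearly with chi.
#'
#' @param chi dimensionless magnetic susceptibility, >= 0.
#' @param mu0 vacuum permeability (T m/A).
#' @return an object of class `magnetic_medium`.
#' @export
magnetic_medium <- function(chi = 0.05, mu0 = 4e-7 * pi) {
  if (!is.finite(mu0) || mu0 <= 0) stop_ff("mu0 must be > 0")
  if (!is.finite(chi) || chi < 0) stop_ff("chi must be >= 0")
  structure(list(mu0 = as.numeric(mu0), chi = as.numeric(chi)),
            class = "magnetic_medium")
}

#' Magnetic field of a point dipole
#'
#' Evaluates the dipole field H(r) = (3 (m . rhat) rhat - m) / (4 pi |r|^3)
#' at one or more points in the plane. The magnitude decays as the inverse
#' cube of the distance from the source.
#'
#' @param point length-2 vector or n x 2 matrix of evaluation points (m).
#' @param source a [magnet_source()].
#' @return n x 2 matrix with columns Hx, Hy (A/m).
#' @export
dipole_field <- function(point, source) {
  stopifnot(inherits(source, "magnet_source"))
  pts <- as_xy_matrix(point)
  rx <- pts[, 1] - source$position[1]
  ry <- pts[, 2] - source$position[2]
  r2 <- rx^2 + ry^2
  if (any(r2 == 0)) stop_ff("dipole_field is singular at the source position")
  mx <- source$moment_magnitude * cos(source$orientation_angle)
  my <- source$moment_magnitude * sin(source$orientation_angle)
  r <- sqrt(r2)
  mdotr <- (mx * rx + my * ry) / r2              # (m . rhat)/|r|
  H <- cbind(Hx = (3 * mdotr * rx - mx) / (4 * pi * r2 * r),
             Hy = (3 * mdotr * ry - my) / (4 * pi * r2 * r))
  H
}

#' Field sampler for a magnet source
#'
#' Wraps [dipole_field()] into a `function(points) -> n x 2` sampler, the
#' form consumed by [kelvin_body_force()].
#'
#' @param source a [magnet_source()].
#' @return a function of an n x 2 point matrix.
#' @export
field_sampler <- function(source) {
  force(source)
  function(points) dipole_field(points, source)
}

#' Kelvin magnetic body force on a grid
#'
#' Evaluates the ferrohydrodynamic body-force density
#' F = mu0 chi (H . grad) H at every node of a structured grid. Gradients of
#' H use centred differences in the interior and one-sided differences on the
#' boundary, so a grid needs at least 3 nodes per axis.
#'
#' For a curl-free external field (any magnet model without free currents in
#' the channel) this force is the gradient of mu0 chi |H|^2 / 2; in
#' incompressible flow it is then balanced by the pressure and does not alter
#' the velocity field. It is retained in the momentum equation because the
#' solver makes no assumption about where the sampled field comes from.
#'
#' @param sampler function mapping an n x 2 point matrix to an n x 2 field
#'   matrix (A/m), e.g. [field_sampler()].
#' @param grid a `flow_grid` from [build_grid()].
#' @param medium a [magnetic_medium()].
#' @return object of class `body_force_field` with nx x ny matrices `fx`,
#'   `fy` (N/m^3) and the grid.
#' @export
kelvin_body_force <- function(sampler, grid, medium) {
  stopifnot(inherits(grid, "flow_grid"), inherits(medium, "magnetic_medium"))
  nx <- grid$nx; ny <- grid$ny
  if (nx < 3L || ny < 3L)
    stop_ff("kelvin_body_force needs at least 3 nodes per axis (got %d x %d)", nx, ny)
  pts <- cbind(rep(grid$x, times = ny), rep(grid$y, each = nx))
  H <- sampler(pts)
  if (!all(is.finite(H))) stop_ff("field sampler returned non-finite values")
  Hx <- matrix(H[, 1], nx, ny)
  Hy <- matrix(H[, 2], nx, ny)
  ddx <- function(A) {
    D <- A
    D[2:(nx - 1L), ] <- (A[3:nx, ] - A[1:(nx - 2L), ]) / (2 * grid$dx)
    D[1L, ] <- (A[2L, ] - A[1L, ]) / grid$dx
    D[nx, ] <- (A[nx, ] - A[nx - 1L, ]) / grid$dx
    D
  }
  ddy <- function(A) {
    D <- A
    D[, 2:(ny - 1L)] <- (A[, 3:ny] - A[, 1:(ny - 2L)]) / (2 * grid$dy)
    D[, 1L] <- (A[, 2L] - A[, 1L]) / grid$dy
    D[, ny] <- (A[, ny] - A[, ny - 1L]) / grid$dy
    D
  }
  coef <- medium$mu0 * medium$chi
  fx <- coef * (Hx * ddx(Hx) + Hy * ddy(Hx))
  fy <- coef * (Hx * ddx(Hy) + Hy * ddy(Hy))
  structure(list(grid = grid, fx = fx, fy = fy), class = "body_force_field")
}

#' Zero body force on a grid
#'
#' @param grid a `flow_grid`.
#' @return a `body_force_field` of zeros.
#' @export
zero_body_force <- function(grid) {
  stopifnot(inherits(grid, "flow_grid"))
  z <- matrix(0, grid$nx, grid$ny)
  structure(list(grid = grid, fx = z, fy = z), class = "body_force_field")
}

## The magnet must sit strictly outside the flow domain rectangle.
assert_magnet_outside <- function(source, grid) {
  p <- source$position
  inside <- p[1] >= grid$x_min && p[1] <= grid$x_max &&
    p[2] >= grid$y_min && p[2] <= grid$y_max
  if (inside)
    stop_ff("magnet position (%g, %g) lies inside the flow domain", p[1], p[2])
  invisible(TRUE)
}
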