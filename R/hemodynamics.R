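#' Structured grid specification
#'
#' The vessel segment is a plane channel: x along the vessel axis, y across
#' the gap between the walls. The default extents and resolution give a
#' 425 x 41 node lattice (17,425 nodes) over x in \[-0.14, 0.08\] m and
#' y in \[-0.02, -0.01\] m.
#'
#' @param x_min,x_max,y_min,y_max domain extents (m).
#' @param nx,ny node counts per axis (>= 3).
#' @return object of class `grid_spec`.
#' @export
grid_spec <- function(x_min = -0.14, x_max = 0.08,
                      y_min = -0.02, y_max = -0.01,
                      nx = 425L, ny = 41L) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (!(x_min < x_max) || !(y_min < y_max))
    stop_ff("degenerate grid extents: need x_min < x_max and y_min < y_max")
  if (nx < 3L || ny < 3L) stop_ff("grid needs nx >= 3 and ny >= 3 nodes")
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 nx = nx, ny = ny), class = "grid_spec")
}

#' Build a uniform node lattice
#'
#' @param spec a [grid_spec()].
#' @return object of class `flow_grid` with node coordinate vectors `x`, `y`
#'   (corner nodes coincide with the extents exactly), spacings `dx`, `dy`
#'   and the extents.
#' @export
build_grid <- function(spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  x <- seq(spec$x_min, spec$x_max, length.out = spec$nx)
  y <- seq(spec$y_min, spec$y_max, length.out = spec$ny)
  structure(list(x = x, y = y, nx = spec$nx, ny = spec$ny,
                 dx = (spec$x_max - spec$x_min) / (spec$nx - 1L),
                 dy = (spec$y_max - spec$y_min) / (spec$ny - 1L),
                 x_min = spec$x_min, x_max = spec$x_max,
                 y_min = spec$y_min, y_max = spec$y_max),
            class = "flow_grid")
}

#' Fluid properties
#'
#' Whole blood treated as a Newtonian fluid.
#'
#' @param rho density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @export
fluid_properties <- function(rho = 1050, mu = 3.5e-3) {
  if (!is.finite(rho) || rho <= 0) stop_ff("rho must be > 0")
  if (!is.finite(mu) || mu <= 0) stop_ff("mu must be > 0")
  structure(list(rho = rho, mu = mu), class = "fluid_properties")
}

#' Pulsatile parabolic inlet specification
#'
#' The inlet carries the classic parabolic (Poiseuille) profile modulated by
#' a sinusoidal heartbeat factor `1 + pulse_amplitude * sin(2 pi f t)`. The
#' simulation is a steady snapshot at the phase `phase_time`; the default
#' phase is the systolic peak of a 72 bpm beat, and the default peak velocity
#' is chosen so that the centreline velocity at that phase is 0.500050 m/s.
#'
#' @param u_peak centreline maximum of the unmodulated profile (m/s).
#' @param pulse_amplitude relative pulsation amplitude in \[0, 1).
#' @param pulse_frequency heartbeat frequency (Hz).
#' @param phase_time snapshot time within the beat (s).
#' @export
inlet_spec <- function(u_peak = 0.500050 / 1.02, pulse_amplitude = 0.02,
                       pulse_frequency = 1.2, phase_time = 1 / (4 * 1.2)) {
  if (!is.finite(u_peak) || u_peak <= 0) stop_ff("u_peak must be > 0")
  if (pulse_amplitude < 0 || pulse_amplitude >= 1)
    stop_ff("pulse_amplitude must lie in [0, 1)")
  tf <- 1 + pulse_amplitude * sin(2 * pi * pulse_frequency * phase_time)
  if (tf <= 0) stop_ff("heartbeat time factor must be positive")
  structure(list(u_peak = u_peak, pulse_amplitude = pulse_amplitude,
                 pulse_frequency = pulse_frequency, phase_time = phase_time,
                 time_factor = tf), class = "inlet_spec")
}

#' Inlet velocity profile
#'
#' u(y) = u_peak (1 - ((y - y_c)/h)^2) (1 + a sin(2 pi f t)) with y_c the
#' mid-gap and h the half-gap; zero at both walls.
#'
#' @param y transverse coordinate(s), must lie within the gap.
#' @param spec an [inlet_spec()].
#' @param walls numeric length-2, the wall positions (y_lo, y_hi).
#' @return velocity (m/s), same length as `y`.
#' @export
inlet_profile <- function(y, spec = inlet_spec(), walls = c(-0.02, -0.01)) {
  stopifnot(inherits(spec, "inlet_spec"))
  y_lo <- min(walls); y_hi <- max(walls)
  if (any(y < y_lo - 1e-15) || any(y > y_hi + 1e-15))
    stop_ff("inlet_profile: y outside the channel gap [%g, %g]", y_lo, y_hi)
  y_c <- (y_lo + y_hi) / 2
  h <- (y_hi - y_lo) / 2
  spec$u_peak * (1 - ((y - y_c) / h)^2) * spec$time_factor
}

#' Solver controls
#'
#' @param cfl advective CFL number for the pseudo-time step.
#' @param steady_tol steady-state tolerance on max |du/dt| (m/s^2).
#' @param div_tol acceptable discrete divergence of the converged field (1/s).
#' @param max_steps pseudo-time iteration cap.
#' @param max_reynolds largest channel Reynolds number the laminar scheme
#'   accepts.
#' @export
solver_control <- function(cfl = 0.4, steady_tol = 5e-4, div_tol = 1e-6,
                           max_steps = 20000L, max_reynolds = 2000) {
  structure(list(cfl = cfl, steady_tol = steady_tol, div_tol = div_tol,
                 max_steps = as.integer(max_steps), max_reynolds = max_reynolds),
            class = "solver_control")
}

#' Steady incompressible channel flow with a magnetic body force
#'
#' Solves the steady 2D incompressible Navier-Stokes equations
#' rho U . grad U = div(mu (grad U + grad U^T)) - grad p + F
#' on a staggered (MAC) finite-volume grid by pseudo-time marching with a
#' pressure-projection step (exact discrete incompressibility via a direct
#' sparse Cholesky solve per step). Convection is first-order upwind,
#' diffusion centred; wall cells use quadratic ghost extrapolation so the
#' discrete Poiseuille solution is an exact fixed point of the scheme.
#' Boundary conditions: parabolic Dirichlet inlet, no-slip walls,
#' zero-gradient mass-conserving outlet.
#'
#' @param grid a `flow_grid` from [build_grid()].
#' @param props [fluid_properties()].
#' @param inlet [inlet_spec()].
#' @param force a `body_force_field` on the same grid, or `NULL` for no force.
#' @param control [solver_control()].
#' @return object of class `flow_field`: nodal velocities `u`, `v` (nx x ny,
#'   m/s), cell pressures `p` (Pa), final residual, max discrete divergence
#'   and step count.
#' @export
solve_flow <- function(grid, props = fluid_properties(), inlet = inlet_spec(),
                       force = NULL, control = solver_control()) {
  stopifnot(inherits(grid, "flow_grid"), inherits(props, "fluid_properties"),
            inherits(inlet, "inlet_spec"), inherits(control, "solver_control"))
  if (is.null(force)) force <- zero_body_force(grid)
  stopifnot(inherits(force, "body_force_field"))
  if (!identical(dim(force$fx), c(grid$nx, grid$ny)))
    stop_ff("body force is not defined on the supplied grid")
  if (!all(is.finite(force$fx)) || !all(is.finite(force$fy)))
    stop_ff("body force contains non-finite components")

  nx <- grid$nx; ny <- grid$ny
  Nx <- nx - 1L; Ny <- ny - 1L          # cells
  dx <- grid$dx; dy <- grid$dy
  rho <- props$rho; mu <- props$mu; nu <- mu / rho
  y_c <- (grid$y_min + grid$y_max) / 2
  h <- (grid$y_max - grid$y_min) / 2
  u_max_in <- inlet$u_peak * inlet$time_factor
  Re <- rho * u_max_in * (2 * h) / mu
  if (Re > control$max_reynolds)
    stop_ff("channel Reynolds number %.0f exceeds the laminar scheme limit %.0f",
            Re, control$max_reynolds)

  yc <- grid$y_min + (seq_len(Ny) - 0.5) * dy   # cell-centre y
  xc <- grid$x_min + (seq_len(Nx) - 0.5) * dx   # cell-centre x
  walls <- c(grid$y_min, grid$y_max)

  ## initial state: analytic Poiseuille + matching linear pressure
  upar <- inlet_profile(yc, inlet, walls)
  u <- matrix(rep(upar, each = Nx + 1L), Nx + 1L, Ny)   # u on vertical faces
  v <- matrix(0, Nx, Ny + 1L)                           # v on horizontal faces
  dpdx0 <- -2 * mu * u_max_in / h^2
  p <- matrix(rep(dpdx0 * (xc - grid$x_max), times = Ny), Nx, Ny)

  ## node force -> face force (2-node averages)
  Fxu <- 0.5 * (force$fx[, 1:Ny] + force$fx[, 2:ny])              # (Nx+1) x Ny
  Fyv <- 0.5 * (force$fy[1:Nx, ] + force$fy[2:nx, ])              # Nx x (Ny+1)

  ## pressure-correction Laplacian: Neumann at walls/inlet, Dirichlet at
  ## the outlet face (fixes the pressure level).  Assembled once, factored.
  CH <- Matrix::Cholesky(-poisson_matrix(Nx, Ny, dx, dy))

  dt <- control$cfl * min(dx / max(u_max_in, 1e-12),
                          0.5 / (nu * (1 / dx^2 + 1 / dy^2)))
  iu <- 2:Nx; jv <- 2:Ny
  res <- Inf; step <- 0L
  while (step < control$max_steps) {
    step <- step + 1L
    ## quadratic no-slip ghosts for u beyond the walls
    ugl <- -2 * u[, 1] + u[, 2] / 3
    ugh <- -2 * u[, Ny] + u[, Ny - 1L] / 3
    vgl <- -v[1, ]                 # inlet: v = 0 on the boundary face
    vgh <- v[Nx, ]                 # outlet: zero gradient

    ## ---- u momentum (interior faces i = 2..Nx) ----
    uc <- u[iu, , drop = FALSE]
    dudx <- ifelse(uc >= 0,
                   (uc - u[iu - 1L, , drop = FALSE]) / dx,
                   (u[iu + 1L, , drop = FALSE] - uc) / dx)
    uY <- cbind(ugl[iu], uc, ugh[iu])
    v_at_u <- 0.25 * (v[iu - 1L, 1:Ny] + v[iu, 1:Ny] +
                      v[iu - 1L, 2:(Ny + 1L)] + v[iu, 2:(Ny + 1L)])
    dudy <- ifelse(v_at_u >= 0,
                   (uY[, 2:(Ny + 1L)] - uY[, 1:Ny]) / dy,
                   (uY[, 3:(Ny + 2L)] - uY[, 2:(Ny + 1L)]) / dy)
    lapu <- (u[iu + 1L, ] - 2 * uc + u[iu - 1L, ]) / dx^2 +
            (uY[, 3:(Ny + 2L)] - 2 * uc + uY[, 1:Ny]) / dy^2
    ustar <- u
    ustar[iu, ] <- uc + dt * (-uc * dudx - v_at_u * dudy + nu * lapu -
                              (p[iu, ] - p[iu - 1L, ]) / (dx * rho) +
                              Fxu[iu, ] / rho)
    ## outlet: zero gradient, rescaled for exact global mass balance
    ustar[Nx + 1L, ] <- ustar[Nx, ]
    Qout <- sum(ustar[Nx + 1L, ])
    if (abs(Qout) > 1e-14) ustar[Nx + 1L, ] <- ustar[Nx + 1L, ] * sum(ustar[1, ]) / Qout

    ## ---- v momentum (interior faces j = 2..Ny) ----
    vc <- v[, jv, drop = FALSE]
    vX <- rbind(vgl[jv], vc, vgh[jv])
    u_at_v <- 0.25 * (u[1:Nx, jv - 1L] + u[2:(Nx + 1L), jv - 1L] +
                      u[1:Nx, jv] + u[2:(Nx + 1L), jv])
    dvdx <- ifelse(u_at_v >= 0,
                   (vX[2:(Nx + 1L), ] - vX[1:Nx, ]) / dx,
                   (vX[3:(Nx + 2L), ] - vX[2:(Nx + 1L), ]) / dx)
    dvdy <- ifelse(vc >= 0,
                   (vc - v[, jv - 1L, drop = FALSE]) / dy,
                   (v[, jv + 1L, drop = FALSE] - vc) / dy)
    lapv <- (vX[3:(Nx + 2L), ] - 2 * vc + vX[1:Nx, ]) / dx^2 +
            (v[, jv + 1L] - 2 * vc + v[, jv - 1L]) / dy^2
    vstar <- v
    vstar[, jv] <- vc + dt * (-u_at_v * dvdx - vc * dvdy + nu * lapv -
                              (p[, jv] - p[, jv - 1L]) / (dy * rho) +
                              Fyv[, jv] / rho)
    vstar[, 1] <- 0; vstar[, Ny + 1L] <- 0

    ## ---- projection ----
    div <- (ustar[2:(Nx + 1L), ] - ustar[1:Nx, ]) / dx +
           (vstar[, 2:(Ny + 1L)] - vstar[, 1:Ny]) / dy
    phi <- matrix(as.numeric(Matrix::solve(CH, -(rho / dt) * as.vector(div))), Nx, Ny)
    unew <- ustar
    unew[iu, ] <- ustar[iu, ] - (dt / rho) * (phi[iu, ] - phi[iu - 1L, ]) / dx
    unew[Nx + 1L, ] <- ustar[Nx + 1L, ] - (dt / rho) * (-2 * phi[Nx, ]) / dx
    vnew <- vstar
    vnew[, jv] <- vstar[, jv] - (dt / rho) * (phi[, jv] - phi[, jv - 1L]) / dy
    p <- p + phi

    res <- max(abs(unew - u), abs(vnew - v)) / dt
    u <- unew; v <- vnew
    if (!all(is.finite(u)) || !all(is.finite(v)))
      stop_ff("flow solver diverged (non-finite velocities at step %d)", step)
    if (res <= control$steady_tol) break
  }
  if (res > control$steady_tol)
    stop_ff("flow solver did not reach steady state in %d steps (residual %.3e m/s^2, tolerance %.3e)",
            control$max_steps, res, control$steady_tol)

  div_final <- max(abs((u[2:(Nx + 1L), ] - u[1:Nx, ]) / dx +
                       (v[, 2:(Ny + 1L)] - v[, 1:Ny]) / dy))

  ## face -> node interpolation; Dirichlet boundaries written exactly
  un <- matrix(0, nx, ny); vn <- matrix(0, nx, ny)
  un[, 2:Ny] <- 0.5 * (u[, 1:(Ny - 1L)] + u[, 2:Ny])
  vn[2:Nx, ] <- 0.5 * (v[1:(Nx - 1L), ] + v[2:Nx, ])
  vn[nx, ] <- vn[Nx, ]
  un[1, ] <- inlet_profile(grid$y, inlet, walls)
  un[, 1] <- 0; un[, ny] <- 0; vn[, 1] <- 0; vn[, ny] <- 0; vn[1, ] <- 0

  structure(list(grid = grid, u = un, v = vn, p = p,
                 u_face = u, v_face = v,
                 residual = res, divergence = div_final, steps = step,
                 props = props, inlet = inlet),
            class = "flow_field")
}

## 5-point Laplacian for the pressure correction (cells Nx x Ny, column-major
## by j).  Neumann at walls and inlet, Dirichlet phi = 0 at the outlet face.
poisson_matrix <- function(Nx, Ny, dx, dy) {
  idx <- function(i, j) i + (j - 1L) * Nx
  ig <- rep(seq_len(Nx), times = Ny)
  jg <- rep(seq_len(Ny), each = Nx)
  k <- idx(ig, jg)
  rows <- integer(0); cols <- integer(0)
  dia <- rep(0, Nx * Ny)
  add <- function(sel, off, w) {
    rows <<- c(rows, k[sel]); cols <<- c(cols, k[sel] + off)
    vals <<- c(vals, rep(w, sum(sel)))
    dia[sel] <<- dia[sel] - w
  }
  vals <- numeric(0)
  add(ig > 1L, -1L, 1 / dx^2)
  add(ig < Nx, +1L, 1 / dx^2)
  dia[ig == Nx] <- dia[ig == Nx] - 2 / dx^2      # Dirichlet outlet face
  add(jg > 1L, -Nx, 1 / dy^2)
  add(jg < Ny, +Nx, 1 / dy^2)
  Matrix::sparseMatrix(i = c(rows, k), j = c(cols, k), x = c(vals, dia),
                       dims = c(Nx * Ny, Nx * Ny))
}

#' Export the velocity dataset
#'
#' Flattens a converged flow field into the (x, y, U) table that feeds the
#' machine-learning stage, with U the velocity magnitude sqrt(u^2 + v^2),
#' one row per grid node, and optionally writes it as CSV with header
#' `x,y,U` at full double precision.
#'
#' @param field a `flow_field` from [solve_flow()].
#' @param path optional CSV output path.
#' @return data.frame with columns `x`, `y`, `U` (invisible when writing).
#' @export
export_dataset <- function(field, path = NULL) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$grid
  d <- data.frame(x = rep(g$x, times = g$ny),
                  y = rep(g$y, each = g$nx),
                  U = sqrt(as.vector(field$u)^2 + as.vector(field$v)^2))
  if (!is.null(path)) {
    ok <- tryCatch({
      con <- suppressWarnings(file(path, open = "wt")); on.exit(close(con))
      writeLines("x,y,U", con)
      writeLines(paste(format(d$x, digits = 17, trim = TRUE, scientific = FALSE),
                       format(d$y, digits = 17, trim = TRUE, scientific = FALSE),
                       format(d$U, digits = 17, trim = TRUE), sep = ","), con)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop_ff("could not write dataset to '%s': %s", path,
                             conditionMessage(ok))
    return(invisible(d))
  }
  d
}

#' Read a velocity dataset CSV
#'
#' @param path CSV with header `x,y,U`.
#' @return data.frame with columns `x`, `y`, `U`.
#' @export
read_dataset <- function(path) {
  d <- read.csv(path)
  if (!identical(names(d), c("x", "y", "U")))
    stop_ff("'%s' is not an x,y,U velocity dataset", path)
  d
}
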