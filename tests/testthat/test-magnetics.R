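test_that("dipole field vanishes for a zero moment and is singular at the source", {
  src <- magnet_source(c(0, -0.03), 0, pi / 2)
  expect_equal(dipole_field(c(0.01, -0.015), src), cbind(Hx = 0, Hy = 0))
  src2 <- magnet_source(c(0, -0.03), 1e-3)
  expect_error(dipole_field(c(0, -0.03), src2), "singular")
})

test_that("dipole field is mirror-symmetric about the dipole axis", {
  src <- magnet_source(c(0.5, -1), 2e-3, pi / 2)  # axis along +y
  pts <- cbind(0.5 + c(0.1, 0.25, 0.4), -1 + c(0.3, 0.5, 0.2))
  mirror <- cbind(0.5 - (pts[, 1] - 0.5), pts[, 2])
  H <- dipole_field(pts, src)
  Hm <- dipole_field(mirror, src)
  expect_equal(Hm[, "Hx"], -H[, "Hx"], tolerance = 1e-14)
  expect_equal(Hm[, "Hy"], H[, "Hy"], tolerance = 1e-14)
})

test_that("dipole magnitude decays as the inverse cube of axial distance", {
  src <- magnet_source(c(0, 0), 5e-4, pi / 2)
  r <- 0.004
  H1 <- dipole_field(c(0, r), src)
  H2 <- dipole_field(c(0, 2 * r), src)
  expect_equal(sqrt(sum(H2^2)) / sqrt(sum(H1^2)), 1 / 8, tolerance = 1e-12)
})

test_that("Kelvin force is zero for uniform fields and zero susceptibility", {
  grid <- build_grid(grid_spec(0, 1, 0, 1, 8L, 8L))
  unif <- function(p) cbind(rep(3, nrow(p)), rep(-2, nrow(p)))
  f <- kelvin_body_force(unif, grid, magnetic_medium(chi = 0.2))
  expect_equal(max(abs(f$fx)), 0)
  expect_equal(max(abs(f$fy)), 0)
  src <- magnet_source(c(-0.5, -0.5), 1)
  f0 <- kelvin_body_force(field_sampler(src), grid, magnetic_medium(chi = 0))
  expect_equal(max(abs(f0$fx)), 0)
  expect_equal(max(abs(f0$fy)), 0)
})

test_that("Kelvin force matches a brute-force stencil oracle on a smooth field", {
  grid <- build_grid(grid_spec(0, 1, 0, 1, 20L, 20L))
  smooth <- function(p) cbind(sin(2 * p[, 1] + p[, 2]), cos(p[, 1] - 3 * p[, 2]))
  med <- magnetic_medium(chi = 0.1)
  f <- kelvin_body_force(smooth, grid, med)

  ## naive per-node oracle: same centred stencil written as explicit loops
  nx <- grid$nx; ny <- grid$ny
  ofx <- matrix(NA_real_, nx, ny); ofy <- ofx
  Hat <- function(x, y) smooth(cbind(x, y))
  for (i in 2:(nx - 1L)) for (j in 2:(ny - 1L)) {
    x <- grid$x[i]; y <- grid$y[j]
    H <- Hat(x, y)
    dHdx <- (Hat(grid$x[i + 1L], y) - Hat(grid$x[i - 1L], y)) / (2 * grid$dx)
    dHdy <- (Hat(x, grid$y[j + 1L]) - Hat(x, grid$y[j - 1L])) / (2 * grid$dy)
    ofx[i, j] <- med$mu0 * med$chi * (H[1] * dHdx[1] + H[2] * dHdy[1])
    ofy[i, j] <- med$mu0 * med$chi * (H[1] * dHdx[2] + H[2] * dHdy[2])
  }
  ii <- 2:(nx - 1L); jj <- 2:(ny - 1L)
  expect_equal(f$fx[ii, jj], ofx[ii, jj], tolerance = 1e-12)
  expect_equal(f$fy[ii, jj], ofy[ii, jj], tolerance = 1e-12)

  ## and within 1% of the analytic (H . grad) H at interior nodes
  aHx <- function(x, y) sin(2 * x + y); aHy <- function(x, y) cos(x - 3 * y)
  X <- matrix(grid$x[ii], length(ii), length(jj))
  Y <- matrix(grid$y[jj], length(ii), length(jj), byrow = TRUE)
  afx <- med$mu0 * med$chi * (aHx(X, Y) * 2 * cos(2 * X + Y) + aHy(X, Y) * cos(2 * X + Y))
  afy <- med$mu0 * med$chi * (aHx(X, Y) * -sin(X - 3 * Y) + aHy(X, Y) * 3 * sin(X - 3 * Y))
  expect_lt(max(abs(f$fx[ii, jj] - afx)) / max(abs(afx)), 0.01)
  expect_lt(max(abs(f$fy[ii, jj] - afy)) / max(abs(afy)), 0.01)
})

test_that("Kelvin force is exactly linear in the susceptibility", {
  grid <- build_grid(grid_spec(0, 1, 0, 1, 12L, 12L))
  src <- magnet_source(c(0.5, -0.2), 1e-3, pi / 3)
  f1 <- kelvin_body_force(field_sampler(src), grid, magnetic_medium(chi = 0.05))
  f2 <- kelvin_body_force(field_sampler(src), grid, magnetic_medium(chi = 0.10))
  expect_identical(f2$fx, 2 * f1$fx)
  expect_identical(f2$fy, 2 * f1$fy)
})

test_that("Kelvin force inherits the mirror symmetry of the dipole", {
  ## vertical dipole under the domain centre: fx is odd, fy even, about mid-x
  grid <- build_grid(grid_spec(-1, 1, 0, 1, 21L, 11L))
  src <- magnet_source(c(0, -0.5), 1e-3, pi / 2)
  f <- kelvin_body_force(field_sampler(src), grid, magnetic_medium(chi = 0.1))
  ii <- 2:20  # interior (centred stencils) — symmetric index range about mid-x
  expect_equal(f$fx[ii, ], -f$fx[rev(ii), ], tolerance = 1e-12)
  expect_equal(f$fy[ii, ], f$fy[rev(ii), ], tolerance = 1e-12)
})

test_that("Kelvin force refuses grids below the 3-node stencil minimum", {
  grid <- build_grid(grid_spec(0, 1, 0, 1, 3L, 3L))
  grid$nx <- 2L
  src <- magnet_source(c(-1, -1), 1e-3)
  expect_error(kelvin_body_force(field_sampler(src), grid, magnetic_medium()),
               "at least 3 nodes")
})

test_that("magnet placement inside the flow domain is rejected", {
  grid <- build_grid(grid_spec())
  expect_error(assert_magnet_outside(magnet_source(c(0, -0.015), 1e-3), grid),
               "inside the flow domain")
  expect_silent(assert_magnet_outside(magnet_source(c(0, -0.0225), 1e-3), grid))
})
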