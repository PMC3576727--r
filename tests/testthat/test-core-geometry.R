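ns <- asNamespace("cryopolish")

test_that("rotation_matrix follows the ZYZ convention and group structure", {
  expect_equal(rotation_matrix(pose(0, 0, 0)), diag(3))
  ## matches the brute-force product of elementary rotations
  a <- c(30, 40, 50)
  deg <- pi / 180
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                             0, 0, 1), 3, 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                             sin(t), 0, cos(t)), 3, 3)
  expect_equal(rotation_matrix(a),
               Rz(30 * deg) %*% Ry(40 * deg) %*% Rz(50 * deg),
               tolerance = 1e-12)
  expect_equal(det(rotation_matrix(a)), 1, tolerance = 1e-12)
  ## inverse Euler triplet gives the transpose
  Rinv <- rotation_matrix(c(-50, -40, -30))
  expect_equal(rotation_matrix(a) %*% Rinv, diag(3), tolerance = 1e-12)
  ## homomorphism: R(a) R(b) is a rotation recovered by euler_from_matrix
  set.seed(1)
  for (i in 1:25) {
    Ra <- rotation_matrix(stats::runif(3, -180, 180) * c(1, 0.5, 1))
    Rb <- rotation_matrix(stats::runif(3, -180, 180) * c(1, 0.5, 1))
    Rc <- Ra %*% Rb
    e <- euler_from_matrix(Rc)
    expect_equal(rotation_matrix(e), Rc, tolerance = 1e-9)
  }
  expect_error(rotation_matrix(c(NA, 0, 0)), "invalid pose")
})

test_that("euler_from_matrix inverts rotation_matrix incl. gimbal cases", {
  for (ang in list(c(30, 40, 50), c(-120, 170, 10), c(0, 0, 77),
                   c(12, 180, -40))) {
    R <- rotation_matrix(ang)
    expect_equal(rotation_matrix(euler_from_matrix(R)), R,
                 tolerance = 1e-9)
  }
})

test_that("rotation_distance is a geodesic metric", {
  R <- rotation_matrix(c(10, 20, 30))
  expect_equal(rotation_distance(R, R), 0, tolerance = 1e-6)
  ## a 3-degree rotation about any axis is 3 degrees away
  P <- ns$axis_angle_matrix(c(1, 2, -1), 3)
  expect_equal(rotation_distance(P %*% R, R), 3, tolerance = 1e-9)
})

test_that("pose normalizes angles and validates inputs", {
  p <- pose(190, 20, -200, 1, 2)
  expect_equal(p$rot, -170)
  expect_equal(p$psi, 160)
  expect_true(p$tilt >= 0 && p$tilt <= 180)
  expect_error(pose(0, Inf, 0), "invalid pose")
})

test_that("electron wavelength and CTF zero-frequency limit are correct", {
  expect_equal(electron_wavelength(300), 0.0197, tolerance = 2e-3)
  cp <- ctf_params(25000, amplitude_contrast = 0.1)
  expect_equal(ctf_evaluate(cp, 0), -0.1, tolerance = 1e-12)
  expect_error(ctf_evaluate(cp, -0.01), "must be >= 0")
})

test_that("CTF first zero matches root bracketing of the phase function", {
  cp <- ctf_params(25000, 25000, 0, 300, 2.0, 0.07)
  ## analytic: first zero where gamma = pi - atan(w / sqrt(1 - w^2))
  w <- 0.07
  lambda <- electron_wavelength(300)
  gamma <- function(nu) pi * lambda * nu^2 *
    (25000 - 0.5 * lambda^2 * nu^2 * 2.0 * 1e7)
  target <- pi - atan(w / sqrt(1 - w^2))
  nu_star <- stats::uniroot(function(nu) gamma(nu) - target,
                            c(1e-4, 0.05), tol = 1e-12)$root
  ## brute-force bracketing on ctf_evaluate itself
  nu <- seq(1e-4, 0.05, by = 1e-5)
  v <- ctf_evaluate(cp, nu)
  i <- which(diff(sign(v)) != 0)[1]
  nu_obs <- stats::uniroot(function(x) ctf_evaluate(cp, x),
                           c(nu[i], nu[i + 1]), tol = 1e-12)$root
  expect_equal(nu_obs, nu_star, tolerance = 1e-4)
})

test_that("CTF is bounded in [-1, 1] up to Nyquist", {
  cp <- ctf_params(13000, 38000, 33, 300, 2.0, 0.1)
  nu <- seq(0, 1 / (2 * 1.77), length.out = 500)
  v <- ctf_evaluate(cp, nu, azimuth = 17)
  expect_true(all(v >= -1 - 1e-12 & v <= 1 + 1e-12))
})

test_that("projection at identity equals the axis sum of the volume", {
  ph <- small_phantom()
  pr <- project(ph, pose())
  ax <- apply(ph$values, c(1, 2), sum)
  rel <- sqrt(sum((pr$values - ax)^2) / sum(ax^2))
  expect_lt(rel, 0.02)
})

test_that("projection is linear and maps a blob to its rotated position", {
  ph <- small_phantom()
  p <- pose(25, 70, -10)
  pr1 <- project(ph, p)
  ph2 <- voxel_grid3d(2 * ph$values, ph$voxel_size)
  expect_equal(project(ph2, p)$values, 2 * pr1$values, tolerance = 1e-9)
  expect_equal(project(voxel_grid3d(ph$values * 0, ph$voxel_size),
                       p)$values,
               matrix(0, 32, 32), tolerance = 1e-12)
  ## single Gaussian blob at c appears at (R c)_xy under tilt = 90
  n <- 48
  x <- seq_len(n) - (n / 2 + 1)
  c0 <- c(7, -4, 10)
  r2 <- outer(outer((x - c0[1])^2, (x - c0[2])^2, `+`), (x - c0[3])^2, `+`)
  vol <- voxel_grid3d(exp(-r2 / 8), 1)
  p90 <- pose(0, 90, 0)
  pr <- project(vol, p90)
  ix <- which(pr$values == max(pr$values), arr.ind = TRUE) - (n / 2 + 1)
  pred <- (rotation_matrix(p90) %*% c0)[1:2]
  expect_lt(max(abs(ix - pred)), 1)
})

test_that("apply_shift is exact on band-limited images", {
  im <- bandlimited_image()
  expect_identical(apply_shift(im, 0, 0)$values, im$values)
  ## integer shift moves a delta circularly
  d <- matrix(0, 32, 32); d[17, 17] <- 1
  ds <- apply_shift(pixel_grid2d(d, 1), 3, -2)
  expect_equal(which(abs(ds$values) > 0.5), (17 - 2 - 1) * 32 + 20)
  ## subpixel round trip
  rt <- apply_shift(apply_shift(im, 0.5, -1.3), -0.5, 1.3)
  expect_lt(sqrt(sum((rt$values - im$values)^2) / sum(im$values^2)), 1e-10)
  ## half-pixel shift matches brute-force sinc interpolation on one row
  sh <- apply_shift(im, 0.5, 0)
  row <- 10
  x <- seq_len(32)
  sinc_val <- vapply(x, function(xi) {
    ## periodic (Dirichlet) interpolation of the band-limited image at
    ## the source coordinate xi - 0.5 (content moves +0.5)
    sum(vapply(x, function(j) {
      dx <- (xi - 0.5) - j
      if (abs(dx %% 32) < 1e-12) return(im$values[j, row])
      im$values[j, row] * sin(pi * dx) / (32 * tan(pi * dx / 32))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sh$values[, row], sinc_val, tolerance = 1e-6)
  expect_error(apply_shift(im, 10, 0), "N/4")
})

test_that("MRC round-trips voxel grids and images", {
  ph <- small_phantom()
  f <- tempfile(fileext = ".mrc")
  write_mrc(ph, f)
  back <- read_mrc(f)
  expect_equal(back$voxel_size, ph$voxel_size, tolerance = 1e-6)
  expect_equal(back$values, ph$values, tolerance = 1e-6)
  im <- bandlimited_image()
  write_mrc(im, f)
  im2 <- read_mrc(f)
  expect_s3_class(im2, "pixel_grid2d")
  expect_equal(im2$values, im$values, tolerance = 1e-6)
  unlink(f)
})

test_that("grid constructors validate invariants", {
  expect_error(voxel_grid3d(array(0, c(15, 15, 15)), 1), "even")
  expect_error(voxel_grid3d(array(NA_real_, c(16, 16, 16)), 1), "finite")
  expect_error(pixel_grid2d(matrix(0, 8, 10), 1), "square")
  expect_error(pixel_grid2d(matrix(0, 8, 8), -1), "positive")
})
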