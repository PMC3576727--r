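ns <- asNamespace("cryopolish")

test_that("sampling grids are quasi-uniform and contain their centre", {
  gg <- sampling_grid(15)
  expect_false(gg$local)
  ## pole rings carry a single rot value
  expect_equal(sum(gg$angles[, "tilt"] == 0),
               length(seq(-180, 165, by = 15)))
  lg <- sampling_grid(1, trans_range = 2, trans_step = 1,
                      center = pose(20, 50, -30, 1, -1))
  expect_true(lg$local)
  dmin <- min(vapply(seq_len(nrow(lg$angles)), function(i)
    rotation_distance(matrix(lg$rmats[i, ], 3, 3),
                      rotation_matrix(c(20, 50, -30))), numeric(1)))
  expect_lt(dmin, 1e-9)
  expect_true(any(lg$shifts[, 1] == 1 & lg$shifts[, 2] == -1))
  expect_error(sampling_grid(0), "angular_step > 0")
})

test_that("posterior over the grid is normalized with MAP self-consistency", {
  ph <- small_phantom()
  cp <- ctf_params(22000)
  gg <- sampling_grid(15)
  a0 <- gg$angles[517, ]
  obs <- render_clean(ph, pose(a0[1], a0[2], a0[3]), cp)
  nm <- noise_model(rep(1, 16))
  ar <- likelihood_over_grid(obs, cp, ph, nm, gg)
  expect_equal(sum(ar$gamma), 1, tolerance = 1e-8)
  expect_equal(unname(c(ar$map_pose$rot, ar$map_pose$tilt,
                        ar$map_pose$psi)),
               unname(a0), tolerance = 1e-9)
  expect_error(likelihood_over_grid(obs, cp, ph,
                                    noise_model(rep(0, 16)), gg),
               "zero noise|positive")
})

test_that("duplicate grid points split the posterior and tie-break low", {
  ph <- small_phantom()
  cp <- ctf_params(22000)
  base <- sampling_grid(40)
  dup <- base
  dup$angles <- rbind(base$angles[5, ], base$angles)
  dup$rmats <- rbind(base$rmats[5, ], base$rmats)
  a0 <- base$angles[5, ]
  obs <- render_clean(ph, pose(a0[1], a0[2], a0[3]), cp)
  ar <- likelihood_over_grid(obs, cp, ph, noise_model(rep(1, 16)), dup)
  g <- ar$gamma
  expect_equal(g[1], g[6], tolerance = 1e-9)   # duplicated mass splits
  ## MAP is the first (lowest-index) of the tied pair
  expect_equal(which.max(g), 1)
})

test_that("a 3-pose toy grid matches the brute-force Gaussian likelihood", {
  ## tiny 16x16 problem evaluated independently from first principles
  set.seed(6)
  n <- 16
  ph <- make_phantom(n, 2.0, n_blobs = 5, seed = 3)
  cp <- ctf_params(18000)
  angles <- rbind(c(0, 30, 10), c(100, 70, -50), c(-120, 110, 80))
  obs <- render_clean(ph, pose(100, 70, -50), cp)
  noisy <- pixel_grid2d(obs$values + matrix(rnorm(n * n, 0, 2), n, n),
                        2.0)
  grid <- sampling_grid(5)
  grid$angles <- angles
  grid$rmats <- ns$pose_matrix_rows(angles)
  grid$shifts <- matrix(0, 1, 2)
  nm <- noise_model(rep(4, 8))
  ar <- likelihood_over_grid(noisy, cp, ph, nm, grid, cap = 6)
  ## independent evaluation: direct residual sums on the half-plane
  pl <- ns$half_pixel_list(n, 6)
  X <- ns$image_at_pixels(ns$ft(noisy$values), pl)
  cv <- ns$ctf_at_pixels(cp, pl, 2.0)
  ll <- vapply(1:3, function(i) {
    pr <- project(ph, pose(angles[i, 1], angles[i, 2], angles[i, 3]))
    S <- ns$image_at_pixels(ns$ft(pr$values), pl)
    -sum(pl$weight * abs(X - cv * S)^2 / (2 * 4))
  }, numeric(1))
  gamma_ref <- exp(ll - max(ll))
  gamma_ref <- gamma_ref / sum(gamma_ref)
  expect_equal(as.numeric(ar$gamma), gamma_ref, tolerance = 1e-6)
})

test_that("estimate_noise recovers flat simulator noise and scales", {
  ph <- small_phantom()
  cp <- ctf_params(20000)
  set.seed(12)
  n <- 32
  poses <- lapply(1:40, function(i)
    pose(runif(1, -180, 180), ns$rad2deg(acos(runif(1, -1, 1))),
         runif(1, -180, 180)))
  clean <- lapply(poses, function(p) render_clean(ph, p, cp))
  noisy <- function(s) lapply(clean, function(im)
    pixel_grid2d(im$values + matrix(rnorm(n * n, 0, s), n, n),
                 im$pixel_size))
  nm1 <- estimate_noise(noisy(1), ph, cp, poses)
  expect_equal(mean(nm1$sigma2[3:14]), 1, tolerance = 0.05)
  nm2 <- estimate_noise(noisy(sqrt(2)), ph, cp, poses)
  expect_equal(mean(nm2$sigma2[3:14]) / mean(nm1$sigma2[3:14]), 2,
               tolerance = 0.1)
  ## noiseless data: residual variance tiny relative to signal power
  nm0 <- estimate_noise(clean, ph, cp, poses)
  sig <- mean(ns$shell_power(ns$ft(clean[[1]]$values))[2:10])
  expect_lt(max(nm0$sigma2), 1e-6 * sig)
  expect_error(estimate_noise(clean[1:5], ph, cp, poses[1:5]),
               "at least 10")
})

test_that("reconstruct inverts projection and keeps Hermitian symmetry", {
  set.seed(31)
  n <- 48
  ph <- fixture("recon_phantom", make_phantom(n, 1.77, seed = 1))
  np <- 3000
  proj <- ns$make_projector(ph)
  poses <- lapply(1:np, function(i)
    pose(runif(1, -180, 180), ns$rad2deg(acos(runif(1, -1, 1))),
         runif(1, -180, 180), runif(1, -1.5, 1.5), runif(1, -1.5, 1.5)))
  imgs <- lapply(poses, function(p) project(proj, p))
  rec <- reconstruct(imgs, NULL, poses)
  lp <- function(v) Re(ns$ift(ns$ft(v) *
                                ns$lowpass_transfer(n, 3, 0.8 * (n / 2))))
  expect_gt(cor(as.numeric(lp(rec$values)), as.numeric(lp(ph$values))),
            0.99)
  ## zero input maps to the zero volume
  z <- lapply(1:4, function(i) pixel_grid2d(matrix(0, n, n), 1.77))
  rz <- reconstruct(z, NULL, poses[1:4])
  expect_equal(max(abs(rz$values)), 0)
  expect_error(reconstruct(list(), NULL, list()), "empty")
})

test_that("gold-standard refinement recovers poses on a small dataset", {
  cfg <- sim_config(n_particles = 120, box_size = 32, seed = 19)
  sim <- fixture("small_refine_sim", simulate_dataset(cfg))
  avgs <- lapply(sim$movies, cryopolish:::movie_average)
  ctfs <- lapply(sim$movies, `[[`, "ctf")
  ref <- fixture("small_refine",
                 gold_standard_refine(avgs, ctfs, sim$phantom,
                                      refine_config(max_iter = 5,
                                                    seed = 2)))
  ## half-split is disjoint and exhaustive
  expect_setequal(ref$half, c(1, 2))
  expect_equal(sum(ref$half == 1) + sum(ref$half == 2), 120)
  ## viewing directions broadly recovered (this reduced 32^3/120-particle
  ## problem supports coarser accuracy than the full-scale study)
  errs <- vapply(1:120, function(i) {
    Rt <- rotation_matrix(c(sim$truth$rot[i], sim$truth$tilt[i],
                            sim$truth$psi[i]))
    ns$direction_distance(rotation_matrix(ref$poses[[i]]), Rt)
  }, numeric(1))
  expect_lt(stats::median(errs), 2 * ref$final_angular_step)
  expect_gt(mean(errs < 3 * ref$final_angular_step), 0.75)
  expect_error(gold_standard_refine(avgs[1:50], ctfs[1:50], sim$phantom),
               "100 particles")
})

test_that("refinement from truth at the truth converges immediately", {
  ## noiseless data, reference = phantom: poses land at grid-nearest truth
  cfg <- sim_config(n_particles = 120, box_size = 32, seed = 23,
                    snr_per_dose = 0, trans_total_mean = 0,
                    trans_total_sd = 0, rot_total_mean = 0,
                    rot_total_sd = 0, walk_sd = 0, damage_rate = 0,
                    pick_error_sd = 0)
  sim <- simulate_dataset(cfg)
  avgs <- lapply(sim$movies, cryopolish:::movie_average)
  ctfs <- lapply(sim$movies, `[[`, "ctf")
  ref <- gold_standard_refine(avgs, ctfs, sim$phantom,
                              refine_config(max_iter = 2,
                                            initial_resolution = 2 * 1.77,
                                            seed = 2))
  errs <- vapply(1:120, function(i) {
    Rt <- rotation_matrix(c(sim$truth$rot[i], sim$truth$tilt[i],
                            sim$truth$psi[i]))
    rotation_distance(rotation_matrix(ref$poses[[i]]), Rt)
  }, numeric(1))
  ## every pose within the sampling spacing of its grid
  expect_lt(stats::quantile(errs, 0.95), 1.5 * ref$final_angular_step)
})

test_that("noise-only half maps show no spurious correlation", {
  set.seed(41)
  n <- 32
  imgs <- lapply(1:200, function(i)
    pixel_grid2d(matrix(rnorm(n * n, 0, 10), n, n), 1.77))
  ctfs <- lapply(1:200, function(i) ctf_params(runif(1, 13000, 38000)))
  ph <- small_phantom()
  ref <- gold_standard_refine(imgs, ctfs, ph,
                              refine_config(max_iter = 3, seed = 5))
  ## beyond 20 A the FSC fluctuates about zero
  sel <- 1 / ref$final_fsc$freq < 20
  expect_lt(abs(mean(ref$final_fsc$fsc[sel])), 0.05)
})
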