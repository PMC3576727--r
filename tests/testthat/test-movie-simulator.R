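ns <- asNamespace("cryopolish")

test_that("make_phantom is deterministic, validated, and asymmetric", {
  p1 <- make_phantom(32, 1.77, n_blobs = 20, seed = 9)
  p2 <- make_phantom(32, 1.77, n_blobs = 20, seed = 9)
  expect_identical(p1$values, p2$values)
  expect_error(make_phantom(32, 1.77, n_blobs = 0), ">= 3")
  expect_error(make_phantom(33, 1.77), "even")
  ## no point-group symmetry: best non-identity rotational self-match
  ## over a coarse exhaustive grid stays well below self-correlation
  ph <- make_phantom(64, 1.77, n_blobs = 30, seed = 1)
  proj <- ns$make_projector(ph)
  grid <- sampling_grid(20)
  keep <- apply(grid$angles, 1, function(a)
    rotation_distance(rotation_matrix(a)) > 10)
  pl <- ns$half_pixel_list(64, 20)
  S <- ns$grid_slices(proj, grid, pl)$S
  ref <- S[which(!keep)[1], ]  # identity-equivalent row
  self <- Re(sum(ref * Conj(ref)))
  cc <- apply(S[keep, ], 1, function(s)
    Re(sum(s * Conj(ref))) / sqrt(Re(sum(s * Conj(s))) * self))
  expect_lt(max(cc), 0.9)
})

test_that("sampled trajectories match the configured motion statistics", {
  cfg <- sim_config(n_frames = 16)
  ## zero-motion config gives the all-zero trajectory
  cfg0 <- sim_config(trans_total_mean = 0, trans_total_sd = 0,
                     rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0)
  tr0 <- sample_trajectory(cfg0, seed = 3)
  expect_equal(max(abs(tr0$trans)), 0)
  expect_equal(max(abs(tr0$rot_euler)), 0)
  ## dose-weighted mean re-centering
  tr <- sample_trajectory(cfg, seed = 5)
  expect_lt(max(abs(colMeans(tr$trans))), 1e-9)
  ## 4,000 draws: realized total translation and rotation moments match
  ## the configured 4.2 +/- 2.3 A and 1.7 +/- 1.2 deg within 5%
  tots <- t(vapply(1:4000, function(i) {
    t <- sample_trajectory(cfg, seed = 10000 + i)
    c(sqrt(sum((t$trans[16, ] - t$trans[1, ])^2)), t$total_rot)
  }, numeric(2)))
  expect_equal(mean(tots[, 1]), 4.2, tolerance = 0.05 * 4.2 / 4.2)
  expect_equal(sd(tots[, 1]), 2.3, tolerance = 0.05)
  expect_equal(mean(tots[, 2]), 1.7, tolerance = 0.05)
  expect_equal(sd(tots[, 2]), 1.2, tolerance = 0.05)
})

test_that("rendered movies follow the imaging model", {
  ph <- small_phantom()
  cfg <- sim_config(n_particles = 1, box_size = 32, snr_per_dose = 0,
                    trans_total_mean = 0, trans_total_sd = 0,
                    rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0,
                    damage_rate = 0)
  tr <- sample_trajectory(cfg, seed = 1)
  cp <- ctf_params(25000)
  p <- pose(40, 60, -30)
  mv <- render_movie(ph, p, tr, cfg, ctf = cp, seed = 2)
  ## noiseless, motionless, damage-free: every frame identical to the
  ## CTF-filtered projection
  clean <- render_clean(ph, p, cp)
  for (k in c(1, 8, 16))
    expect_equal(mv$frames[[k]]$values, clean$values, tolerance = 1e-9)
  ## independent-noise arithmetic: the 16-frame sum has 16x the signal
  ## amplitude and 16x the noise variance of one frame
  cfgn <- sim_config(n_particles = 1, box_size = 32,
                     trans_total_mean = 0, trans_total_sd = 0,
                     rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0,
                     damage_rate = 0)
  mvn <- render_movie(ph, p, sample_trajectory(cfgn, seed = 1), cfgn,
                      ctf = cp, seed = 7)
  tot <- Reduce(`+`, lapply(mvn$frames, `[[`, "values"))
  resid1 <- mvn$frames[[1]]$values - clean$values
  residsum <- tot - 16 * clean$values
  expect_equal(var(as.numeric(residsum)) / var(as.numeric(resid1)), 16,
               tolerance = 0.15)
  ## damage: high-shell/low-shell power ratio drops from frame 1 to 16
  cfgd <- sim_config(n_particles = 1, box_size = 32, snr_per_dose = 0,
                     trans_total_mean = 0, trans_total_sd = 0,
                     rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0,
                     damage_rate = 8)
  mvd <- render_movie(ph, p, sample_trajectory(cfgd, seed = 1), cfgd,
                      ctf = cp, seed = 2)
  ratio <- function(img) {
    pw <- ns$shell_power(ns$ft(img$values))
    sum(pw[9:14]) / sum(pw[2:5])
  }
  expect_lt(ratio(mvd$frames[[16]]), ratio(mvd$frames[[1]]))
  expect_error(render_movie(make_phantom(16, 1.0, seed = 1), p, tr, cfg),
               "box sizes differ|voxel size")
})

test_that("simulate_dataset emits consistent truth and tilt pairs", {
  cfg <- sim_config(n_particles = 6, box_size = 32, tilt_angle = 10,
                    tilt_axis_azimuth = 30, seed = 21)
  ds <- simulate_dataset(cfg)
  expect_length(ds$movies, 12)
  expect_equal(nrow(ds$truth), 12)
  ## per-frame dose metadata: total_dose / F <= 1 e/A^2 with defaults
  expect_equal(unique(ds$truth$per_frame_dose), 1)
  ## tilt mode: relative rotation between pair poses is exactly 10 deg
  for (i in 1:6) {
    Ru <- rotation_matrix(c(ds$truth$rot[i], ds$truth$tilt[i],
                            ds$truth$psi[i]))
    Rt <- rotation_matrix(c(ds$truth$rot[i + 6], ds$truth$tilt[i + 6],
                            ds$truth$psi[i + 6]))
    expect_equal(rotation_distance(Rt, Ru), 10, tolerance = 1e-6)
  }
  ## determinism: identical truth on re-run
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$truth, ds2$truth)
  expect_identical(ds$movies[[3]]$frames[[5]]$values,
                   ds2$movies[[3]]$frames[[5]]$values)
})

test_that("true viewing directions are uniform over the sphere", {
  cfg <- sim_config(n_particles = 4000, box_size = 16, seed = 3)
  poses <- cryopolish:::with_seed(cryopolish:::child_seed(3, "poses"), {
    data.frame(tilt = ns$rad2deg(acos(stats::runif(4000, -1, 1))))
  })
  ## E|cos(tilt)| = 1/2 for uniform directions
  expect_equal(mean(abs(cos(ns$deg2rad(poses$tilt)))), 0.5,
               tolerance = 0.02)
})

test_that("noise is independent across frames", {
  ph <- make_phantom(48, 1.77, seed = 2)
  cfg <- sim_config(n_particles = 1, box_size = 48,
                    trans_total_mean = 0, trans_total_sd = 0,
                    rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0,
                    damage_rate = 0)
  cp <- ctf_params(20000)
  p <- pose(10, 50, 70)
  mv <- render_movie(ph, p, sample_trajectory(cfg, seed = 1), cfg,
                     ctf = cp, seed = 31)
  clean <- render_clean(ph, p, cp)
  res <- lapply(mv$frames, function(f) as.numeric(f$values - clean$values))
  ## 8 disjoint frame pairs pooled: > 1.8e4 pixel pairs
  a <- unlist(res[seq(1, 15, 2)])
  b <- unlist(res[seq(2, 16, 2)])
  expect_lt(abs(cor(a, b)), 0.01)
})
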