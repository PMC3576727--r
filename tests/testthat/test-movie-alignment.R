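ns <- asNamespace("cryopolish")

## small movie fixture for window/partition arithmetic: constant frames
## whose value equals the frame index
index_movie <- function(f = 16, n = 16) {
  frames <- lapply(seq_len(f), function(k)
    pixel_grid2d(matrix(as.numeric(k), n, n), 1.77))
  structure(list(frames = frames, per_frame_dose = rep(1, f),
                 particle_id = 1L, micrograph_id = 1L,
                 picked_x = 0, picked_y = 0, ctf = ctf_params(20000)),
            class = "particle_movie")
}

test_that("running averages use truncated centred windows", {
  mv <- index_movie(16)
  ra <- running_average(mv, 5)
  expect_length(ra, 16)
  expect_equal(ra[[8]]$values[1, 1], mean(6:10))   # = 8
  expect_equal(ra[[1]]$values[1, 1], mean(1:3))    # = 2
  expect_equal(ra[[16]]$values[1, 1], mean(14:16))
  ## W = 1 reproduces the input frames
  r1 <- running_average(mv, 1)
  for (k in c(1, 7, 16))
    expect_identical(r1[[k]]$values, mv$frames[[k]]$values)
  ## W = F (odd case): the middle frame sees the global mean, edge
  ## frames their truncated windows
  mv15 <- index_movie(15)
  r15 <- running_average(mv15, 15)
  expect_equal(r15[[8]]$values[1, 1], mean(1:15))
  expect_equal(r15[[1]]$values[1, 1], mean(1:8))
  expect_equal(r15[[15]]$values[1, 1], mean(8:15))
  expect_error(running_average(mv, 4), "odd")
  expect_error(running_average(mv, 17), "1..F")
})

test_that("partition averages cover all frames with the remainder rule", {
  mv <- index_movie(16)
  p4 <- partition_average(mv, 4)
  expect_length(p4, 4)
  expect_equal(attr(p4, "frames"), list(1:4, 5:8, 9:12, 13:16))
  expect_equal(vapply(p4, function(x) x$values[1, 1], numeric(1)),
               c(mean(1:4), mean(5:8), mean(9:12), mean(13:16)))
  ## width 16 gives the exposure average
  p16 <- partition_average(mv, 16)
  expect_length(p16, 1)
  expect_equal(p16[[1]]$values[1, 1], mean(1:16))
  ## width 6: the final block overlaps so every frame is used
  p6 <- partition_average(mv, 6)
  expect_equal(attr(p6, "frames"), list(1:6, 7:12, 11:16))
})

test_that("prior weight is a joint Gaussian with maximum 1 at the centre", {
  ctr <- pose(10, 60, -30, 0.5, -0.5)
  pr <- orientation_prior(ctr, sigma_angle = 1, sigma_trans = 1)
  expect_equal(prior_weight(ctr, pr), 1)
  ## one-sigma rotation: weight exp(-1/2)
  P <- ns$axis_angle_matrix(c(1, 1, 0), 1)
  e <- euler_from_matrix(P %*% rotation_matrix(ctr))
  cand <- pose(e[1], e[2], e[3], 0.5, -0.5)
  expect_equal(prior_weight(cand, pr), exp(-0.5), tolerance = 1e-6)
  ## translation-only displacement
  cand2 <- pose(10, 60, -30, 1.5, -0.5)
  expect_equal(prior_weight(cand2, pr), exp(-0.5), tolerance = 1e-9)
  ## flat limit: infinite widths weight everything 1
  flat <- orientation_prior(ctr, sigma_angle = 1e9, sigma_trans = 1e9)
  expect_equal(prior_weight(pose(13, 58, -29, 2, 1), flat), 1,
               tolerance = 1e-6)
  expect_error(orientation_prior(ctr, sigma_angle = 0), "sigma_angle")
})

test_that("with constant likelihood the posterior equals the prior", {
  ## a zero reference makes every candidate equally likely, so the
  ## posterior over the grid must reproduce the normalized prior weights
  n <- 32
  zero_ref <- voxel_grid3d(array(0, c(n, n, n)), 1.77)
  ctr <- pose(20, 80, 10)
  pr <- orientation_prior(ctr, sigma_angle = 1, sigma_trans = 1,
                          angle_range = 1.8, angle_step = 0.9,
                          trans_range = 1, trans_step = 1)
  pg <- ns$prior_grid(pr)
  set.seed(3)
  img <- pixel_grid2d(matrix(rnorm(n * n), n, n), 1.77)
  ar <- likelihood_over_grid(img, ctf_params(20000), zero_ref,
                             noise_model(rep(1, 16)), pg$grid,
                             cap = 8, logprior = pg$logprior)
  ref_post <- exp(pg$logprior - max(pg$logprior))
  ref_post <- ref_post / sum(ref_post)
  expect_equal(as.numeric(ar$gamma), as.numeric(ref_post),
               tolerance = 1e-10)
})

test_that("align_frames tracks a linear drift and respects prior limits", {
  cfg <- sim_config(n_particles = 1, box_size = 48, seed = 71,
                    trans_total_mean = 4 * 1.77, trans_total_sd = 0,
                    rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0)
  sim <- fixture("drift_sim_small", {
    cfgs <- sim_config(n_particles = 15, box_size = 48, seed = 71,
                       trans_total_mean = 4 * 1.77, trans_total_sd = 0,
                       rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0)
    simulate_dataset(cfgs)
  })
  nm <- cryopolish:::initial_noise(lapply(sim$movies,
                                          function(m) m$frames[[1]]))
  proj <- ns$make_projector(sim$phantom)
  sq <- c()
  dev_line <- c()
  for (i in 1:15) {
    tr <- sim$trajectories[[i]]
    ctr <- pose(sim$truth$rot[i], sim$truth$tilt[i], sim$truth$psi[i],
                sim$truth$offset_x[i], sim$truth$offset_y[i])
    ftr <- align_frames(sim$movies[[i]], proj,
                        orientation_prior(ctr, sigma_trans = 1), nm,
                        W = 5)
    ex <- ftr$track$offset_x - ctr$offset_x
    ey <- ftr$track$offset_y - ctr$offset_y
    tx <- tr$trans[, 1] / 1.77
    ty <- tr$trans[, 2] / 1.77
    sq <- c(sq, (ex - tx)^2, (ey - ty)^2)
    ## smoothness: deviation from the straight-line fit of the track
    fit <- stats::lm.fit(cbind(1, 1:16), cbind(ex, ey))
    dev_line <- c(dev_line, as.numeric(fit$residuals))
  }
  expect_lt(sqrt(mean(sq)), 0.75)
  expect_lt(sqrt(mean(dev_line^2)), 1)
  ## a vanishing angular prior keeps every frame at the centre angles
  i <- 1
  ctr <- pose(sim$truth$rot[i], sim$truth$tilt[i], sim$truth$psi[i])
  tight <- orientation_prior(ctr, sigma_angle = 1e-4, sigma_trans = 1,
                             angle_range = 0.9, angle_step = 0.45)
  ftr <- align_frames(sim$movies[[i]], proj, tight, nm, W = 5)
  expect_lt(max(vapply(1:16, function(k)
    rotation_distance(cryopolish:::track_pose(ftr, k), ctr),
    numeric(1))), 1e-3)
  ## centre beyond the box quarter is rejected
  bad <- orientation_prior(pose(0, 0, 0, 11, 0), sigma_trans = 1)
  expect_error(align_frames(sim$movies[[1]], proj, bad, nm), "reach")
})

test_that("polishing a zero-motion movie set changes nothing material", {
  cfg <- sim_config(n_particles = 8, box_size = 32, seed = 41,
                    trans_total_mean = 0, trans_total_sd = 0,
                    rot_total_mean = 0, rot_total_sd = 0, walk_sd = 0,
                    pick_error_sd = 0)
  sim <- simulate_dataset(cfg)
  nm <- cryopolish:::initial_noise(lapply(sim$movies,
                                          function(m) m$frames[[1]]))
  proj <- ns$make_projector(sim$phantom)
  tracks <- lapply(1:8, function(i) {
    ctr <- pose(sim$truth$rot[i], sim$truth$tilt[i], sim$truth$psi[i])
    align_frames(sim$movies[[i]], proj,
                 orientation_prior(ctr, sigma_trans = 0.5), nm, W = 5)
  })
  ## assigned poses stay within one grid step of the centre
  for (i in 1:8) {
    ctr <- pose(sim$truth$rot[i], sim$truth$tilt[i], sim$truth$psi[i])
    dr <- vapply(1:16, function(k)
      rotation_distance(cryopolish:::track_pose(tracks[[i]], k), ctr),
      numeric(1))
    expect_lt(max(dr), 0.9)
    expect_lt(max(abs(tracks[[i]]$track$offset_x)), 0.75)
  }
  ## polished reconstruction runs and returns finite half maps + FSC
  half <- rep(c(1, 2), each = 4)
  rec <- polish_reconstruct(sim$movies, tracks, half)
  expect_true(all(is.finite(rec$half_maps[[1]]$values)))
  expect_s3_class(rec$fsc, "fsc_curve")
  expect_true(rec$resolution >= 2 * 1.77)
  ## degenerate single-movie input still runs
  rec1 <- polish_reconstruct(sim$movies[1], tracks[1], 1)
  expect_true(all(is.finite(rec1$half_maps[[2]]$values)))
  expect_error(polish_reconstruct(sim$movies, tracks[1:3], half),
               "differ in length")
})
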