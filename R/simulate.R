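## Dose-fractionated particle-movie simulator with known ground truth.
##
## The generator emulates the acquisition used to develop the method:
## 16-frame movies recorded during a 1-s exposure at a total dose of
## 16 e/A^2 (so each frame integrates <= 1 e/A^2), 1.77 A pixels, 300 kV,
## defocus between 1.3 and 3.8 um, optional tilt pairs at 0/10 degrees,
## beam-induced motion with total exposure magnitudes of 1.7 +/- 1.2 deg
## and 4.2 +/- 2.3 A, and a dose-dependent B-factor damage envelope.

## run `expr` under a private RNG stream; restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## derive a bounded child seed for a named substream
child_seed <- function(seed, label, i = 0L) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.numeric(seed) * 7919 + h * 131 + as.numeric(i)) %% 2147483629
}

#' Simulation configuration
#'
#' Defaults are the acquisition conditions the package is developed
#' against: F = 16 frames at a total dose of 16 e/A^2 (1 e/A^2 per frame),
#' 1.77 A pixels, 300 kV, defocus 1.3-3.8 um, total in-exposure motion of
#' 1.7 +/- 1.2 degrees and 4.2 +/- 2.3 A, tilt pairs at 10 degrees when
#' enabled.  `snr_per_dose` is the per-pixel variance SNR contributed per
#' e/A^2 of dose (0.05 by default): a 1 e/A^2 frame has SNR 0.05 and the
#' 16 e/A^2 exposure average SNR 0.8; SNR is linear in dose.
#' `damage_rate` is the B-factor accumulated per e/A^2 of dose
#' (A^2 per e/A^2).
#'
#' @param n_particles number of particles
#' @param n_frames frames per movie (F)
#' @param box_size image/box side in pixels (even)
#' @param pixel_size A per pixel
#' @param total_dose electrons/A^2 over the whole exposure
#' @param defocus_range defocus min/max in Angstrom
#' @param voltage kV
#' @param spherical_aberration mm
#' @param amplitude_contrast fraction
#' @param trans_total_mean,trans_total_sd exposure-total translation (A)
#' @param rot_total_mean,rot_total_sd exposure-total rotation (degrees)
#' @param walk_sd per-frame random-walk step (A)
#' @param damage_rate A^2 of B-factor per e/A^2 of accumulated dose
#' @param snr_per_dose per-pixel variance SNR per e/A^2 of dose
#' @param pick_error_sd picking error (pixels) on particle centres
#' @param tilt_angle tilt-pair geometry in degrees, or NULL for untilted
#' @param tilt_axis_azimuth in-plane tilt-axis direction, degrees
#' @param n_blobs phantom complexity
#' @param particles_per_micrograph grouping used for micrograph ids
#' @param seed master seed; every stage derives a named substream from it
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_particles = 100, n_frames = 16, box_size = 48,
                       pixel_size = 1.77, total_dose = 16,
                       defocus_range = c(13000, 38000), voltage = 300,
                       spherical_aberration = 2.0, amplitude_contrast = 0.1,
                       trans_total_mean = 4.2, trans_total_sd = 2.3,
                       rot_total_mean = 1.7, rot_total_sd = 1.2,
                       walk_sd = 0.1, damage_rate = 3.0,
                       snr_per_dose = 0.05,
                       pick_error_sd = 1.0, tilt_angle = NULL,
                       tilt_axis_azimuth = 0, n_blobs = 60,
                       particles_per_micrograph = 50, seed = 1) {
  cfg <- list(n_particles = n_particles, n_frames = n_frames,
              box_size = box_size, pixel_size = pixel_size,
              total_dose = total_dose, defocus_range = defocus_range,
              voltage = voltage, spherical_aberration = spherical_aberration,
              amplitude_contrast = amplitude_contrast,
              trans_total_mean = trans_total_mean,
              trans_total_sd = trans_total_sd,
              rot_total_mean = rot_total_mean, rot_total_sd = rot_total_sd,
              walk_sd = walk_sd, damage_rate = damage_rate,
              snr_per_dose = snr_per_dose, pick_error_sd = pick_error_sd,
              tilt_angle = tilt_angle, tilt_axis_azimuth = tilt_axis_azimuth,
              n_blobs = n_blobs,
              particles_per_micrograph = particles_per_micrograph,
              seed = seed)
  stopifnot(n_frames >= 1, box_size %% 2 == 0, total_dose > 0,
            all(unlist(cfg[c("trans_total_mean", "trans_total_sd",
                             "rot_total_mean", "rot_total_sd", "walk_sd",
                             "damage_rate", "snr_per_dose")]) >= 0))
  if (!is.null(tilt_angle)) stopifnot(tilt_angle > 0, tilt_angle < 90)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> %d particles, %d frames, %d px box @ %.2f A/px\n",
           "  dose %.1f e/A^2 (%.3f per frame), motion %.1f+/-%.1f deg / ",
           "%.1f+/-%.1f A, SNR %.3f per e/A^2%s\n"),
    x$n_particles, x$n_frames, x$box_size, x$pixel_size, x$total_dose,
    x$total_dose / x$n_frames, x$rot_total_mean, x$rot_total_sd,
    x$trans_total_mean, x$trans_total_sd, x$snr_per_dose,
    if (is.null(x$tilt_angle)) "" else
      sprintf(", tilt pairs at %.1f deg", x$tilt_angle)))
  invisible(x)
}

#' Synthetic asymmetric density map
#'
#' A sum of `n_blobs` anisotropic Gaussian blobs under a broad spherical
#' envelope; a stand-in for a large asymmetric particle.  Blob widths span
#' domain-sized lumps down to secondary-structure-scale detail, amplitudes
#' are weighted towards the smaller blobs and carry mixed signs
#' (density fluctuations about the mean interior density, as in
#' solvent-flattened contrast), which together give the protein-like broad
#' amplitude spectrum that projection alignment relies on.  With enough
#' blobs the map has no point-group symmetry, so alignment has a unique
#' answer.  Deterministic for a fixed seed.
#'
#' @param n box side in voxels (even)
#' @param voxel_size A per voxel
#' @param n_blobs number of blobs (>= 3; fewer is too symmetric to align)
#' @param seed RNG seed
#' @return a [voxel_grid3d()]
#' @export
make_phantom <- function(n, voxel_size, n_blobs = 60, seed = 1) {
  if (n %% 2 != 0) stop("N must be even")
  if (n_blobs < 3) stop("n_blobs must be >= 3 (fewer is too symmetric)")
  with_seed(seed, {
    c0 <- n / 2
    rad <- 0.30 * n
    centers <- matrix(stats::rnorm(3 * n_blobs, 0, rad / 2), n_blobs, 3)
    ## clamp inside the support sphere
    rr <- sqrt(rowSums(centers^2))
    scale <- pmin(1, rad / pmax(rr, 1e-9))
    centers <- centers * scale + c0
    prec <- matrix(0, n_blobs, 9)
    sgeo <- numeric(n_blobs)
    for (b in seq_len(n_blobs)) {
      sds <- stats::runif(3, 0.018 * n, 0.06 * n)
      sgeo[b] <- exp(mean(log(sds)))
      A <- matrix(stats::rnorm(9), 3, 3)
      Q <- qr.Q(qr(A))
      P <- Q %*% diag(1 / sds^2) %*% t(Q)
      prec[b, ] <- as.numeric(P)
    }
    amp <- stats::runif(n_blobs, 0.5, 1.5) *
      sample(c(-1, 1), n_blobs, replace = TRUE) *
      (0.04 * n / sgeo)^1.5
    vals <- cpp_blob_sum(as.integer(n), centers, prec, amp)
    ## broad envelope keeps density inside the box
    x <- seq_len(n) - (c0 + 1)
    r2 <- outer(outer(x^2, x^2, `+`), x^2, `+`)
    env <- exp(-r2 / (2 * (0.35 * n)^2))
    voxel_grid3d(vals * env, voxel_size)
  })
}

## Solve for the parameters (mu0, sd0) of a folded normal whose realized
## mean/sd equal the requested ones, so nonnegative motion magnitudes keep
## the configured moments exactly.
folded_normal_params <- local({
  cache <- new.env(parent = emptyenv())
  function(mean, sd) {
    key <- paste(mean, sd)
    if (!is.null(cache[[key]])) return(cache[[key]])
    cache[[key]] <- folded_normal_params_solve(mean, sd)
    cache[[key]]
  }
})

folded_normal_params_solve <- function(mean, sd) {
  if (mean <= 0) return(c(0, sd))
  if (sd == 0) return(c(mean, 0))
  fold_moments <- function(mu, s) {
    m <- s * sqrt(2 / pi) * exp(-mu^2 / (2 * s^2)) +
      mu * (1 - 2 * stats::pnorm(-mu / s))
    v <- mu^2 + s^2 - m^2
    c(m, sqrt(v))
  }
  obj <- function(p) {
    fm <- fold_moments(p[1], exp(p[2]))
    sum((fm - c(mean, sd))^2)
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(fit$par[1], exp(fit$par[2]))
}

rfolded <- function(n, mean, sd) {
  p <- folded_normal_params(mean, sd)
  abs(stats::rnorm(n, p[1], p[2]))
}

#' Sample a beam-induced motion trajectory
#'
#' Translation: a linear drift in a random direction whose total length is
#' drawn with mean/sd `trans_total_mean`/`trans_total_sd` (folded at zero),
#' plus a small per-frame random walk.  Rotation: a linear ramp about a
#' random axis with total angle drawn the same way.  Both are re-centred so
#' the dose-weighted mean over frames is zero: the trajectory is expressed
#' about the exposure-average pose that refinement sees.
#'
#' @param config a [sim_config()]
#' @param seed RNG seed
#' @return class `motion_trajectory`: list with `trans` (F x 2 matrix, A),
#'   `rot_euler` (F x 3 per-frame ZYZ perturbations, degrees), `total_trans`
#'   (A), `total_rot` (degrees), `axis`
#' @export
sample_trajectory <- function(config, seed = config$seed) {
  f <- config$n_frames
  if (f < 2) stop("need at least 2 frames")
  with_seed(seed, {
    dose <- rep(config$total_dose / f, f)
    w <- dose / sum(dose)
    ## translation: drift + walk (Angstrom)
    total <- if (config$trans_total_mean == 0 && config$trans_total_sd == 0)
      0 else rfolded(1, config$trans_total_mean, config$trans_total_sd)
    theta <- stats::runif(1, 0, 2 * pi)
    ramp <- seq(-0.5, 0.5, length.out = f)
    trans <- cbind(total * cos(theta) * ramp, total * sin(theta) * ramp)
    if (config$walk_sd > 0) {
      walk <- apply(matrix(stats::rnorm(2 * f, 0, config$walk_sd), f, 2),
                    2, cumsum)
      trans <- trans + walk
    }
    trans <- sweep(trans, 2, colSums(trans * w))
    ## rotation: ramp about a random axis (degrees)
    ang <- if (config$rot_total_mean == 0 && config$rot_total_sd == 0)
      0 else rfolded(1, config$rot_total_mean, config$rot_total_sd)
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    angles <- ang * ramp
    rot_euler <- t(vapply(angles, function(a)
      euler_from_matrix(axis_angle_matrix(u, a)), numeric(3)))
    structure(list(trans = trans, rot_euler = rot_euler,
                   total_trans = sqrt(sum((trans[f, ] - trans[1, ])^2)),
                   total_rot = ang, axis = u, per_frame_dose = dose),
              class = "motion_trajectory")
  })
}

## rotation matrix of frame f: lab-frame wobble left-composed on the mean pose
frame_rotation <- function(mean_pose, trajectory, f) {
  dR <- rotation_matrix(trajectory$rot_euler[f, ])
  dR %*% rotation_matrix(mean_pose)
}

#' Render one particle movie
#'
#' Each frame is the CTF-filtered central-slice projection of the phantom at
#' the frame pose (mean pose composed with the trajectory perturbation),
#' attenuated by the dose-dependent damage envelope
#' `exp(-B_dmg(f) nu^2 / 4)` with `B_dmg(f) = damage_rate x accumulated
#' dose at the frame midpoint`, plus white Gaussian noise.  Every frame
#' carries the full projection amplitude, so the F-frame average has the
#' same signal and 1/F the noise variance of a single frame.
#'
#' @param phantom a [voxel_grid3d()] with voxel size equal to the config
#'   pixel size
#' @param p mean [pose()] of the particle (exposure average)
#' @param trajectory a [sample_trajectory()] result
#' @param config a [sim_config()]
#' @param ctf a [ctf_params()]; defaults to mid-range defocus
#' @param seed RNG seed for the noise
#' @return class `particle_movie`: list of F [pixel_grid2d()] frames plus
#'   metadata (`ctf`, `per_frame_dose`, ids, picked coordinates)
#' @export
render_movie <- function(phantom, p, trajectory, config,
                         ctf = NULL, seed = config$seed,
                         particle_id = 1L, micrograph_id = 1L,
                         picked_x = 0, picked_y = 0) {
  n <- config$box_size
  proj <- if (inherits(phantom, "fourier_projector")) phantom
          else make_projector(phantom)
  if (proj$n != n) stop("phantom and config box sizes differ")
  if (abs(proj$voxel_size - config$pixel_size) > 1e-9)
    stop("phantom voxel size must equal config pixel size")
  if (is.null(ctf)) ctf <- ctf_params(mean(config$defocus_range),
                                      voltage = config$voltage,
                                      spherical_aberration =
                                        config$spherical_aberration,
                                      amplitude_contrast =
                                        config$amplitude_contrast)
  f <- config$n_frames
  px <- full_pixel_list(n)
  cimg <- ctf_image(ctf, n, config$pixel_size)
  nu2 <- (fourier_radius(n, 2) / (n * config$pixel_size))^2
  dose <- trajectory$per_frame_dose
  acc <- cumsum(dose) - dose / 2     # accumulated dose at frame midpoint
  ## reference signal variance: clean CTF projection at the mean pose
  sl0 <- matrix(as.complex(cpp_extract_slices(
    proj$vft, pose_matrix_rows(c(p$rot, p$tilt, p$psi)),
    as.integer(px$kx * proj$pad), as.integer(px$ky * proj$pad))),
    n, n) * (proj$scale * sqrt(n))
  clean0 <- Re(ift(sl0 * cimg))
  vs <- stats::var(as.numeric(clean0))
  frames <- vector("list", f)
  with_seed(seed, {
    for (k in seq_len(f)) {
      Rk <- frame_rotation(p, trajectory, k)
      ek <- euler_from_matrix(Rk)
      sl <- matrix(as.complex(cpp_extract_slices(
        proj$vft, pose_matrix_rows(ek),
        as.integer(px$kx * proj$pad), as.integer(px$ky * proj$pad))),
        n, n) * (proj$scale * sqrt(n))
      dx <- p$offset_x + trajectory$trans[k, 1] / config$pixel_size
      dy <- p$offset_y + trajectory$trans[k, 2] / config$pixel_size
      sl <- sl * cimg * exp(-config$damage_rate * acc[k] * nu2 / 4) *
        shift_ramp(n, dx, dy)
      img <- Re(ift(sl))
      if (config$snr_per_dose > 0 && vs > 0) {
        sigma_f <- sqrt(vs / (config$snr_per_dose * dose[k]))
        img <- img + matrix(stats::rnorm(n * n, 0, sigma_f), n, n)
      }
      frames[[k]] <- pixel_grid2d(img, config$pixel_size)
    }
  })
  structure(list(frames = frames, per_frame_dose = dose,
                 particle_id = particle_id, micrograph_id = micrograph_id,
                 picked_x = picked_x, picked_y = picked_y, ctf = ctf),
            class = "particle_movie")
}

#' @export
print.particle_movie <- function(x, ...) {
  cat(sprintf(
    "<particle_movie> particle %s, %d frames of %d px, %.3f e/A^2/frame\n",
    x$particle_id, length(x$frames), grid_n(x$frames[[1]]),
    x$per_frame_dose[1]))
  invisible(x)
}

## average of all frames of a movie
movie_average <- function(movie, frames = seq_along(movie$frames)) {
  vals <- Reduce(`+`, lapply(movie$frames[frames], `[[`, "values")) /
    length(frames)
  pixel_grid2d(vals, movie$frames[[1]]$pixel_size)
}

#' Simulate a full dataset with ground truth
#'
#' Draws uniformly distributed true poses (viewing directions uniform on the
#' sphere), per-particle defocus uniform in the configured range, picking
#' errors on the offsets, a motion trajectory per exposure, and renders the
#' movies.  With `tilt_angle` set, each particle is imaged twice: untilted
#' and after left-composition with the rotation by `tilt_angle` about the
#' in-plane axis at `tilt_axis_azimuth` (an independent exposure with its
#' own trajectory and noise).
#'
#' @param config a [sim_config()]
#' @param phantom optional [voxel_grid3d()]; generated from the config seed
#'   when omitted
#' @return list with `movies` (list of `particle_movie`; tilt mode appends
#'   the tilted copies after the untilted set), `truth` (data.frame of true
#'   mean poses and defocus per movie), `trajectories`, `phantom`, `config`
#' @export
simulate_dataset <- function(config, phantom = NULL) {
  n <- config$box_size
  if (is.null(phantom))
    phantom <- make_phantom(n, config$pixel_size, config$n_blobs,
                            seed = child_seed(config$seed, "phantom"))
  proj <- make_projector(phantom)
  np <- config$n_particles
  tilted <- !is.null(config$tilt_angle)
  poses <- with_seed(child_seed(config$seed, "poses"), {
    data.frame(
      rot = stats::runif(np, -180, 180),
      tilt = rad2deg(acos(stats::runif(np, -1, 1))),
      psi = stats::runif(np, -180, 180),
      offset_x = stats::rnorm(np, 0, config$pick_error_sd),
      offset_y = stats::rnorm(np, 0, config$pick_error_sd),
      defocus = stats::runif(np, config$defocus_range[1],
                             config$defocus_range[2]),
      astig_angle = stats::runif(np, 0, 180))
  })
  R_tilt <- if (tilted)
    axis_angle_matrix(c(cos(deg2rad(config$tilt_axis_azimuth)),
                        sin(deg2rad(config$tilt_axis_azimuth)), 0),
                      config$tilt_angle)
  n_expo <- if (tilted) 2L * np else np
  movies <- vector("list", n_expo)
  trajectories <- vector("list", n_expo)
  truth <- vector("list", n_expo)
  for (i in seq_len(np)) {
    for (side in if (tilted) 0:1 else 0) {
      idx <- i + side * np
      p0 <- pose(poses$rot[i], poses$tilt[i], poses$psi[i],
                 poses$offset_x[i], poses$offset_y[i])
      p <- if (side == 1) compose_rotation(R_tilt, p0) else p0
      ctf <- ctf_params(poses$defocus[i], poses$defocus[i] * 0.98,
                        poses$astig_angle[i], config$voltage,
                        config$spherical_aberration,
                        config$amplitude_contrast)
      tr <- sample_trajectory(config,
                              seed = child_seed(config$seed, "traj", idx))
      mg <- (i - 1) %/% config$particles_per_micrograph + 1L
      movies[[idx]] <- render_movie(proj_as_phantom(proj, phantom), p, tr,
                                    config, ctf,
                                    seed = child_seed(config$seed, "noise",
                                                      idx),
                                    particle_id = idx, micrograph_id = mg)
      trajectories[[idx]] <- tr
      truth[[idx]] <- data.frame(
        particle_id = idx, pair_id = i, tilted = side == 1,
        micrograph_id = mg, rot = p$rot, tilt = p$tilt, psi = p$psi,
        offset_x = p$offset_x, offset_y = p$offset_y,
        defocus_u = ctf$defocus_u, defocus_v = ctf$defocus_v,
        astig_angle = ctf$astig_angle,
        total_rot = tr$total_rot, total_trans = tr$total_trans,
        per_frame_dose = config$total_dose / config$n_frames,
        seed = config$seed)
    }
  }
  list(movies = movies, truth = do.call(rbind, truth),
       trajectories = trajectories, phantom = phantom, config = config)
}

## reuse a prebuilt projector while keeping render_movie's interface
proj_as_phantom <- function(proj, phantom) {
  proj$voxel_size <- phantom$voxel_size
  proj
}
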