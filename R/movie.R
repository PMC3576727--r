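## Statistical movie processing: per-frame alignment of dose-fractionated
## particle movies under Gaussian priors on rotations and translations,
## centred at the orientation observed for the whole-exposure average.
## Alignment uses running averages of W frames; the result is assigned to
## the window's middle frame only.

#' Gaussian orientation/translation prior for movie-frame alignment
#'
#' The prior is centred at the pose determined for the F-frame average.
#' Its angular part weights a candidate by
#' `exp(-Delta^2 / (2 sigma_angle^2))` with `Delta` the geodesic rotation
#' angle between candidate and centre (the three Euler perturbations are
#' treated jointly); the translational part is an isotropic Gaussian on the
#' offset difference.  Defaults are the working values of the method:
#' sigma of 1 degree on the angles, searches to +-3 degrees in steps of
#' 0.45 degrees and +-2 pixels in steps of 0.5 pixels; `sigma_trans`
#' should be the translational spread estimated from the whole-exposure
#' refinement.
#'
#' @param center a [pose()] from the F-frame-average alignment
#' @param sigma_angle degrees (> 0)
#' @param sigma_trans pixels (> 0)
#' @param angle_range,angle_step local rotational search, degrees
#' @param trans_range,trans_step local translational search, pixels
#' @return an object of class `orientation_prior`
#' @export
orientation_prior <- function(center, sigma_angle = 1.0, sigma_trans = 1.0,
                              angle_range = 3.0, angle_step = 0.45,
                              trans_range = 2.0, trans_step = 0.5) {
  stopifnot(inherits(center, "pose"), sigma_angle > 0, sigma_trans > 0,
            angle_step > 0, trans_step > 0,
            angle_range >= angle_step, trans_range >= trans_step)
  structure(list(center = center, sigma_angle = sigma_angle,
                 sigma_trans = sigma_trans, angle_range = angle_range,
                 angle_step = angle_step, trans_range = trans_range,
                 trans_step = trans_step),
            class = "orientation_prior")
}

#' @export
print.orientation_prior <- function(x, ...) {
  cat(sprintf(
    paste0("<orientation_prior> sigma %.2f deg / %.2f px, search +-%.2g deg",
           " step %.2g, +-%.2g px step %.2g\n"),
    x$sigma_angle, x$sigma_trans, x$angle_range, x$angle_step,
    x$trans_range, x$trans_step))
  print(x$center)
  invisible(x)
}

#' Prior weight of a candidate pose
#'
#' `exp(-Delta^2/(2 sigma_angle^2)) * exp(-(dx^2+dy^2)/(2 sigma_trans^2))`
#' with `Delta` the geodesic angle of the relative rotation between
#' candidate and prior centre, and (dx, dy) the offset difference.
#' Unnormalized: the weight is 1 at the centre.
#'
#' @param candidate a [pose()]
#' @param prior an [orientation_prior()]
#' @return nonnegative weight <= 1
#' @export
prior_weight <- function(candidate, prior) {
  delta <- rotation_distance(candidate, prior$center)
  d2 <- (candidate$offset_x - prior$center$offset_x)^2 +
    (candidate$offset_y - prior$center$offset_y)^2
  exp(-delta^2 / (2 * prior$sigma_angle^2)) *
    exp(-d2 / (2 * prior$sigma_trans^2))
}

## search grid + log prior matrix implied by an orientation prior
prior_grid <- function(prior) {
  grid <- sampling_grid(prior$angle_step, prior$trans_range,
                        prior$trans_step, center = prior$center,
                        angular_range = prior$angle_range)
  R0 <- rotation_matrix(prior$center)
  dang <- vapply(seq_len(nrow(grid$angles)), function(i)
    rotation_distance(matrix(grid$rmats[i, ], 3, 3), R0), numeric(1))
  d2 <- (grid$shifts[, 1] - prior$center$offset_x)^2 +
    (grid$shifts[, 2] - prior$center$offset_y)^2
  lp <- outer(-dang^2 / (2 * prior$sigma_angle^2),
              -d2 / (2 * prior$sigma_trans^2), `+`)
  list(grid = grid, logprior = lp)
}

#' Running averages of movie frames
#'
#' Output f is the mean of frames `max(1, f - (W-1)/2) ..
#' min(F, f + (W-1)/2)`: a sliding window of odd width W, truncated at the
#' movie edges, one output per frame.  The alignment of window f is later
#' assigned to frame f only (the window's middle frame).
#'
#' @param movie a `particle_movie` (see [render_movie()])
#' @param W odd window width, 1 <= W <= F
#' @return list of F [pixel_grid2d()]
#' @export
running_average <- function(movie, W = 5) {
  f <- length(movie$frames)
  if (W %% 2 == 0) stop("W must be odd (no unique middle frame)")
  if (W < 1 || W > f) stop("W must be in 1..F")
  hw <- (W - 1) %/% 2
  lapply(seq_len(f), function(k)
    movie_average(movie, max(1, k - hw):min(f, k + hw)))
}

#' Contiguous multi-frame partition averages
#'
#' Splits the F frames into non-overlapping blocks of `frames_per_average`
#' and averages each: the independent multi-frame particles of the naive
#' baseline (e.g. 4 x 4 for a 16-frame movie).  When F is not divisible,
#' the final block is formed from the last `frames_per_average` frames and
#' overlaps the previous block, so every frame is used (the 3 x 6 case).
#'
#' @param movie a `particle_movie`
#' @param frames_per_average block width, 1 <= width <= F
#' @return list of [pixel_grid2d()] averages, with attribute `frames`
#'   giving each block's frame indices
#' @export
partition_average <- function(movie, frames_per_average) {
  f <- length(movie$frames)
  w <- frames_per_average
  if (w < 1 || w > f) stop("frames_per_average must be in 1..F")
  starts <- seq(1, f - w + 1, by = w)
  if (max(starts) + w - 1 < f) starts <- c(starts, f - w + 1)
  blocks <- lapply(starts, function(s) s:(s + w - 1))
  out <- lapply(blocks, function(b) movie_average(movie, b))
  attr(out, "frames") <- blocks
  out
}

#' Align the frames of one particle movie under the Gaussian prior
#'
#' For each frame f the posterior over the local grid implied by the prior
#' is `likelihood(running-average image f) x prior weight`; the assigned
#' pose is the posterior mean over the grid (`assignment = "map"` for the
#' mode) and applies to frame f only.  Gold-standard discipline is the
#' caller's responsibility: pass the half-map of the particle's half-set
#' as `reference`.
#'
#' @param movie a `particle_movie`
#' @param reference a [voxel_grid3d()] (the particle's half-map)
#' @param prior an [orientation_prior()] centred at the pose of the
#'   F-frame average against the same reference
#' @param noise a [noise_model()]
#' @param W odd running-average window (5 by default)
#' @param cap alignment resolution cap in shells
#' @param assignment `"mean"` (posterior mean, default) or `"map"`
#' @return class `frame_track`: data.frame `track` with per-frame pose and
#'   posterior confidence, plus provenance attributes
#' @export
align_frames <- function(movie, reference, prior, noise, W = 5,
                         cap = NULL, assignment = c("mean", "map")) {
  assignment <- match.arg(assignment)
  f <- length(movie$frames)
  n <- grid_n(movie$frames[[1]])
  ps <- movie$frames[[1]]$pixel_size
  if (abs(prior$center$offset_x) + prior$trans_range >= n / 4 ||
      abs(prior$center$offset_y) + prior$trans_range >= n / 4)
    stop("prior centre offsets put the search grid out of reach")
  proj <- if (inherits(reference, "fourier_projector")) reference
          else make_projector(reference)
  if (is.null(cap)) cap <- max(8, n %/% 4)
  pg <- prior_grid(prior)
  pl <- half_pixel_list(n, cap)
  iv <- pixel_weights(noise, pl)
  slices <- grid_slices(proj, pg$grid, pl)
  cv <- ctf_at_pixels(movie$ctf, pl, ps)
  ravg <- running_average(movie, W)
  xf <- lapply(ravg, function(im) image_at_pixels(ft(im$values), pl))
  res <- align_batch(xf, rep(list(cv), f), slices, pg$grid, iv, pl,
                     logprior = pg$logprior)
  track <- do.call(rbind, lapply(seq_len(f), function(k) {
    psd <- batch_pose(res, pg$grid, k)
    p <- if (assignment == "mean") psd$expected else psd$map
    data.frame(frame = k, rot = p$rot, tilt = p$tilt, psi = p$psi,
               offset_x = p$offset_x, offset_y = p$offset_y,
               confidence = res$max_post[k])
  }))
  structure(list(track = track, particle_id = movie$particle_id,
                 W = W, prior = prior, assignment = assignment),
            class = "frame_track")
}

#' @export
print.frame_track <- function(x, ...) {
  dr <- vapply(seq_len(nrow(x$track)), function(k)
    rotation_distance(pose(x$track$rot[k], x$track$tilt[k],
                           x$track$psi[k]), x$prior$center), numeric(1))
  cat(sprintf(
    "<frame_track> particle %s, %d frames (W=%d), max |dR| %.2f deg\n",
    x$particle_id, nrow(x$track), x$W, max(dr)))
  invisible(x)
}

## pose of frame k of a track
track_pose <- function(track, k) {
  tr <- track$track
  pose(tr$rot[k], tr$tilt[k], tr$psi[k], tr$offset_x[k], tr$offset_y[k])
}

#' Gold-standard reconstruction from polished movie frames
#'
#' Every frame of every movie enters the reconstruction of its particle's
#' half-set as an independent image at its per-frame pose.  Returns the two
#' half-maps and their masked FSC.
#'
#' @param movies list of `particle_movie`
#' @param tracks list of [align_frames()] results (same order)
#' @param half integer vector of half-set labels (1/2) per movie
#' @param tau2,noise optional per-shell Wiener regularization (see
#'   [reconstruct()])
#' @param mask_radius,mask_falloff soft spherical mask used for the FSC
#' @return list with `half_maps`, `fsc` (masked [fsc_curve()]),
#'   `resolution` (FSC = 0.143, Angstrom)
#' @export
polish_reconstruct <- function(movies, tracks, half, tau2 = NULL,
                               noise = NULL, mask_radius = NULL,
                               mask_falloff = 5) {
  if (length(movies) != length(tracks))
    stop("movies and tracks differ in length")
  n <- grid_n(movies[[1]]$frames[[1]])
  ps <- movies[[1]]$frames[[1]]$pixel_size
  if (length(half) == 1) half <- rep(half, length(movies))
  maps <- vector("list", 2)
  for (h in 1:2) {
    sel <- which(half == h)
    if (length(sel) == 0 && length(unique(half)) == 1 && h == 2) {
      ## degenerate single-half input: duplicate so an FSC still exists
      sel <- which(half == half[1])
    }
    imgs <- list()
    ctfs <- list()
    poses <- list()
    for (i in sel) {
      f <- length(movies[[i]]$frames)
      for (k in seq_len(f)) {
        imgs[[length(imgs) + 1]] <- movies[[i]]$frames[[k]]
        ctfs[[length(ctfs) + 1]] <- movies[[i]]$ctf
        poses[[length(poses) + 1]] <- track_pose(tracks[[i]], k)
      }
    }
    ## frames carry the full projection amplitude, so average rather than
    ## sum: reconstruct() normalizes by the CTF^2 weights internally
    maps[[h]] <- reconstruct(imgs, ctfs, poses, tau2 = tau2, noise = noise)
  }
  if (is.null(mask_radius)) mask_radius <- n / 2 - mask_falloff - 2
  msk <- soft_spherical_mask(n, mask_radius, mask_falloff, ps)
  curve <- fsc(maps[[1]], maps[[2]], mask = msk)
  list(half_maps = maps, fsc = curve,
       resolution = resolution_at(curve, 0.143))
}
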