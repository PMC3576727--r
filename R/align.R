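## Regularized-likelihood alignment over sampling grids.
##
## The Gaussian data model assigns each candidate pose phi the
## log-likelihood
##   log L(phi) = - sum_k |X(k) - CTF(k) P_phi V(k)|^2 / (2 sigma^2(shell))
## over Fourier pixels up to a resolution cap.  Posterior responsibilities
## Gamma over the grid are exp(log L + log prior), normalized by
## log-sum-exp; the comparison runs on the Hermitian half-plane with
## doubled weights, which is exact for real images.

## half-plane pixel list up to `cap` shells: kx, ky, shell, weight
half_pixel_list <- function(n, cap) {
  k <- freq_axis(n)
  kx <- rep(k, times = n)
  ky <- rep(k, each = n)
  r <- sqrt(kx^2 + ky^2)
  keep <- r >= 0.5 & r <= cap & (ky > 0 | (ky == 0 & kx > 0))
  list(kx = kx[keep], ky = ky[keep], shell = round(r[keep]),
       weight = rep(2, sum(keep)), cap = cap, n = n)
}

## image transform sampled at a pixel list
image_at_pixels <- function(image_ft, pl) {
  n <- pl$n
  image_ft[cbind(pl$kx + n / 2 + 1, pl$ky + n / 2 + 1)]
}

## CTF values at a pixel list
ctf_at_pixels <- function(ctf, pl, pixel_size) {
  nu <- sqrt(pl$kx^2 + pl$ky^2) / (pl$n * pixel_size)
  az <- rad2deg(atan2(pl$ky, pl$kx))
  ctf_evaluate(ctf, nu, az)
}

## translation phase ramps exp(+2 pi i k.d / N), npix x nshift
shift_phases <- function(pl, shifts) {
  ph <- matrix(0i, length(pl$kx), nrow(shifts))
  for (t in seq_len(nrow(shifts)))
    ph[, t] <- exp(2i * pi * (pl$kx * shifts[t, 1] + pl$ky * shifts[t, 2]) /
                     pl$n)
  ph
}

## reference slices at the grid orientations: list(S, Sabs2)
grid_slices <- function(projector, grid, pl) {
  S <- cpp_extract_slices(projector$vft, grid$rmats,
                          as.integer(pl$kx * projector$pad),
                          as.integer(pl$ky * projector$pad)) *
    (projector$scale * sqrt(pl$n))
  list(S = S, Sabs2 = abs(S)^2)
}

## 1/(2 sigma^2) with half-plane weight folded in
pixel_weights <- function(noise, pl) {
  s2 <- noise$sigma2[pl$shell + 1]
  if (any(!is.finite(s2)) || any(s2 <= 0))
    stop("noise variance must be positive in every used shell")
  pl$weight / (2 * s2)
}

## internal batch alignment: images as a list, shared grid/slices
align_batch <- function(images_ft, ctf_vals, slices, grid, iv, pl,
                        logprior = NULL, return_post = FALSE) {
  X <- do.call(cbind, images_ft)
  C <- do.call(cbind, ctf_vals)
  phases <- shift_phases(pl, grid$shifts)
  lp <- if (is.null(logprior)) matrix(0, 0, 0) else logprior
  cpp_align_batch(slices$S, slices$Sabs2, grid$rmats, X, C, iv, phases,
                  grid$shifts, lp, return_post)
}

## turn one column of a batch result into poses
batch_pose <- function(res, grid, j) {
  mp <- res$map_pose[j]
  mt <- res$map_shift[j]
  a <- grid$angles[mp, ]
  map <- pose(a[1], a[2], a[3], grid$shifts[mt, 1], grid$shifts[mt, 2])
  Rm <- nearest_rotation(matrix(res$wR[j, ], 3, 3))
  e <- euler_from_matrix(Rm)
  expected <- pose(e[1], e[2], e[3], res$wT[j, 1], res$wT[j, 2])
  list(map = map, expected = expected)
}

#' Posterior over a sampling grid for one image
#'
#' Evaluates the Gaussian likelihood of `image` for every (orientation,
#' translation) candidate of `grid` against the reference map, with a flat
#' prior, and returns the normalized posterior responsibilities together
#' with the MAP pose (ties broken by lowest grid index) and the
#' posterior-weighted (expected) pose.
#'
#' @param image a [pixel_grid2d()]
#' @param ctf a [ctf_params()]
#' @param reference a [voxel_grid3d()] with the image's pixel size
#' @param noise a [noise_model()]
#' @param grid a [sampling_grid()]
#' @param cap resolution cap in Fourier shells (default: up to Nyquist - 2)
#' @param logprior optional n_orientations x n_translations matrix of log
#'   prior weights
#' @return class `alignment_result`: `gamma` (orientations x translations
#'   posterior matrix, sums to 1), `map_pose`, `expected_pose`,
#'   `log_evidence`
#' @export
likelihood_over_grid <- function(image, ctf, reference, noise, grid,
                                 cap = NULL, logprior = NULL) {
  if (nrow(grid$angles) == 0) stop("empty grid")
  if (all(noise$sigma2 == 0)) stop("all-zero noise variance")
  n <- grid_n(image)
  if (inherits(reference, "fourier_projector")) {
    proj <- reference
  } else {
    if (abs(image$pixel_size - reference$voxel_size) > 1e-9)
      stop("image and reference pixel sizes differ")
    proj <- make_projector(reference)
  }
  if (is.null(cap)) cap <- n %/% 2 - 2
  pl <- half_pixel_list(n, cap)
  iv <- pixel_weights(noise, pl)
  slices <- grid_slices(proj, grid, pl)
  xf <- image_at_pixels(ft(image$values), pl)
  cv <- ctf_at_pixels(ctf, pl, image$pixel_size)
  res <- align_batch(list(xf), list(cv), slices, grid, iv, pl,
                     logprior = logprior, return_post = TRUE)
  ps <- batch_pose(res, grid, 1)
  structure(list(gamma = res$post[, , 1, drop = TRUE],
                 map_pose = ps$map, expected_pose = ps$expected,
                 log_evidence = res$log_evidence[1],
                 max_post = res$max_post[1], grid = grid),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf(
    "<alignment_result> %d x %d grid, MAP weight %.3f, logZ %.2f\n",
    nrow(x$grid$angles), nrow(x$grid$shifts), x$max_post, x$log_evidence))
  print(x$map_pose)
  invisible(x)
}

#' Direct Fourier-inversion reconstruction
#'
#' Inserts each image transform into the 3D Fourier volume on the central
#' slice of its pose (trilinear spreading), CTF-weighted, and divides by
#' `sum CTF^2 + sigma^2(shell) / tau^2(shell)` (a per-shell Wiener term;
#' a small ridge when no regularization is given).
#'
#' @param images list of [pixel_grid2d()]
#' @param ctfs list of [ctf_params()] (or one shared; NULL for unit CTF)
#' @param poses list of [pose()]
#' @param tau2 per-shell signal power (length N/2), or NULL for a plain
#'   ridge
#' @param noise a [noise_model()] used with `tau2`
#' @param chunk images per insertion batch
#' @param pad Fourier oversampling of the insertion grid
#' @return a [voxel_grid3d()]
#' @export
reconstruct <- function(images, ctfs, poses, tau2 = NULL, noise = NULL,
                        chunk = 256, pad = 2L) {
  if (length(images) == 0) stop("empty input")
  n <- grid_n(images[[1]])
  np <- pad * n
  ps <- images[[1]]$pixel_size
  if (inherits(ctfs, "ctf_params")) ctfs <- rep(list(ctfs), length(images))
  unit_ctf <- is.null(ctfs)
  num <- array(0i, c(np, np, np))
  wt <- array(0, c(np, np, np))
  idx <- split(seq_along(images), ceiling(seq_along(images) / chunk))
  for (ii in idx) {
    m <- length(ii)
    imgs <- array(0i, c(n, n, m))
    cts <- array(0, c(n, n, m))
    rms <- matrix(0, m, 9)
    shf <- matrix(0, m, 2)
    for (j in seq_len(m)) {
      i <- ii[j]
      imgs[, , j] <- ft(images[[i]]$values)
      cts[, , j] <- if (unit_ctf) 1 else ctf_image(ctfs[[i]], n, ps)
      rms[j, ] <- as.numeric(rotation_matrix(poses[[i]]))
      shf[j, ] <- c(poses[[i]]$offset_x, poses[[i]]$offset_y)
    }
    acc <- cpp_insert_slices(imgs, cts, rms, shf,
                             as.integer(n %/% 2 - 1), as.integer(pad))
    num <- num + acc$num
    wt <- wt + acc$wt
  }
  ## Hermitian symmetrization of the accumulators
  num <- (num + Conj(revcenter3(num))) / 2
  wt <- (wt + revcenter3(wt)) / 2
  shell <- pmin(round(fourier_radius(np, 3) / pad), n %/% 2)
  if (!is.null(tau2) && !is.null(noise)) {
    si0 <- pmin(shell, n_shells(n) - 1)
    ## per-shell mean CTF^2 weight, used to clamp the regularization:
    ## no shell is attenuated by more than ~100x, so genuine content is
    ## reduced, never annihilated (a spectral cliff would ring across
    ## shells when the padded grid is cropped)
    wbar <- as.numeric(tapply(wt, si0, mean))[si0 + 1]
    reg <- noise$sigma2[si0 + 1] / pmax(tau2[si0 + 1], 1e-12)
    denom <- wt + array(pmin(reg, 99 * wbar), dim(wt)) + 1e-6 * max(wt)
  } else {
    denom <- wt + 1e-3 * max(wt)
  }
  vol <- num / denom
  vol[shell > n %/% 2 - 1] <- 0i
  ## undo the unitary slice scaling (sqrt(n)) and the padding amplitude
  ## factor, back-transform on the padded grid, crop the centre box
  vol <- vol / (sqrt(n) * pad^1.5)
  full <- Re(ift(vol))
  at <- (np %/% 2 - n %/% 2) + seq_len(n)
  voxel_grid3d(full[at, at, at], ps)
}

## reverse an array about the centred Fourier origin: k -> -k
revcenter3 <- function(x) {
  n <- dim(x)[1]
  idx <- c(1, n:2)  # index i=1 (k=-N/2) is its own mirror partner
  x[idx, idx, idx]
}
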