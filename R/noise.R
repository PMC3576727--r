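#' Per-shell noise model
#'
#' One nonnegative variance per Fourier shell (shells 0 .. N/2 - 1 by
#' rounded radius).  The variance is of the full complex Fourier
#' coefficient, `E|N(k)|^2`, under the unitary transform convention, so
#' flat real-space noise of variance s^2 gives sigma2 = s^2 in every shell.
#'
#' @param sigma2 numeric vector of shell variances (>= 0), length N/2
#' @return an object of class `noise_model`
#' @export
noise_model <- function(sigma2) {
  if (any(!is.finite(sigma2)) || any(sigma2 < 0))
    stop("sigma2 must be finite and >= 0")
  structure(list(sigma2 = as.numeric(sigma2)), class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("<noise_model> %d shells, sigma2 range %.3g .. %.3g\n",
              length(x$sigma2), min(x$sigma2), max(x$sigma2)))
  invisible(x)
}

#' Estimate the per-shell noise variance from aligned particles
#'
#' The mean squared Fourier residual between the images and the
#' CTF-modulated reference projections at the assigned poses, averaged per
#' shell over images and pixels.
#'
#' @param images list of [pixel_grid2d()]
#' @param reference a [voxel_grid3d()]
#' @param ctfs list of [ctf_params()] (one per image, or one shared)
#' @param poses list of [pose()] assignments
#' @return a [noise_model()] with N/2 shells
#' @export
estimate_noise <- function(images, reference, ctfs, poses) {
  if (length(images) < 10) stop("need at least 10 particles")
  n <- grid_n(images[[1]])
  if (n_shells(n) < 4) stop("fewer than 4 shells")
  if (inherits(ctfs, "ctf_params")) ctfs <- rep(list(ctfs), length(images))
  proj <- make_projector(reference)
  shell <- shell_index(n, 2)
  keep <- shell < n_shells(n)
  sums <- numeric(n_shells(n))
  cnts <- numeric(n_shells(n))
  for (i in seq_along(images)) {
    pr <- project(proj, poses[[i]])
    cimg <- ctf_image(ctfs[[i]], n, images[[i]]$pixel_size)
    res <- ft(images[[i]]$values) - cimg * ft(pr$values)
    a <- abs(res[keep])^2
    s <- factor(shell[keep], levels = 0:(n_shells(n) - 1))
    ss <- tapply(a, s, sum)
    ss[is.na(ss)] <- 0
    sums <- sums + as.numeric(ss)
    cnts <- cnts + as.numeric(table(s))
  }
  noise_model(sums / pmax(cnts, 1))
}
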