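## Masked gold-standard FSC, resolution reporting, MTF correction,
## Guinier B-factor estimation/sharpening, and the Rosenthal-Henderson
## particle-number extrapolation.

#' Fourier shell correlation curve
#'
#' @param freq shell centre frequencies in 1/Angstrom, strictly increasing
#' @param fsc correlation per shell, in \[-1, 1\]
#' @param pixel_size A/pixel of the maps the curve came from
#' @return an object of class `fsc_curve`
#' @export
fsc_curve <- function(freq, fsc, pixel_size = NA_real_) {
  stopifnot(length(freq) == length(fsc), all(diff(freq) > 0))
  fsc <- pmin(1, pmax(-1, fsc))
  structure(list(freq = freq, fsc = fsc, pixel_size = pixel_size),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("<fsc_curve> %d shells to %.3f 1/A; FSC=0.143 at %.2f A\n",
              length(x$freq), max(x$freq), resolution_at(x)))
  invisible(x)
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.143, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}

#' Soft spherical mask
#'
#' 1 inside `radius`, raised-cosine fall-off over `falloff` pixels
#' (`0.5 (1 + cos(pi (r - radius)/falloff))`), 0 beyond.
#'
#' @param n box side in voxels
#' @param radius flat-region radius in pixels
#' @param falloff fall-off width in pixels (default 5)
#' @param voxel_size A/voxel recorded on the result
#' @return a [voxel_grid3d()]
#' @export
soft_spherical_mask <- function(n, radius, falloff = 5, voxel_size = 1) {
  if (falloff <= 0) stop("falloff must be positive")
  if (radius + falloff >= n / 2) stop("radius + falloff must be < N/2")
  x <- seq_len(n) - (n / 2 + 1)
  r <- sqrt(outer(outer(x^2, x^2, `+`), x^2, `+`))
  m <- array(0, c(n, n, n))
  m[r <= radius] <- 1
  band <- r > radius & r <= radius + falloff
  m[band] <- 0.5 * (1 + cos(pi * (r[band] - radius) / falloff))
  voxel_grid3d(m, voxel_size)
}

#' Fourier shell correlation between two maps
#'
#' Per shell s: `FSC(s) = Re sum F1 F2* / sqrt(sum |F1|^2 sum |F2|^2)` over
#' the voxels of shell s (one Fourier voxel per shell, assignment by
#' rounded radius).  A zero-power shell gets FSC = 0 with a warning.
#'
#' @param map1,map2 [voxel_grid3d()] of identical dimensions
#' @param mask optional real-space mask multiplied into both maps
#' @return an [fsc_curve()]
#' @export
fsc <- function(map1, map2, mask = NULL) {
  stopifnot(identical(dim(map1$values), dim(map2$values)))
  n <- grid_n(map1)
  a <- map1$values
  b <- map2$values
  if (!is.null(mask)) {
    a <- a * mask$values
    b <- b * mask$values
  }
  fa <- ft(a)
  fb <- ft(b)
  s <- shell_index(n, 3)
  keep <- s >= 1 & s < n_shells(n)
  sf <- factor(s[keep], levels = 1:(n_shells(n) - 1))
  num <- tapply(Re(fa[keep] * Conj(fb[keep])), sf, sum)
  p1 <- tapply(abs(fa[keep])^2, sf, sum)
  p2 <- tapply(abs(fb[keep])^2, sf, sum)
  denom <- sqrt(p1 * p2)
  vals <- ifelse(denom > 0, num / pmax(denom, .Machine$double.xmin), 0)
  if (any(denom == 0)) warning("zero-power shell(s): FSC set to 0")
  shells <- 1:(n_shells(n) - 1)
  fsc_curve(shells / (n * map1$voxel_size), as.numeric(vals),
            map1$voxel_size)
}

#' Resolution at an FSC threshold
#'
#' The lowest-frequency crossing of the threshold, linearly interpolated
#' between shells; Nyquist resolution (2 x pixel size) if the curve never
#' crosses.
#'
#' @param curve an [fsc_curve()]
#' @param threshold FSC threshold (0.143 for half-map curves)
#' @return resolution in Angstrom
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  f <- curve$freq
  v <- curve$fsc
  if (length(f) == 0) stop("empty FSC curve")
  below <- which(v < threshold)
  if (length(below) == 0 || below[1] == 1) {
    if (length(below) > 0 && below[1] == 1) return(1 / f[1])
    return(if (is.na(curve$pixel_size)) 1 / max(f) else
      2 * curve$pixel_size)
  }
  i <- below[1]
  ## linear interpolation between shells i-1 and i
  f_cross <- f[i - 1] + (f[i] - f[i - 1]) *
    (v[i - 1] - threshold) / (v[i - 1] - v[i])
  1 / f_cross
}

#' Correct a map for the detector modulation transfer function
#'
#' Divides the Fourier amplitudes by the MTF, interpolated linearly in
#' fraction of Nyquist between the tabulated points.
#'
#' @param map a [voxel_grid3d()]
#' @param mtf a two-column matrix or data.frame: fraction of Nyquist in
#'   \[0, 1\] and MTF value in (0, 1\]
#' @return corrected [voxel_grid3d()]
#' @export
mtf_correct <- function(map, mtf) {
  mtf <- as.matrix(mtf)
  if (max(mtf[, 1]) < 1) stop("MTF table must extend to Nyquist")
  n <- grid_n(map)
  r <- fourier_radius(n, 3) / (n / 2)     # fraction of Nyquist (3D radius)
  ## corner voxels beyond the Nyquist sphere use the value at Nyquist
  vals <- stats::approx(mtf[, 1], mtf[, 2], xout = pmin(r, 1),
                        rule = 2)$y
  if (any(vals <= 0.01))
    stop("MTF below 0.01 inside Nyquist: correction would blow up")
  fa <- ft(map$values) / array(vals, dim(r))
  voxel_grid3d(Re(ift(fa)), map$voxel_size)
}

#' Guinier B-factor estimate
#'
#' Least-squares slope of `ln` (spherically averaged structure-factor
#' amplitude) against `1/d^2`; `B = -4 x slope`.  Positive B means the map
#' amplitudes fall off as `exp(-B nu^2 / 4)`; sharpening applies the
#' negative.
#'
#' @param map a [voxel_grid3d()]
#' @param fit_range frequency range in 1/Angstrom, default from 1/10 to the
#'   Nyquist edge
#' @return class `guinier_fit`: `bfactor` (A^2), `intercept`, `fit_range`,
#'   `n_shells`
#' @export
estimate_bfactor <- function(map, fit_range = NULL) {
  n <- grid_n(map)
  ps <- map$voxel_size
  if (is.null(fit_range)) fit_range <- c(1 / 10, (n / 2 - 1) / (n * ps))
  shells <- 1:(n_shells(n) - 1)
  freq <- shells / (n * ps)
  amp <- sqrt(shell_power(ft(map$values))[-1])
  use <- freq >= fit_range[1] & freq <= fit_range[2]
  if (sum(use) < 4) stop("need at least 4 shells in the fit range")
  if (any(amp[use] <= 0)) stop("non-positive amplitudes in fit range")
  fit <- stats::lm.fit(cbind(1, freq[use]^2), log(amp[use]))
  structure(list(bfactor = -4 * fit$coefficients[[2]],
                 intercept = fit$coefficients[[1]],
                 fit_range = fit_range, n_shells = sum(use)),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf(
    "<guinier_fit> B = %.1f A^2 over %.3f-%.3f 1/A (%d shells)\n",
    x$bfactor, x$fit_range[1], x$fit_range[2], x$n_shells))
  invisible(x)
}

#' Sharpen (or dampen) a map by a B-factor and low-pass filter it
#'
#' Multiplies the amplitudes by `exp(-bfactor nu^2 / 4)` (negative bfactor
#' amplifies high frequencies), then applies a low-pass at `lowpass`
#' Angstrom with a 2-shell raised-cosine edge.
#'
#' @param map a [voxel_grid3d()]
#' @param bfactor A^2 (negative sharpens)
#' @param lowpass resolution in Angstrom, or NULL/Nyquist for none
#' @return filtered [voxel_grid3d()]
#' @export
sharpen <- function(map, bfactor, lowpass = NULL) {
  stopifnot(is.finite(bfactor))
  n <- grid_n(map)
  ps <- map$voxel_size
  nu2 <- (fourier_radius(n, 3) / (n * ps))^2
  fa <- ft(map$values) * exp(-bfactor * nu2 / 4)
  if (!is.null(lowpass) && lowpass > 2 * ps) {
    fa <- fa * lowpass_transfer(n, 3, resolution_to_shell(lowpass, n, ps))
  }
  voxel_grid3d(Re(ift(fa)), ps)
}

#' Rosenthal-Henderson particle-number extrapolation
#'
#' Solves `ln(n2/n1) = (B/2) (1/d2^2 - 1/d1^2)` for the resolution `d2`
#' expected when the particle number changes from `n1` to `n2` under an
#' amplitude-decay B-factor of magnitude `B`.
#'
#' @param B B-factor magnitude in A^2 (> 0)
#' @param n1 current particle count
#' @param d1 current resolution in Angstrom
#' @param n2 target particle count
#' @return predicted resolution `d2` in Angstrom
#' @export
rh_extrapolate <- function(B, n1, d1, n2) {
  stopifnot(B > 0, n1 > 0, d1 > 0, n2 > 0)
  inv_d2_sq <- 2 * log(n2 / n1) / B + 1 / d1^2
  if (inv_d2_sq <= 0)
    stop("extrapolation out of validity: implied 1/d2^2 <= 0")
  1 / sqrt(inv_d2_sq)
}
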