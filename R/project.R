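## Fourier central-slice projection and subpixel shifting.

## Precompute the centred Fourier transform of a map once so that many
## slices can be extracted from it cheaply.  The map is zero-padded by
## `pad` (2 by default) before transforming: slices are then interpolated
## on a lattice twice as fine, which keeps the trilinear kernel's spectral
## leakage negligible.
make_projector <- function(volume, pad = 2L) {
  stopifnot(inherits(volume, "voxel_grid3d"), pad >= 1)
  n <- grid_n(volume)
  np <- pad * n
  padded <- array(0, c(np, np, np))
  at <- (np %/% 2 - n %/% 2) + seq_len(n)
  padded[at, at, at] <- volume$values
  structure(list(vft = ft(padded), n = n, pad = as.integer(pad),
                 ## padding shrinks unitary amplitudes by pad^(3/2)
                 scale = pad^1.5,
                 voxel_size = volume$voxel_size),
            class = "fourier_projector")
}

## rotation matrices of a set of poses as an npose x 9 matrix (column-major)
pose_matrix_rows <- function(angles) {
  if (is.null(dim(angles))) angles <- matrix(angles, nrow = 1)
  t(apply(angles, 1, function(a) as.numeric(rotation_matrix(a))))
}

## full-plane integer frequency list of an N-box
full_pixel_list <- function(n) {
  k <- freq_axis(n)
  list(kx = rep(k, times = n), ky = rep(k, each = n))
}

## phase ramp exp(-2 pi i k.d / N) that shifts an image by (dx, dy) pixels.
## The unpaired Nyquist frequency k = -N/2 gets the real factor cos(pi d),
## which keeps shifted real images exactly real (Hermitian ramp).
shift_ramp <- function(n, dx, dy) {
  k <- freq_axis(n)
  px <- exp(-2i * pi * k * dx / n)
  py <- exp(-2i * pi * k * dy / n)
  px[1] <- cos(pi * dx)
  py[1] <- cos(pi * dy)
  outer(px, py)
}

#' Project a map along the viewing axis of a pose
#'
#' Extracts the central Fourier slice of the map transform on the plane
#' perpendicular to the viewing direction (trilinear interpolation), applies
#' the phase ramp for the pose offsets, and back-transforms.  This is the
#' forward imaging model (before CTF) used by both the simulator and the
#' refinement engine.
#'
#' @param volume a [voxel_grid3d()] (or a prebuilt internal projector)
#' @param p a [pose()]
#' @return a [pixel_grid2d()] with the same pixel size
#' @export
project <- function(volume, p) {
  proj <- if (inherits(volume, "fourier_projector")) volume
          else make_projector(volume)
  n <- proj$n
  if (abs(p$offset_x) >= n / 4 || abs(p$offset_y) >= n / 4)
    stop("offsets beyond +-N/4 are not supported")
  px <- full_pixel_list(n)
  sl <- cpp_extract_slices(proj$vft, pose_matrix_rows(c(p$rot, p$tilt, p$psi)),
                           as.integer(px$kx * proj$pad),
                           as.integer(px$ky * proj$pad)) * proj$scale
  slice <- matrix(as.complex(sl), n, n)
  ## projection theorem: a sum over z equals sqrt(N) times the central
  ## slice under the unitary convention
  slice <- slice * sqrt(n)
  if (p$offset_x != 0 || p$offset_y != 0)
    slice <- slice * shift_ramp(n, p$offset_x, p$offset_y)
  pixel_grid2d(Re(ift(slice)), proj$voxel_size)
}

#' Shift an image by a (possibly subpixel) offset
#'
#' Fourier phase-ramp translation: exact for band-limited images, circular
#' at the box edge.  `apply_shift(apply_shift(I, dx, dy), -dx, -dy)`
#' recovers `I` to round-off.
#'
#' @param image a [pixel_grid2d()]
#' @param dx,dy shift in pixels (|dx|, |dy| < N/4)
#' @return shifted [pixel_grid2d()]
#' @export
apply_shift <- function(image, dx, dy) {
  stopifnot(inherits(image, "pixel_grid2d"))
  n <- grid_n(image)
  if (abs(dx) >= n / 4 || abs(dy) >= n / 4)
    stop("shifts beyond +-N/4 are not supported")
  if (dx == 0 && dy == 0) return(image)
  pixel_grid2d(Re(ift(ft(image$values) * shift_ramp(n, dx, dy))),
               image$pixel_size)
}
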