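#' Contrast transfer function parameters
#'
#' Microscope/imaging parameters of one particle (or micrograph): astigmatic
#' defocus in Angstrom (underfocus positive), the azimuth of the defocus_u
#' axis in degrees, acceleration voltage in kV, spherical aberration in mm
#' and the amplitude-contrast fraction.
#'
#' @param defocus_u,defocus_v defocus along the major/minor astigmatism axes
#'   (Angstrom, underfocus positive)
#' @param astig_angle azimuth of the `defocus_u` axis, degrees
#' @param voltage acceleration voltage, kV
#' @param spherical_aberration Cs, mm
#' @param amplitude_contrast fraction in (0, 1)
#' @return an object of class `ctf_params`
#' @export
ctf_params <- function(defocus_u, defocus_v = defocus_u, astig_angle = 0,
                       voltage = 300, spherical_aberration = 2.0,
                       amplitude_contrast = 0.1) {
  if (defocus_u <= 0 || defocus_v <= 0) stop("defocus must be positive")
  if (amplitude_contrast <= 0 || amplitude_contrast >= 1)
    stop("amplitude_contrast must be in (0, 1)")
  structure(list(defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, voltage = voltage,
                 spherical_aberration = spherical_aberration,
                 amplitude_contrast = amplitude_contrast),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf(
    "<ctf_params> defocus %.0f/%.0f A @ %.1f deg, %g kV, Cs %g mm, w %g\n",
    x$defocus_u, x$defocus_v, x$astig_angle, x$voltage,
    x$spherical_aberration, x$amplitude_contrast))
  invisible(x)
}

#' Relativistic electron wavelength
#'
#' @param voltage_kv acceleration voltage in kV
#' @return wavelength in Angstrom (about 0.0197 A at 300 kV)
#' @export
electron_wavelength <- function(voltage_kv) {
  v <- voltage_kv * 1e3
  12.2639 / sqrt(v + 0.97845e-6 * v^2)
}

#' Evaluate the contrast transfer function
#'
#' `CTF(nu) = -(sqrt(1 - w^2) sin(gamma) + w cos(gamma))` with phase
#' `gamma = pi * lambda * nu^2 * (df(azimuth) - lambda^2 nu^2 Cs * 1e7 / 2)`,
#' where `df(azimuth)` is the astigmatic defocus and `lambda` the
#' relativistic electron wavelength.  With underfocus positive this sign
#' convention makes protein contrast negative (dark) before any flipping;
#' set `invert = TRUE` for the opposite convention.
#'
#' @param params a [ctf_params()]
#' @param spatial_frequency nu in 1/Angstrom (vectorized, >= 0)
#' @param azimuth direction of nu in the image plane, degrees (vectorized)
#' @param invert flip the overall sign
#' @return CTF values in \[-1, 1\]
#' @export
ctf_evaluate <- function(params, spatial_frequency, azimuth = 0,
                         invert = FALSE) {
  if (any(spatial_frequency < 0)) stop("spatial_frequency must be >= 0")
  w <- params$amplitude_contrast
  lambda <- electron_wavelength(params$voltage)
  df_mean <- 0.5 * (params$defocus_u + params$defocus_v)
  df_diff <- 0.5 * (params$defocus_u - params$defocus_v)
  df <- df_mean + df_diff * cos(2 * deg2rad(azimuth - params$astig_angle))
  nu2 <- spatial_frequency^2
  gamma <- pi * lambda * nu2 *
    (df - 0.5 * lambda^2 * nu2 * params$spherical_aberration * 1e7)
  ctf <- -(sqrt(1 - w^2) * sin(gamma) + w * cos(gamma))
  if (invert) -ctf else ctf
}

## CTF evaluated on the centred Fourier grid of an N-box with `pixel_size`;
## returns an N x N matrix aligned with `ft()` output
ctf_image <- function(params, n, pixel_size, invert = FALSE) {
  k <- freq_axis(n)
  kx <- matrix(k, n, n)
  ky <- t(kx)
  nu <- sqrt(kx^2 + ky^2) / (n * pixel_size)
  az <- rad2deg(atan2(ky, kx))
  matrix(ctf_evaluate(params, as.numeric(nu), as.numeric(az), invert), n, n)
}
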