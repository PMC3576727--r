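## Centred, unitary Fourier transforms and shell bookkeeping.
##
## All real-space arrays put the object centre at 0-based index N/2
## (1-based N/2 + 1).  Fourier arrays are stored centred the same way, so
## index i along any axis corresponds to integer frequency i - (N/2 + 1)
## cycles per box.  Transforms are unitary (1/sqrt(n) each way), which makes
## Parseval checks exact and keeps noise variance identical in both domains.

fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

ifftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) c((ceiling(n / 2) + 1):n, 1:ceiling(n / 2)))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

## centred forward/backward unitary FFTs (2D or 3D arrays)
ft <- function(x) {
  fftshift(fft(ifftshift(x))) / sqrt(length(x))
}

ift <- function(x) {
  fftshift(fft(ifftshift(x), inverse = TRUE)) / sqrt(length(x))
}

ift_real <- function(x) Re(ift(x))

## integer frequency along one axis of a centred length-N transform
freq_axis <- function(n) seq_len(n) - (n %/% 2 + 1)

## radius (in Fourier voxels) of every element of a centred N^d transform
fourier_radius <- function(n, d) {
  k <- freq_axis(n)
  if (d == 2) {
    kx <- matrix(k, n, n)
    sqrt(kx^2 + t(kx)^2)
  } else {
    k2 <- k^2
    r2 <- array(0, c(n, n, n))
    r2 <- outer(outer(k2, k2, `+`), k2, `+`)
    sqrt(r2)
  }
}

## shell index by rounded radius; shells 0 .. n/2 - 1 are "valid"
shell_index <- function(n, d) {
  round(fourier_radius(n, d))
}

## number of shells carried by an N-box noise model / FSC curve
n_shells <- function(n) n %/% 2

## per-shell mean of |x|^2 (x complex centred transform); shells 0..n/2-1
shell_power <- function(x) {
  n <- dim(x)[1]
  s <- shell_index(n, length(dim(x)))
  keep <- s < n_shells(n)
  as.numeric(tapply(abs(x[keep])^2, s[keep], mean))
}

## raised-cosine low-pass with a 2-shell edge, operating on a centred
## transform; `cutoff_shell` is the last fully-passed shell.
lowpass_transfer <- function(n, d, cutoff_shell, edge_shells = 2) {
  r <- fourier_radius(n, d)
  tr <- array(0, dim(r))
  tr[r <= cutoff_shell] <- 1
  band <- r > cutoff_shell & r < cutoff_shell + edge_shells
  tr[band] <- 0.5 * (1 + cos(pi * (r[band] - cutoff_shell) / edge_shells))
  tr
}

## resolution (Angstrom) of Fourier shell s for an N-box with given pixel size
shell_resolution <- function(shell, n, pixel_size) {
  n * pixel_size / shell
}

resolution_to_shell <- function(res, n, pixel_size) {
  n * pixel_size / res
}
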