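#' Cubic density map with a physical voxel size
#'
#' The currency of all 3D imaging operations: an N x N x N array of real
#' densities plus the edge length of one voxel in Angstrom.  N must be even
#' (the Fourier-space origin then sits at 0-based index N/2) and at least 16.
#'
#' @param values numeric N x N x N array, all finite
#' @param voxel_size voxel edge in Angstrom, > 0
#' @return an object of class `voxel_grid3d`
#' @export
voxel_grid3d <- function(values, voxel_size) {
  d <- dim(values)
  if (length(d) != 3 || length(unique(d)) != 1)
    stop("values must be a cubic N x N x N array")
  n <- d[1]
  if (n %% 2 != 0 || n < 16) stop("N must be even and >= 16")
  if (!all(is.finite(values))) stop("values must all be finite")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 || voxel_size <= 0)
    stop("voxel_size must be a positive scalar")
  structure(list(values = values, voxel_size = as.numeric(voxel_size)),
            class = "voxel_grid3d")
}

#' Square image with a physical pixel size
#'
#' A single recorded frame or projection: an N x N array of real values plus
#' the pixel edge in Angstrom. N must be even.
#'
#' @param values numeric N x N matrix, all finite
#' @param pixel_size pixel edge in Angstrom, > 0
#' @return an object of class `pixel_grid2d`
#' @export
pixel_grid2d <- function(values, pixel_size) {
  d <- dim(values)
  if (length(d) != 2 || d[1] != d[2]) stop("values must be a square matrix")
  if (d[1] %% 2 != 0) stop("N must be even")
  if (!all(is.finite(values))) stop("values must all be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("pixel_size must be a positive scalar")
  structure(list(values = values, pixel_size = as.numeric(pixel_size)),
            class = "pixel_grid2d")
}

#' @export
print.voxel_grid3d <- function(x, ...) {
  n <- dim(x$values)[1]
  cat(sprintf("<voxel_grid3d> %d^3 voxels, %.3f A/voxel (box %.1f A)\n",
              n, x$voxel_size, n * x$voxel_size))
  invisible(x)
}

#' @export
print.pixel_grid2d <- function(x, ...) {
  n <- dim(x$values)[1]
  cat(sprintf("<pixel_grid2d> %d^2 pixels, %.3f A/pixel\n", n, x$pixel_size))
  invisible(x)
}

#' @export
dim.voxel_grid3d <- function(x) dim(x$values)

#' @export
dim.pixel_grid2d <- function(x) dim(x$values)

grid_n <- function(x) dim(x$values)[1]

#' Nyquist resolution of a grid (2 x pixel size, in Angstrom)
#' @param x a `voxel_grid3d` or `pixel_grid2d`
#' @return Angstrom
#' @export
nyquist_resolution <- function(x) {
  ps <- if (inherits(x, "voxel_grid3d")) x$voxel_size else x$pixel_size
  2 * ps
}

#' Read an MRC-format density map or image
#'
#' Minimal reader for MRC2014 mode-2 (float32) files as exchanged between
#' single-particle packages.  The voxel size is taken from the cell
#' dimensions divided by the grid size.  A 2D file (NZ = 1) is returned as a
#' [pixel_grid2d()], otherwise a [voxel_grid3d()].
#'
#' @param path file path
#' @return `voxel_grid3d` or `pixel_grid2d`
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 256, size = 4, endian = "little")
  seek(con, 0)
  hdr_num <- readBin(con, "numeric", n = 256, size = 4, endian = "little")
  nx <- hdr_int[1]; ny <- hdr_int[2]; nz <- hdr_int[3]
  mode <- hdr_int[4]
  if (mode != 2) stop("only MRC mode 2 (float32) is supported")
  cella <- hdr_num[11:13]
  nsymbt <- hdr_int[24]
  seek(con, 1024 + nsymbt)
  dat <- readBin(con, "numeric", n = nx * ny * nz, size = 4, endian = "little")
  vs <- if (cella[1] > 0) cella[1] / nx else 1
  if (nz == 1) {
    pixel_grid2d(matrix(dat, nx, ny), vs)
  } else {
    voxel_grid3d(array(dat, c(nx, ny, nz)), vs)
  }
}

#' Write a density map or image in MRC format (mode 2, float32)
#'
#' @param x a `voxel_grid3d` or `pixel_grid2d`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_mrc <- function(x, path) {
  if (inherits(x, "pixel_grid2d")) {
    d <- c(dim(x$values), 1L)
    vs <- x$pixel_size
    vals <- as.numeric(x$values)
  } else {
    d <- dim(x$values)
    vs <- x$voxel_size
    vals <- as.numeric(x$values)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(d)                       # NX NY NZ
  wi(2)                       # MODE float32
  wi(c(0, 0, 0))              # NXSTART..
  wi(d)                       # MX MY MZ
  wf(d * vs)                  # CELLA
  wf(c(90, 90, 90))           # CELLB
  wi(c(1, 2, 3))              # MAPC MAPR MAPS
  wf(c(min(vals), max(vals), mean(vals)))  # DMIN DMAX DMEAN
  wi(c(1, 0))                 # ISPG, NSYMBT
  wi(rep(0, 25))              # EXTRA
  wf(c(0, 0, 0))              # ORIGIN
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(stats::sd(vals))         # RMS
  wi(0)                       # NLABL
  writeBin(raw(800), con)     # labels
  wf(vals)
  invisible(path)
}
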