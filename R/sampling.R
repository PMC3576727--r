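## Orientation and translation sampling grids.

#' Build an orientation/translation sampling grid
#'
#' Global grids cover SO(3) quasi-uniformly: tilt rings every `angular_step`
#' degrees from 0 to 180, `round(360 sin(tilt)/step)` rot values per ring
#' (one at the poles), and psi sampled every `angular_step` over 360.
#' Local grids perturb a centre pose: viewing-direction offsets on rings of
#' spacing `angular_step` out to `angular_range`, combined with psi offsets
#' on the same 1D grid, composed on the right of the centre rotation (so
#' the geodesic distance from the centre is close to the nominal
#' perturbation).  Local grids always contain their centre.
#'
#' @param angular_step degrees (> 0)
#' @param trans_range,trans_step translation search in pixels (range may be
#'   0 for no translational search)
#' @param center a [pose()] for local grids; NULL builds a global grid
#' @param angular_range local search radius in degrees
#' @return class `sampling_grid`: list with `angles` (n x 3 Euler rows),
#'   `rmats` (n x 9), `shifts` (m x 2), `angular_step`, `local`
#' @export
sampling_grid <- function(angular_step, trans_range = 0, trans_step = 1,
                          center = NULL, angular_range = NULL) {
  stopifnot(angular_step > 0, trans_step > 0)
  if (is.null(center)) {
    tilts <- seq(0, 180, by = angular_step)
    ang <- do.call(rbind, lapply(tilts, function(tl) {
      nr <- max(1, round(360 * sin(deg2rad(tl)) / angular_step))
      rots <- seq(0, 360 - 360 / nr, length.out = nr) - 180
      cbind(rot = rots, tilt = tl)
    }))
    psis <- seq(-180, 180 - angular_step, by = angular_step)
    angles <- cbind(rot = rep(ang[, 1], each = length(psis)),
                    tilt = rep(ang[, 2], each = length(psis)),
                    psi = rep(psis, times = nrow(ang)))
    local <- FALSE
  } else {
    if (is.null(angular_range)) angular_range <- 2 * angular_step
    R0 <- rotation_matrix(center)
    ## direction perturbations: rings of spacing `angular_step`
    dirs <- list(c(0, 0))
    radii <- seq(angular_step, angular_range + 1e-9, by = angular_step)
    for (rho in radii) {
      m <- max(1, round(2 * pi * rho / angular_step))
      th <- seq(0, 2 * pi - 2 * pi / m, length.out = m)
      dirs <- c(dirs, lapply(th, function(t) c(rho, t)))
    }
    dpsis <- seq(-angular_range, angular_range, by = angular_step)
    ## ensure 0 is on the psi grid
    if (min(abs(dpsis)) > 1e-9) dpsis <- sort(c(0, dpsis))
    combos <- expand.grid(d = seq_along(dirs), dpsi = dpsis)
    angles <- t(vapply(seq_len(nrow(combos)), function(k) {
      dd <- dirs[[combos$d[k]]]
      ## tilt the viewing axis by rho towards azimuth theta, then twist
      dR <- rot_z(rad2deg(dd[2])) %*% rot_y(dd[1]) %*%
        rot_z(-rad2deg(dd[2])) %*% rot_z(combos$dpsi[k])
      euler_from_matrix(R0 %*% dR)
    }, numeric(3)))
    colnames(angles) <- c("rot", "tilt", "psi")
    local <- TRUE
  }
  if (trans_range > 0) {
    s <- seq(-trans_range, trans_range, by = trans_step)
    if (min(abs(s)) > 1e-9) s <- sort(c(0, s))
    shifts <- as.matrix(expand.grid(dx = s, dy = s))
  } else {
    shifts <- matrix(0, 1, 2, dimnames = list(NULL, c("dx", "dy")))
  }
  if (!is.null(center)) {
    shifts[, 1] <- shifts[, 1] + center$offset_x
    shifts[, 2] <- shifts[, 2] + center$offset_y
  }
  structure(list(angles = angles, rmats = pose_matrix_rows(angles),
                 shifts = shifts, angular_step = angular_step,
                 angular_range = if (local) angular_range else 180,
                 local = local, center = center),
            class = "sampling_grid")
}

#' @export
print.sampling_grid <- function(x, ...) {
  cat(sprintf(
    "<sampling_grid> %s, %d orientations @ %.3g deg, %d translations\n",
    if (x$local) "local" else "global", nrow(x$angles), x$angular_step,
    nrow(x$shifts)))
  invisible(x)
}
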