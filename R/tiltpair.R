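## Tilt-pair validation: the relative rotation between independently
## refined orientations of an untilted/tilted image pair should equal the
## known microscope tilt; deviations measure alignment error.

#' Tilt-pair geometry
#'
#' @param tilt_angle stage tilt in degrees (0 < angle < 90; 10 by default)
#' @param tilt_axis_azimuth in-plane direction of the tilt axis, degrees
#' @return an object of class `tilt_geometry`
#' @export
tilt_geometry <- function(tilt_angle = 10, tilt_axis_azimuth = 0) {
  if (tilt_angle <= 0 || tilt_angle >= 90)
    stop("tilt_angle must be in (0, 90)")
  structure(list(tilt_angle = tilt_angle,
                 tilt_axis_azimuth = tilt_axis_azimuth),
            class = "tilt_geometry")
}

## rotation matrix of the stage tilt
tilt_rotation <- function(geometry) {
  az <- deg2rad(geometry$tilt_axis_azimuth)
  axis_angle_matrix(c(cos(az), sin(az), 0), geometry$tilt_angle)
}

#' Angular error of one tilt pair
#'
#' The geodesic angle of `R_tilted (R_geometry R_untilted)^-1`: zero when
#' the two independently determined orientations are exactly consistent
#' with the stage tilt.  In-plane psi and offsets enter only through the
#' full rotation matrices; the metric is the standard geodesic distance on
#' SO(3).
#'
#' @param pose_untilted,pose_tilted [pose()] objects from the two
#'   independent refinements
#' @param geometry a [tilt_geometry()]
#' @return error in degrees, in \[0, 180\]
#' @export
pair_error <- function(pose_untilted, pose_tilted, geometry) {
  expected <- tilt_rotation(geometry) %*% rotation_matrix(pose_untilted)
  rotation_distance(rotation_matrix(pose_tilted), expected)
}

#' Estimate the tilt-axis azimuth from pose pairs
#'
#' The true in-plane direction of the tilt axis is unknown on a real
#' microscope; it is recovered by a grid search over the azimuth (0.5
#' degree steps over the full circle, refined to 0.05 degrees) minimizing
#' the median pair error, which tolerates up to half the pairs being
#' misaligned.
#'
#' @param pairs data.frame with columns `rot1, tilt1, psi1, rot2, tilt2,
#'   psi2` (untilted / tilted Euler angles, degrees); >= 20 rows
#' @param geometry starting [tilt_geometry()] (fixes the tilt angle)
#' @return a [tilt_geometry()] with the fitted azimuth
#' @export
estimate_axis <- function(pairs, geometry) {
  if (nrow(pairs) < 20) stop("need at least 20 pairs")
  R1 <- lapply(seq_len(nrow(pairs)), function(i)
    rotation_matrix(c(pairs$rot1[i], pairs$tilt1[i], pairs$psi1[i])))
  R2 <- lapply(seq_len(nrow(pairs)), function(i)
    rotation_matrix(c(pairs$rot2[i], pairs$tilt2[i], pairs$psi2[i])))
  med_err <- function(az) {
    g <- tilt_geometry(geometry$tilt_angle, az)
    Rt <- tilt_rotation(g)
    stats::median(vapply(seq_along(R1), function(i)
      rotation_distance(R2[[i]], Rt %*% R1[[i]]), numeric(1)))
  }
  coarse <- seq(0, 359.5, by = 0.5)
  e1 <- vapply(coarse, med_err, numeric(1))
  a0 <- coarse[which.min(e1)]
  fine <- seq(a0 - 0.5, a0 + 0.5, by = 0.05)
  e2 <- vapply(fine, med_err, numeric(1))
  tilt_geometry(geometry$tilt_angle, wrap180(fine[which.min(e2)]) %% 360)
}

#' Alignment precision and misaligned count from tilt-pair errors
#'
#' Histograms the errors from zero upward in half-open bins of
#' `bin_width`, finds the first contiguous peak, and measures its width at
#' half its maximum count (linear interpolation between bin centres; when
#' the peak sits in the first bin the left half-width is mirrored from the
#' right).  That width is the tilt-pair alignment precision, floored at
#' one bin width.  Pairs with errors larger than three times the precision
#' are counted as aligned incorrectly.
#'
#' @param errors numeric vector of pair errors in degrees (>= 1 value)
#' @param bin_width histogram bin width in degrees (0.5 by default)
#' @param precision optional fixed precision (degrees) overriding the
#'   peak-width measurement (only the misaligned count is then computed)
#' @return class `tilt_pair_result`: `precision` (degrees),
#'   `n_misaligned`, `n_total`, `histogram` (data.frame), `errors`
#' @export
precision_and_misaligned <- function(errors, bin_width = 0.5,
                                     precision = NULL) {
  if (length(errors) == 0) stop("no error values")
  if (bin_width <= 0) stop("bin_width must be positive")
  if (any(errors < 0 | errors > 180)) stop("errors must be in [0, 180]")
  nb <- max(1, ceiling((max(errors) + 1e-9) / bin_width))
  bins <- pmin(floor(errors / bin_width), nb - 1)  # half-open [k w, (k+1) w)
  counts <- as.numeric(table(factor(bins, levels = 0:(nb - 1))))
  centers <- (0:(nb - 1) + 0.5) * bin_width
  if (is.null(precision)) {
    ## first local maximum scanning from zero
    pk <- nb
    for (k in seq_len(nb)) {
      if (counts[k] > 0 && (k == nb || counts[k] >= counts[k + 1])) {
        pk <- k
        break
      }
    }
    hmax <- counts[pk] / 2
    ## absolute position of the half-height crossing right of the peak,
    ## linearly interpolated between bin centres; NA when the histogram
    ## ends before crossing
    j <- pk
    while (j < nb && counts[j + 1] >= hmax) j <- j + 1
    right_cross <- if (j == nb) NA_real_ else
      centers[j] + (counts[j] - hmax) / (counts[j] - counts[j + 1]) *
        bin_width
    if (is.na(right_cross)) {
      width <- 0  # degenerate peak: floored below
    } else if (pk == 1) {
      ## peak touches zero: treat it as centred at 0 and mirror
      width <- 2 * right_cross
    } else {
      j <- pk
      while (j > 1 && counts[j - 1] >= hmax) j <- j - 1
      left_cross <- if (j == 1) 2 * centers[pk] - right_cross else
        centers[j] - (counts[j] - hmax) / (counts[j] - counts[j - 1]) *
          bin_width
      width <- right_cross - left_cross
    }
    precision <- max(bin_width, width)
  }
  n_mis <- sum(errors > 3 * precision)
  structure(list(precision = precision, n_misaligned = n_mis,
                 n_total = length(errors),
                 histogram = data.frame(center = centers, count = counts),
                 bin_width = bin_width, errors = errors),
            class = "tilt_pair_result")
}

#' @export
print.tilt_pair_result <- function(x, ...) {
  cat(sprintf(
    "<tilt_pair_result> precision %.2f deg; %d / %d pairs misaligned (> %.1f deg)\n",
    x$precision, x$n_misaligned, x$n_total, 3 * x$precision))
  invisible(x)
}

#' @export
plot.tilt_pair_result <- function(x, ...) {
  graphics::barplot(x$histogram$count, names.arg = x$histogram$center,
                    xlab = "tilt-pair alignment error (deg)",
                    ylab = "pairs", ...)
  invisible(x)
}

#' Exposure-total motion summary from frame tracks
#'
#' Per particle, the total rotation is the geodesic angle between the first
#' and last frame orientations, and the total translation the Euclidean
#' distance (in Angstrom) between the first and last offsets; returns
#' means and standard deviations over particles.
#'
#' @param tracks list of [align_frames()] results (or any objects with a
#'   `track` data.frame)
#' @param pixel_size A/pixel used to convert offsets to Angstrom
#' @return list with `rotation` and `translation`, each `c(mean, sd)`
#'   (degrees / Angstrom)
#' @export
exposure_motion_summary <- function(tracks, pixel_size) {
  if (any(vapply(tracks, function(t) nrow(t$track), integer(1)) < 2))
    stop("tracks must have at least 2 frames")
  tot <- t(vapply(tracks, function(t) {
    f <- nrow(t$track)
    r <- rotation_distance(track_pose(t, 1), track_pose(t, f))
    d <- sqrt((t$track$offset_x[f] - t$track$offset_x[1])^2 +
                (t$track$offset_y[f] - t$track$offset_y[1])^2) * pixel_size
    c(r, d)
  }, numeric(2)))
  list(rotation = c(mean = mean(tot[, 1]), sd = stats::sd(tot[, 1])),
       translation = c(mean = mean(tot[, 2]), sd = stats::sd(tot[, 2])))
}
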