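#' Particle orientation: three Euler angles plus an in-plane translation
#'
#' Angles follow the ZYZ intrinsic convention used throughout the
#' single-particle ecosystem: the rotation applied to the map before
#' projecting along z is `R = Rz(rot) %*% Ry(tilt) %*% Rz(psi)` (degrees).
#' `tilt` is kept in \[0, 180\]; `rot` and `psi` are normalized to
#' \[-180, 180).  Offsets are the translation, in pixels, applied to the
#' projected image (positive moves density towards larger x/y).
#'
#' @param rot,tilt,psi Euler angles in degrees
#' @param offset_x,offset_y translation in pixels
#' @return an object of class `pose`
#' @export
pose <- function(rot = 0, tilt = 0, psi = 0, offset_x = 0, offset_y = 0) {
  v <- c(rot, tilt, psi, offset_x, offset_y)
  if (!all(is.finite(v))) stop("invalid pose: non-finite components")
  if (tilt < 0 || tilt > 180) {
    ## fold tilt back into [0, 180] by the ZYZ identity
    ## (rot, -tilt, psi) == (rot + 180, tilt, psi - 180)
    tilt <- wrap180(tilt)
    if (tilt < 0) {
      tilt <- -tilt
      rot <- rot + 180
      psi <- psi - 180
    }
  }
  structure(list(rot = wrap180(rot), tilt = tilt, psi = wrap180(psi),
                 offset_x = offset_x, offset_y = offset_y),
            class = "pose")
}

## normalize an angle (degrees) to [-180, 180)
wrap180 <- function(a) ((a + 180) %% 360) - 180

#' @export
print.pose <- function(x, ...) {
  cat(sprintf(
    "<pose> rot=%.3f tilt=%.3f psi=%.3f deg, offsets=(%.3f, %.3f) px\n",
    x$rot, x$tilt, x$psi, x$offset_x, x$offset_y))
  invisible(x)
}

deg2rad <- function(a) a * pi / 180
rad2deg <- function(a) a * 180 / pi

rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Rotation matrix of a pose (ZYZ intrinsic)
#'
#' @param p a [pose()], or a numeric vector `c(rot, tilt, psi)` in degrees
#' @return 3x3 orthonormal matrix `Rz(rot) %*% Ry(tilt) %*% Rz(psi)` with
#'   determinant +1
#' @export
rotation_matrix <- function(p) {
  if (inherits(p, "pose")) p <- c(p$rot, p$tilt, p$psi)
  if (!is.numeric(p) || length(p) != 3 || !all(is.finite(p)))
    stop("invalid pose: need three finite Euler angles")
  rot_z(p[1]) %*% rot_y(p[2]) %*% rot_z(p[3])
}

#' Euler angles (ZYZ, degrees) of a rotation matrix
#'
#' Inverse of [rotation_matrix()].  At the gimbal singularity (tilt = 0 or
#' 180) `rot` is set to 0 and the in-plane angle is carried by `psi`.
#'
#' @param R 3x3 rotation matrix
#' @return numeric `c(rot, tilt, psi)` in degrees
#' @export
euler_from_matrix <- function(R) {
  ct <- max(-1, min(1, R[3, 3]))
  tilt <- acos(ct)
  if (sin(tilt) > 1e-9) {
    rot <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else if (ct > 0) {
    ## tilt = 0: R = Rz(rot + psi)
    rot <- 0
    psi <- atan2(R[2, 1], R[1, 1])
  } else {
    ## tilt = 180: R = Ry(180) Rz(psi - rot)
    rot <- 0
    psi <- atan2(R[2, 1], R[2, 2])
  }
  c(rot = wrap180(rad2deg(rot)), tilt = rad2deg(tilt),
    psi = wrap180(rad2deg(psi)))
}

#' Geodesic angle (degrees) between two rotations
#'
#' The rotation angle of `R1 %*% t(R2)`: the canonical SO(3) distance used
#' for tilt-pair errors and angular priors.
#'
#' @param R1,R2 3x3 rotation matrices (or [pose()] objects)
#' @return angle in degrees, in \[0, 180\]
#' @export
rotation_distance <- function(R1, R2 = diag(3)) {
  if (inherits(R1, "pose")) R1 <- rotation_matrix(R1)
  if (inherits(R2, "pose")) R2 <- rotation_matrix(R2)
  tr <- sum(diag(R1 %*% t(R2)))
  rad2deg(acos(max(-1, min(1, (tr - 1) / 2))))
}

## rotation by `angle` degrees about unit axis `u` (Rodrigues)
axis_angle_matrix <- function(u, angle) {
  u <- u / sqrt(sum(u^2))
  a <- deg2rad(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## left-compose a lab-frame rotation matrix onto a pose's orientation,
## keeping the pose offsets
compose_rotation <- function(R_left, p) {
  e <- euler_from_matrix(R_left %*% rotation_matrix(p))
  pose(e[1], e[2], e[3], p$offset_x, p$offset_y)
}

## project an arbitrary 3x3 matrix onto SO(3) (polar decomposition via SVD);
## used for posterior-weighted mean orientations
nearest_rotation <- function(M) {
  s <- svd(M)
  d <- diag(c(1, 1, sign(det(s$u %*% t(s$v)))))
  s$u %*% d %*% t(s$v)
}

## angle (deg) between the viewing directions (third Euler axis) of two
## rotations; ignores the in-plane angle psi
direction_distance <- function(R1, R2) {
  v1 <- R1[3, ]
  v2 <- R2[3, ]
  rad2deg(acos(max(-1, min(1, sum(v1 * v2)))))
}
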