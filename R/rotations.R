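## Rotation utilities shared by the symmetry and sub-particle machinery.
## Euler angles follow the ZYZ intrinsic (rot, tilt, psi) convention used by
## RELION-style particle tables: A(rot, tilt, psi) = Rz(psi) Ry(tilt) Rz(rot),
## mapping reference-frame (map) coordinates into the particle/image frame.

#' Elementary rotation matrices
#'
#' Proper rotations about the z or y axis by an angle in degrees.
#'
#' @param deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @keywords internal
rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

#' @rdname rot_z
#' @keywords internal
rot_y <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), 0, -sin(th),
           0, 1, 0,
           sin(th), 0, cos(th)), 3, 3)
}

#' Rotation about an arbitrary axis
#'
#' Rodrigues rotation by `deg` degrees about the (not necessarily unit)
#' axis `axis`.
#'
#' @param axis Numeric length-3 axis direction.
#' @param deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @export
rot_about_axis <- function(axis, deg) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- deg * pi / 180
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Convert ZYZ Euler angles to a rotation matrix
#'
#' The convention is the particle-table one: `A = Rz(psi) Ry(tilt) Rz(rot)`,
#' taking reference-frame coordinates to the particle frame; projecting the
#' rotated map along z gives the particle image.
#'
#' @param rot,tilt,psi Euler angles in degrees (vectorised; recycled to a
#'   common length).
#' @return A 3x3 matrix for scalar input, otherwise a `3 x 3 x n` array.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  n <- max(length(rot), length(tilt), length(psi))
  rot <- rep_len(rot, n) * pi / 180
  tilt <- rep_len(tilt, n) * pi / 180
  psi <- rep_len(psi, n) * pi / 180
  ca <- cos(rot); sa <- sin(rot)
  cb <- cos(tilt); sb <- sin(tilt)
  cg <- cos(psi); sg <- sin(psi)
  A <- array(0, c(3, 3, n))
  A[1, 1, ] <- cg * cb * ca - sg * sa
  A[1, 2, ] <- -cg * cb * sa - sg * ca
  A[1, 3, ] <- cg * sb
  A[2, 1, ] <- sg * cb * ca + cg * sa
  A[2, 2, ] <- -sg * cb * sa + cg * ca
  A[2, 3, ] <- sg * sb
  A[3, 1, ] <- -sb * ca
  A[3, 2, ] <- sb * sa
  A[3, 3, ] <- cb
  if (n == 1) A[, , 1] else A
}

#' Recover ZYZ Euler angles from rotation matrices
#'
#' Inverse of [euler_to_matrix()]. At the gimbal-lock poles
#' (tilt = 0 or 180 degrees) `rot` is set to 0 and the full in-plane angle is
#' carried by `psi`.
#'
#' @param A A 3x3 rotation matrix or a `3 x 3 x n` array.
#' @return A data frame with columns `rot`, `tilt`, `psi` in degrees.
#' @export
matrix_to_euler <- function(A) {
  if (length(dim(A)) == 2) A <- array(A, c(3, 3, 1))
  cb <- pmin(1, pmax(-1, A[3, 3, ]))
  tilt <- acos(cb)
  sb <- sin(tilt)
  degen <- sb < 1e-9
  rot <- ifelse(degen, 0, atan2(A[3, 2, ], -A[3, 1, ]))
  psi <- ifelse(degen, 0, atan2(A[2, 3, ], A[1, 3, ]))
  ## gimbal lock: tilt ~ 0 gives A = Rz(psi + rot); tilt ~ 180 gives
  ## A = Rz(psi - rot) Ry(180), whose first column is (-cos, -sin, 0)
  up <- degen & cb > 0
  dn <- degen & cb < 0
  psi[up] <- atan2(A[2, 1, up], A[1, 1, up])
  psi[dn] <- atan2(-A[2, 1, dn], -A[1, 1, dn])
  data.frame(rot = rot * 180 / pi,
             tilt = tilt * 180 / pi,
             psi = psi * 180 / pi)
}

#' Minimal rotation taking the z axis onto a direction
#'
#' Returns the rotation `Q` with `Q %*% c(0, 0, 1)` equal to the unit vector
#' along `v`, rotating about the axis `z x v` (the unique rotation with no
#' in-plane twist). For `v` antiparallel to z the 180-degree rotation about x
#' is returned; this degenerate choice is the documented in-plane reference.
#'
#' @param v Numeric length-3 direction (need not be unit length).
#' @return A 3x3 rotation matrix.
#' @export
align_z_to <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("direction must be non-zero")
  u <- v / n
  z <- c(0, 0, 1)
  c_th <- sum(z * u)
  if (c_th > 1 - 1e-12) return(diag(3))
  if (c_th < -1 + 1e-12) return(rot_about_axis(c(1, 0, 0), 180))
  axis <- c(z[2] * u[3] - z[3] * u[2],
            z[3] * u[1] - z[1] * u[3],
            z[1] * u[2] - z[2] * u[1])
  rot_about_axis(axis, acos(c_th) * 180 / pi)
}

#' Uniform random rotations
#'
#' Samples rotation matrices uniformly over SO(3) via normalised quaternions
#' drawn from four independent standard normals (subgroup-free sampling).
#' Uses the current RNG stream.
#'
#' @param n Number of rotations.
#' @return A `3 x 3 x n` array of rotation matrices.
#' @export
random_rotations <- function(n) {
  q <- matrix(stats::rnorm(4 * n), n, 4)
  q <- q / sqrt(rowSums(q^2))
  w <- q[, 1]; x <- q[, 2]; y <- q[, 3]; z <- q[, 4]
  A <- array(0, c(3, 3, n))
  A[1, 1, ] <- 1 - 2 * (y^2 + z^2)
  A[1, 2, ] <- 2 * (x * y - w * z)
  A[1, 3, ] <- 2 * (x * z + w * y)
  A[2, 1, ] <- 2 * (x * y + w * z)
  A[2, 2, ] <- 1 - 2 * (x^2 + z^2)
  A[2, 3, ] <- 2 * (y * z - w * x)
  A[3, 1, ] <- 2 * (x * z - w * y)
  A[3, 2, ] <- 2 * (y * z + w * x)
  A[3, 3, ] <- 1 - 2 * (x^2 + y^2)
  A
}
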