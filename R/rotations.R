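# Rotation algebra shared by the simulator, reconstruction and kinematics code.
# All angles are degrees; rotation matrices are 3x3, right-handed, det +1.

.DEG2RAD <- pi / 180

#' Elementary rotation matrices
#'
#' Right-handed rotations about the lab x, y and z axes.
#'
#' @param deg Rotation angle in degrees.
#' @return A 3x3 rotation matrix.
#' @name elementary-rotations
NULL

#' @rdname elementary-rotations
#' @export
rot_x <- function(deg) {
  a <- deg * .DEG2RAD
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

#' @rdname elementary-rotations
#' @export
rot_y <- function(deg) {
  a <- deg * .DEG2RAD
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}
# note: rot_y fills column-major, giving R[1,3] = +sin, R[3,1] = -sin

#' @rdname elementary-rotations
#' @export
rot_z <- function(deg) {
  a <- deg * .DEG2RAD
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

#' Compose a wrist rotation from Cardan angles
#'
#' The wrist rotation convention used throughout: an intrinsic y-z-x
#' (flexion, deviation, pronation) Cardan sequence,
#' \code{R = Ry(fe) Rz(rud) Rx(prosup)}. Rotation about x is pronation (+) /
#' supination (-), about y flexion (+) / extension (-), and about z
#' ulnar (+) / radial (-) deviation.
#'
#' @param prosup_deg Pronation(+)/supination(-) angle, degrees.
#' @param fe_deg Flexion(+)/extension(-) angle, degrees.
#' @param rud_deg Ulnar(+)/radial(-) deviation angle, degrees.
#' @return A 3x3 rotation matrix.
#' @seealso [decompose_angles()] for the inverse.
#' @export
cardan_rotation <- function(prosup_deg, fe_deg, rud_deg) {
  rot_y(fe_deg) %*% rot_z(rud_deg) %*% rot_x(prosup_deg)
}

#' Decompose a rotation into wrist Cardan angles
#'
#' Inverse of [cardan_rotation()]: extracts the intrinsic y-z-x sequence
#' (flexion, deviation, pronation). A warning is issued near gimbal lock
#' (|deviation| > 89 degrees), where the decomposition degrades.
#'
#' @param R 3x3 rotation matrix.
#' @return Named numeric vector \code{c(prosup_deg, fe_deg, rud_deg)}.
#' @export
decompose_angles <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  if (!is_rotation(R)) {
    stop("decompose_angles: input is not a proper rotation matrix")
  }
  s <- max(-1, min(1, R[2, 1]))
  rud <- asin(s)
  if (abs(rud) > 89 * .DEG2RAD) {
    warning(sprintf(
      "decompose_angles: deviation angle %.2f deg is near gimbal lock",
      rud / .DEG2RAD))
  }
  fe <- atan2(-R[3, 1], R[1, 1])
  prosup <- atan2(-R[2, 3], R[2, 2])
  c(prosup_deg = prosup / .DEG2RAD,
    fe_deg = fe / .DEG2RAD,
    rud_deg = rud / .DEG2RAD)
}

#' Test whether a matrix is a proper rotation
#'
#' @param R Matrix to test.
#' @param tol Orthonormality tolerance.
#' @return Logical scalar.
#' @export
is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) && all(is.finite(R)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Geodesic angle of a rotation
#'
#' The rotation angle (degrees) of a single rotation matrix, used to measure
#' rotation errors as the angle of \code{R_est \%*\% t(R_true)}.
#'
#' @param R 3x3 rotation matrix.
#' @return Angle in degrees, in \[0, 180\].
#' @export
rotation_angle_deg <- function(R) {
  # atan2 form: full precision for small angles, unlike acos((tr-1)/2)
  s <- 0.5 * vnorm(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  c <- (max(-1, min(3, sum(diag(R)))) - 1) / 2
  atan2(s, c) / .DEG2RAD
}

# Rotation <-> unit quaternion (w, x, y, z). Shepperd's method for stability.
rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# Chordal mean rotation of a list of rotation matrices via the dominant
# eigenvector of the quaternion outer-product sum (hemisphere-safe).
mean_rotation <- function(Rs) {
  Q <- vapply(Rs, rot_to_quat, numeric(4))
  M <- Q %*% t(Q)
  quat_to_rot(eigen(M, symmetric = TRUE)$vectors[, 1])
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps^0.5) stop("cannot normalize a zero vector")
  v / n
}
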