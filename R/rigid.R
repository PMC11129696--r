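# Orthogonal Procrustes rigid-body fitting of bead groups, and the pose
# series container used by the reconstruction chain.

#' Least-squares rigid-body transform between matched point sets
#'
#' Closed-form orthogonal Procrustes (SVD) solution minimizing
#' sum ||R p_i + t - q_i||^2 over proper rotations; reflections are excluded
#' by a sign correction on the smallest singular vector.
#'
#' @param reference Matrix (n x 3) of reference (CT-frame) positions, mm.
#' @param observed Matrix (n x 3) of matched observed positions, mm.
#' @return A `rigid_transform`: list with `R` (3x3, det +1), `t` (mm) and
#'   `residuals_mm` (per-marker fit residuals).
#' @export
fit_rigid_transform <- function(reference, observed) {
  P <- as.matrix(reference); Q <- as.matrix(observed)
  if (nrow(P) < 3 || !all(dim(P) == dim(Q))) {
    stop("rigid fit needs >= 3 matched 3D points")
  }
  if (any(!is.finite(P)) || any(!is.finite(Q))) {
    stop("rigid fit inputs contain non-finite values")
  }
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  if (svd(Pc, nu = 0, nv = 0)$d[2] < 1e-9) {
    stop("reference markers are collinear: rotation is not identifiable")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- qbar - as.numeric(R %*% pbar)
  fitted <- sweep(P %*% t(R), 2, t, `+`)
  structure(list(R = R, t = t,
                 residuals_mm = sqrt(rowSums((fitted - Q)^2))),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- decompose_angles(x$R)
  cat(sprintf(
    "Rigid transform: rotation %.2f deg, translation (%.2f, %.2f, %.2f) mm, RMS residual %.4f mm\n",
    rotation_angle_deg(x$R), x$t[1], x$t[2], x$t[3],
    sqrt(mean(x$residuals_mm^2))))
  invisible(x)
}

# Pose series: per-bone list(R = array [3,3,n], t = matrix [n,3]), plus fps.
pose_series <- function(bones, fps) {
  structure(list(bones = bones, fps = fps), class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  n <- dim(x$bones[[1]]$R)[3]
  cat(sprintf("Pose series: %d frames at %g fps, bones: %s\n", n, x$fps,
              paste(names(x$bones), collapse = ", ")))
  invisible(x)
}

n_pose_frames <- function(series) dim(series$bones[[1]]$R)[3]

pose_at <- function(series, bone, frame) {
  list(R = series$bones[[bone]]$R[, , frame],
       t = series$bones[[bone]]$t[frame, ])
}
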