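# Anatomical coordinate systems and wrist-angle extraction. Wrist motion is
# the rotation of the third-metacarpal coordinate system (MCS) about the
# radial coordinate system (RCS), with neutral defined as the alignment of
# the two frames; mounting offsets are removed with the static-trial pose.

anatomical_frame <- function(origin, x, y, z) {
  B <- unname(cbind(x, y, z))
  dimnames(B) <- NULL
  if (max(abs(crossprod(B) - diag(3))) > 1e-9 || det(B) < 0) {
    stop("anatomical frame axes must be right-handed orthonormal")
  }
  structure(list(origin = origin, R = B), class = "anatomical_frame")
}

#' Build the radial coordinate system from landmarks
#'
#' The x-axis runs along the distal radial shaft (proximal to distal); the
#' origin is the point where it meets the distal articular surface; the
#' y-axis is the component of the direction to the sigmoid notch center
#' orthogonal to x; z completes the right-handed frame.
#'
#' @param landmarks Named list of radius landmarks (mm, CT frame):
#'   `shaft_proximal`, `shaft_distal`, `articular_surface_point`,
#'   `sigmoid_notch_center`.
#' @return An `anatomical_frame` (origin + rotation whose columns are the
#'   frame axes in the CT frame).
#' @export
build_rcs <- function(landmarks) {
  need <- c("shaft_proximal", "shaft_distal", "articular_surface_point",
            "sigmoid_notch_center")
  .check_landmarks(landmarks, need)
  x <- unit(landmarks$shaft_distal - landmarks$shaft_proximal)
  origin <- landmarks$articular_surface_point
  w <- landmarks$sigmoid_notch_center - origin
  y <- w - sum(w * x) * x
  if (vnorm(y) < 1e-6) {
    stop("sigmoid notch center is collinear with the shaft axis: degenerate frame")
  }
  y <- unit(y)
  anatomical_frame(origin, x, y, pracma_cross(x, y))
}

#' Build the third-metacarpal coordinate system from landmarks
#'
#' The x-axis runs along the MCIII diaphysis; the y-axis is the best-fit
#' line (principal direction) through the MCII, MCIII and MCIV centroids,
#' orthogonalized against x, with its sign fixed by the MCII centroid; z
#' completes the right-handed frame.
#'
#' @param landmarks Named list (mm, CT frame): `mcIII_diaphysis_proximal`,
#'   `mcIII_diaphysis_distal`, `centroid_MCII`, `centroid_MCIII`,
#'   `centroid_MCIV`.
#' @return An `anatomical_frame`.
#' @export
build_mcs <- function(landmarks) {
  need <- c("mcIII_diaphysis_proximal", "mcIII_diaphysis_distal",
            "centroid_MCII", "centroid_MCIII", "centroid_MCIV")
  .check_landmarks(landmarks, need)
  x <- unit(landmarks$mcIII_diaphysis_distal - landmarks$mcIII_diaphysis_proximal)
  C <- rbind(landmarks$centroid_MCII, landmarks$centroid_MCIII,
             landmarks$centroid_MCIV)
  Cc <- sweep(C, 2, colMeans(C))
  v <- svd(Cc)$v[, 1]                      # principal direction of the line fit
  toward_mcii <- landmarks$centroid_MCII - colMeans(C)
  if (sum(v * toward_mcii) < 0) v <- -v    # tie-break toward MCII
  y <- v - sum(v * x) * x
  if (vnorm(y) < 1e-6) {
    stop("metacarpal centroids are collinear with the diaphysis: degenerate frame")
  }
  y <- unit(y)
  anatomical_frame(colMeans(C), x, y, pracma_cross(x, y))
}

.check_landmarks <- function(landmarks, need) {
  miss <- setdiff(need, names(landmarks))
  if (length(miss)) {
    stop(sprintf("missing landmarks: %s", paste(miss, collapse = ", ")))
  }
  P <- do.call(rbind, landmarks[need])
  d <- as.matrix(stats::dist(P))
  diag(d) <- Inf
  if (min(d) < 1e-9) stop("landmark points coincide")
  invisible(TRUE)
}

#' Default synthetic landmark sets
#'
#' Landmarks for the synthetic wrist, constructed so that both anatomical
#' frames coincide with the lab frame at the neutral pose (the neutral
#' wrist position is defined as the alignment of RCS and MCS).
#'
#' @return List with `radius` and `metacarpal` landmark lists (mm).
#' @export
default_landmarks <- function() {
  list(
    radius = list(
      shaft_proximal = c(-200, 0, 0),
      shaft_distal = c(-10, 0, 0),
      articular_surface_point = c(0, 0, 0),
      sigmoid_notch_center = c(0, 20, 0)
    ),
    metacarpal = list(
      mcIII_diaphysis_proximal = c(25, 0, 0),
      mcIII_diaphysis_distal = c(70, 0, 0),
      centroid_MCII = c(45, 15, 0),
      centroid_MCIII = c(47, 0, 0),
      centroid_MCIV = c(45, -15, 0)
    )
  )
}

#' Relative rotation of the metacarpal frame about the radial frame
#'
#' `R_rel = t(R_radius_pose %*% R_RCS) %*% (R_mc_pose %*% R_MCS)`: identity
#' when the anatomical frames are aligned, and invariant to whole-arm
#' motion.
#'
#' @param rcs,mcs `anatomical_frame`s in the respective bone CT frames.
#' @param radius_pose,mc_pose `rigid_transform`s (or lists with `R`) of the
#'   radius and third metacarpal for one frame.
#' @return 3x3 rotation matrix.
#' @export
relative_rotation <- function(rcs, mcs, radius_pose, mc_pose) {
  crossprod(radius_pose$R %*% rcs$R, mc_pose$R %*% mcs$R)
}

#' Wrist angle series from reconstructed poses
#'
#' Applies [relative_rotation()] and [decompose_angles()] frame by frame.
#'
#' @param series A `pose_series` with radius and MCIII bones.
#' @param rcs,mcs Anatomical frames (default from [default_landmarks()]).
#' @param radius_bone,mc_bone Bone names in the series.
#' @return A `joint_angles` data frame.
#' @export
wrist_angles <- function(series, rcs = NULL, mcs = NULL,
                         radius_bone = "radius", mc_bone = "MCIII") {
  if (is.null(rcs)) rcs <- build_rcs(default_landmarks()$radius)
  if (is.null(mcs)) mcs <- build_mcs(default_landmarks()$metacarpal)
  n <- n_pose_frames(series)
  A <- t(vapply(seq_len(n), function(k) {
    decompose_angles(relative_rotation(
      rcs, mcs, pose_at(series, radius_bone, k), pose_at(series, mc_bone, k)))
  }, numeric(3)))
  joint_angles(A[, 1], A[, 2], A[, 3], fps = series$fps)
}

#' Remove the static-trial neutral offset from an angle series
#'
#' The initial wrist position is taken from a static trial and composed out
#' in rotation space: `R_corrected = t(R_static) %*% R_raw`, which equals
#' angle subtraction for small offsets and is exact for large ones.
#'
#' @param angles A `joint_angles` series (raw).
#' @param static_angles A `joint_angles` series from the motion's static
#'   trial; its mean rotation defines the neutral reference. Required - a
#'   missing static trial is an error, never silently assumed neutral.
#' @return Corrected `joint_angles`.
#' @export
neutral_correct <- function(angles, static_angles) {
  if (missing(static_angles) || is.null(static_angles)) {
    stop("no static trial supplied: cannot establish the neutral wrist position")
  }
  S <- angles_matrix(static_angles)
  Rs <- mean_rotation(lapply(seq_len(nrow(S)), function(k)
    pose_rotation(S[k, ])))
  A <- angles_matrix(angles)
  out <- t(vapply(seq_len(nrow(A)), function(k) {
    decompose_angles(crossprod(Rs, pose_rotation(A[k, ])))
  }, numeric(3)))
  joint_angles(out[, 1], out[, 2], out[, 3], fps = attr(angles, "fps"),
               motion = attr(angles, "motion"))
}
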