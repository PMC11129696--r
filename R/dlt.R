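# Direct linear transform camera model: 11 coefficients L1..L11 mapping a
# lab point (X, Y, Z) in mm to an image point (u, v) in px,
#   u = (L1 X + L2 Y + L3 Z + L4) / (L9 X + L10 Y + L11 Z + 1)
#   v = (L5 X + L6 Y + L7 Z + L8) / (L9 X + L10 Y + L11 Z + 1).
# Synthetic cameras are ideal pinholes (image undistortion is a hardware
# correction for image intensifiers and is not modeled); an optional
# `undistort` hook on the camera is reserved for pre-applied corrections.

#' Construct a DLT camera
#'
#' @param L Numeric vector of the 11 DLT coefficients.
#' @param image_size Image width/height in px (length 2).
#' @param undistort Optional function mapping raw (u, v) to corrected
#'   (u, v); reserved hook, identity when NULL.
#' @return A `dlt_camera` object.
#' @export
dlt_camera <- function(L, image_size = c(1024, 1024), undistort = NULL) {
  L <- as.numeric(L)
  if (length(L) != 11 || any(!is.finite(L))) {
    stop("a DLT camera needs 11 finite coefficients")
  }
  structure(list(L = L, image_size = image_size, undistort = undistort),
            class = "dlt_camera")
}

#' Project lab points through a DLT camera
#'
#' @param cam A `dlt_camera`.
#' @param X Matrix (n x 3) or length-3 vector of lab points, mm.
#' @return Matrix (n x 2) of image points, px.
#' @export
dlt_project <- function(cam, X) {
  if (is.null(dim(X))) X <- matrix(X, 1)
  L <- cam$L
  den <- X %*% L[9:11] + 1
  if (any(abs(den) < 1e-9)) {
    stop("DLT projection denominator vanishes inside the capture volume")
  }
  u <- (X %*% L[1:3] + L[4]) / den
  v <- (X %*% L[5:7] + L[8]) / den
  cbind(u = as.numeric(u), v = as.numeric(v))
}

# Build a DLT camera from an ideal pinhole: source (focal spot) at position
# `center`, viewing the lab origin, with up direction `up`.
pinhole_dlt <- function(center, target = c(0, 0, 0), up = c(0, 0, 1),
                        focal_px = 3000, principal_px = c(512, 512),
                        image_size = c(1024, 1024)) {
  zc <- unit(target - center)
  xc <- unit(pracma_cross(zc, up))
  yc <- pracma_cross(zc, xc)
  R <- rbind(xc, yc, zc)
  K <- matrix(c(focal_px, 0, 0,
                0, focal_px, 0,
                principal_px[1], principal_px[2], 1), 3, 3)
  P <- K %*% cbind(R, -R %*% center)
  if (abs(P[3, 4]) < 1e-12) stop("degenerate pinhole geometry")
  P <- P / P[3, 4]
  dlt_camera(c(P[1, ], P[2, ], P[3, 1:3]), image_size = image_size)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Default orthogonal biplanar X-ray rig
#'
#' Two ideal cameras with orthogonal beams, each at 45 degrees to the
#' forearm (lab x) axis, with the paper-rig geometry: 110 cm source-to-image
#' distance and the specimen centered in the capture volume.
#'
#' @param source_to_image_mm Source-to-image distance (default 1100 mm).
#' @param source_to_specimen_mm Source-to-specimen distance (default 760 mm).
#' @param focal_px Principal distance in px.
#' @return List of two `dlt_camera`s.
#' @export
default_biplanar_rig <- function(source_to_image_mm = 1100,
                                 source_to_specimen_mm = 760,
                                 focal_px = 3000) {
  d <- source_to_specimen_mm
  stopifnot(d > 0, source_to_image_mm > d)
  ca <- d * c(cos(pi / 4), sin(pi / 4), 0)
  cb <- d * c(cos(-pi / 4), sin(-pi / 4), 0)
  list(a = pinhole_dlt(ca, focal_px = focal_px),
       b = pinhole_dlt(cb, focal_px = focal_px))
}

#' Synthetic 64-bead calibration cube
#'
#' A 4 x 4 x 4 grid of bead positions of known spacing, mimicking the
#' calibration object used for 3D volume calibration.
#'
#' @param spacing_mm Grid spacing (default 30 mm).
#' @param center Cube center in the lab frame.
#' @return Data frame `bead_id, X, Y, Z` (mm).
#' @export
calibration_cube <- function(spacing_mm = 30, center = c(0, 0, 0)) {
  g <- (seq_len(4) - 2.5) * spacing_mm
  grid <- expand.grid(X = g, Y = g, Z = g)
  data.frame(bead_id = seq_len(nrow(grid)),
             X = grid$X + center[1], Y = grid$Y + center[2],
             Z = grid$Z + center[3])
}

#' Calibrate a DLT camera from known 3D-2D correspondences
#'
#' Least-squares solution of the 11 DLT coefficients from at least six
#' non-coplanar calibration points (the calibration cube provides 64).
#'
#' @param points_3d Matrix/data frame (n x 3) of known lab positions, mm.
#' @param points_2d Matrix (n x 2) of matched image points, px.
#' @param image_size Image size passed to the camera object.
#' @return A `dlt_camera` with attribute `rms_residual_px`.
#' @export
calibrate_dlt <- function(points_3d, points_2d, image_size = c(1024, 1024)) {
  X <- as.matrix(points_3d)[, 1:3, drop = FALSE]
  U <- as.matrix(points_2d)[, 1:2, drop = FALSE]
  n <- nrow(X)
  if (n < 6 || nrow(U) != n) {
    stop("calibration needs >= 6 matched 3D-2D points")
  }
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  if (sv[3] < 1e-6 * sv[1]) {
    stop("calibration points are coplanar: DLT system is rank-deficient")
  }
  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- X[i, ]
    A[2 * i - 1, ] <- c(x, 1, 0, 0, 0, 0, -U[i, 1] * x)
    A[2 * i, ]     <- c(0, 0, 0, 0, x, 1, -U[i, 2] * x)
    b[2 * i - 1] <- U[i, 1]
    b[2 * i] <- U[i, 2]
  }
  qrA <- qr(A)
  if (qrA$rank < 11) {
    stop("calibration points are degenerate: DLT system is rank-deficient")
  }
  L <- qr.coef(qrA, b)
  cam <- dlt_camera(L, image_size = image_size)
  res <- dlt_project(cam, X) - U
  attr(cam, "rms_residual_px") <- sqrt(mean(res^2))
  cam
}

#' Triangulate a 3D point from two camera observations
#'
#' Linear least-squares intersection of the two DLT rays, with the RMS
#' reprojection residual in px. A warning is issued for ill-conditioned
#' (near-parallel) ray geometry; inconsistent observations are reported
#' through the residual, not an error.
#'
#' @param cam_a,cam_b Calibrated `dlt_camera`s.
#' @param pt_a,pt_b Image observations `(u, v)` in each camera, px.
#' @return Numeric 3-vector (mm) with attribute `residual_px`.
#' @export
triangulate <- function(cam_a, cam_b, pt_a, pt_b) {
  A <- rbind(.tri_rows(cam_a, pt_a), .tri_rows(cam_b, pt_b))
  M <- A[, 1:3]; b <- A[, 4]
  sv <- svd(M, nu = 0, nv = 0)$d
  if (sv[3] < 1e-8 * sv[1]) {
    warning("near-parallel rays: triangulation is ill-conditioned")
  }
  x <- qr.solve(M, b)
  r <- rbind(dlt_project(cam_a, x) - rbind(pt_a),
             dlt_project(cam_b, x) - rbind(pt_b))
  attr(x, "residual_px") <- sqrt(mean(r^2))
  x
}

.tri_rows <- function(cam, pt) {
  L <- cam$L
  rbind(c(L[1] - pt[1] * L[9], L[2] - pt[1] * L[10], L[3] - pt[1] * L[11],
          pt[1] - L[4]),
        c(L[5] - pt[2] * L[9], L[6] - pt[2] * L[10], L[7] - pt[2] * L[11],
          pt[2] - L[8]))
}
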