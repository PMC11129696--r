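# Derived motion statistics: trial averaging and truncation, in-/out-of-
# plane range of motion, dart thrower's motion plane regression, and
# circumduction ellipse fitting with the 100-vector RMSE.

#' Average repeat trials sample by sample
#'
#' All trials are truncated to the length of the shortest and the
#' arithmetic mean taken at every sampling point. Works on angle series and
#' equally on force/displacement channel tables.
#'
#' @param trials List (>= 2) of data frames or matrices with identical
#'   numeric columns.
#' @return A `mean_motion_profile`: data frame of per-sample means with
#'   attributes `n_trials` and `truncated_to`.
#' @export
average_trials <- function(trials) {
  if (length(trials) < 2) {
    stop("averaging needs >= 2 trials; pass a single trial through directly")
  }
  mats <- lapply(trials, function(tr) {
    m <- as.data.frame(tr)
    m[vapply(m, is.numeric, TRUE)]
  })
  cols <- colnames(mats[[1]])
  if (!all(vapply(mats, function(m) identical(colnames(m), cols), TRUE))) {
    stop("trials must share the same channel columns")
  }
  len <- min(vapply(mats, nrow, 1L))
  acc <- Reduce(`+`, lapply(mats, function(m)
    as.matrix(m[seq_len(len), , drop = FALSE])))
  out <- as.data.frame(acc / length(mats))
  if ("frame" %in% cols) out$frame <- seq_len(len)
  structure(out, n_trials = length(trials), truncated_to = len,
            class = c("mean_motion_profile", "data.frame"))
}

.motion_peak_index <- function(profile, motion) {
  fe <- profile$fe_deg; rud <- profile$rud_deg
  switch(motion,
    flexion = , extension = which.max(abs(fe)),
    RD = , UD = which.max(abs(rud)),
    RE = , UF = which.max(sqrt(fe^2 + rud^2)),
    stop(sprintf("unknown motion '%s'", motion)))
}

#' Truncate a mean profile at the maximum joint rotation
#'
#' Cuts the profile (inclusive) at the largest rotation about the motion's
#' axis: |fe| for flexion/extension, |rud| for RD/UD, and the combined
#' magnitude sqrt(fe^2 + rud^2) for RE/UF. Circumduction is explicitly
#' exempt and passed through unchanged with a message.
#'
#' @param profile A `mean_motion_profile` (or angle data frame).
#' @param motion Motion name.
#' @return Truncated profile (never lengthened).
#' @export
truncate_to_max <- function(profile, motion) {
  if (motion == "circumduction") {
    message("circumduction profiles are not truncated")
    return(profile)
  }
  cut <- .motion_peak_index(profile, motion)
  out <- profile[seq_len(cut), , drop = FALSE]
  attr(out, "n_trials") <- attr(profile, "n_trials")
  attr(out, "truncated_to") <- cut
  out
}

#' In-plane and out-of-plane range of motion
#'
#' The in-plane value is the signed extremum on the motion's own axis
#' (extension and RD report negative values per the sign convention); the
#' out-of-plane value is the other axis read at that same sample, since
#' coupled motion is not eliminated by displacement control.
#'
#' @param profile Truncated angle profile.
#' @param motion One of flexion, extension, RD, UD.
#' @return List `in_plane_max_deg`, `out_of_plane_at_max_deg`, `peak_index`.
#' @export
extract_rom <- function(profile, motion) {
  if (!motion %in% c("flexion", "extension", "RD", "UD")) {
    stop(sprintf("unknown planar motion '%s'", motion))
  }
  idx <- .motion_peak_index(profile, motion)
  in_axis <- if (motion %in% c("flexion", "extension")) "fe_deg" else "rud_deg"
  out_axis <- if (in_axis == "fe_deg") "rud_deg" else "fe_deg"
  list(in_plane_max_deg = profile[[in_axis]][idx],
       out_of_plane_at_max_deg = profile[[out_axis]][idx],
       peak_index = idx)
}

.r_squared <- function(y, res) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(res^2) / ss_tot
}

#' Fit the dart thrower's motion plane
#'
#' Ordinary least squares of the flexion-extension angle on the radioulnar
#' deviation angle over an RE or UF profile (the plotting convention: RUD on
#' x, FE on y). The plane angle is measured from the sagittal axis (the
#' pure-FE direction), `atan(1/|slope|)`; fits with R^2 below 0.7 are
#' flagged excluded. A near-vertical scatter (no RUD variance) is handled
#' by regressing on swapped axes, which measures the same line.
#'
#' @param profile Angle profile of an RE or UF motion (>= 10 samples).
#' @return A `dtm_fit`: slope, intercept, r_squared, plane_angle_deg,
#'   fit_rmse_deg, excluded.
#' @export
fit_dtm_plane <- function(profile) {
  fe <- profile$fe_deg; rud <- profile$rud_deg
  if (length(fe) < 10) stop("DTM fit needs >= 10 samples")
  if (stats::var(fe) < 1e-12) stop("DTM fit needs nonzero FE variance")
  swapped <- FALSE
  if (stats::var(rud) < 1e-12 * stats::var(fe)) {
    # purely sagittal scatter: regress RUD on FE (equivalent line, angle 0)
    swapped <- TRUE
    fit <- stats::lm(rud ~ fe)
    slope_rud_per_fe <- stats::coef(fit)[[2]]
    slope <- if (abs(slope_rud_per_fe) < 1e-12) Inf else 1 / slope_rud_per_fe
    plane <- atan(abs(slope_rud_per_fe)) / .DEG2RAD
    r2 <- .r_squared(rud, stats::resid(fit))
    rmse <- sqrt(mean(stats::resid(fit)^2))
    intercept <- stats::coef(fit)[[1]]
  } else {
    fit <- stats::lm(fe ~ rud)
    slope <- stats::coef(fit)[[2]]
    intercept <- stats::coef(fit)[[1]]
    plane <- atan(1 / abs(slope)) / .DEG2RAD
    r2 <- .r_squared(fe, stats::resid(fit))
    rmse <- sqrt(mean(stats::resid(fit)^2))
  }
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 plane_angle_deg = plane, fit_rmse_deg = rmse,
                 excluded = r2 < 0.7, swapped_axes = swapped),
            class = "dtm_fit")
}

#' @export
print.dtm_fit <- function(x, ...) {
  cat(sprintf(
    "DTM plane: %.1f deg from sagittal (R^2 = %.3f, RMSE %.2f deg)%s\n",
    x$plane_angle_deg, x$r_squared, x$fit_rmse_deg,
    if (x$excluded) " [EXCLUDED: R^2 < 0.7]" else ""))
  invisible(x)
}

#' Join the two circumduction half-profiles
#'
#' Circumduction is commanded as two half-profiles
#' (extension-UD-flexion, then flexion-RD-extension) and rejoined during
#' analysis into one closed envelope, dropping the duplicated junction
#' sample. A junction gap beyond `tol_deg` is an error reporting its size.
#'
#' @param profile_a,profile_b Angle data frames for the two halves.
#' @param tol_deg Junction tolerance (default 2 degrees).
#' @return Concatenated closed envelope data frame.
#' @export
join_circumduction <- function(profile_a, profile_b, tol_deg = 2) {
  na <- nrow(profile_a)
  gap <- sqrt((profile_a$fe_deg[na] - profile_b$fe_deg[1])^2 +
              (profile_a$rud_deg[na] - profile_b$rud_deg[1])^2)
  if (gap > tol_deg) {
    stop(sprintf(
      "circumduction junction gap %.2f deg exceeds the %.2f deg tolerance",
      gap, tol_deg))
  }
  out <- rbind(as.data.frame(profile_a), as.data.frame(profile_b)[-1, ])
  out$frame <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

# Direct least-squares ellipse fit (Halir & Flusser's numerically stable
# partitioning of the Fitzgibbon constrained conic fit). Input x, y;
# returns conic coefficients (a, b, c, d, e, f) with 4ac - b^2 > 0.
.fit_ellipse_conic <- function(x, y) {
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  T <- -solve(S3, t(S2))
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  e <- eigen(M)
  ev <- Re(e$vectors)
  cond <- 4 * ev[1, ] * ev[3, ] - ev[2, ]^2
  i <- which(cond > 0)
  if (!length(i)) stop("no elliptical solution found for the envelope")
  a1 <- ev[, i[1]]
  c(a1, as.numeric(T %*% a1))
}

#' Fit an ellipse to a circumduction envelope
#'
#' Direct least-squares conic fit constrained to an ellipse, applied to the
#' closed (rud, fe) envelope. Reports center, semi-axes (a >= b), area
#' (pi a b), the acute orientation of the major axis from the sagittal (FE)
#' axis, and the RMSE between the magnitudes of 100 vectors on the ellipse
#' and the corresponding vectors on the envelope (envelope radius linearly
#' interpolated in polar angle about the ellipse center).
#'
#' @param envelope Data frame with `fe_deg` and `rud_deg` tracing a closed
#'   path (>= 20 samples spanning >= 350 degrees of polar angle).
#' @param n_vectors Number of comparison rays (default 100).
#' @return An `ellipse_fit`.
#' @export
fit_circumduction_ellipse <- function(envelope, n_vectors = 100) {
  x <- envelope$rud_deg; y <- envelope$fe_deg
  if (length(x) < 20) stop("ellipse fit needs >= 20 samples")
  cx0 <- mean(x); cy0 <- mean(y)
  th <- atan2(y - cy0, x - cx0)
  dth <- diff(th)
  dth <- atan2(sin(dth), cos(dth))   # wrap increments to (-pi, pi]
  if (abs(sum(dth)) / .DEG2RAD < 350) {
    stop("envelope does not span >= 350 degrees of polar angle: open path")
  }
  co <- .fit_ellipse_conic(x, y)
  if (co[1] + co[3] < 0) co <- -co   # fix the conic's arbitrary overall sign
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; Fc <- co[6]
  den <- 4 * A * C - B^2
  xc <- (B * E - 2 * C * D) / den
  yc <- (B * D - 2 * A * E) / den
  # principal axes from the quadratic form; the major axis is the
  # eigendirection of the smaller eigenvalue
  num <- 2 * (A * E^2 + C * D^2 + Fc * B^2 - B * D * E - 4 * A * C * Fc)
  s <- sqrt((A - C)^2 + B^2)
  major <- sqrt(num / (den * ((A + C) - s)))
  minor <- sqrt(num / (den * ((A + C) + s)))
  eg <- eigen(matrix(c(A, B / 2, B / 2, C), 2), symmetric = TRUE)
  v <- eg$vectors[, which.min(eg$values)]
  psi <- atan2(v[2], v[1])                # major-axis angle from the x (RUD) axis
  orientation <- acos(min(1, abs(v[2]))) / .DEG2RAD  # acute angle from FE (y) axis

  phi <- seq(0, 2 * pi, length.out = n_vectors + 1)[-(n_vectors + 1)]
  r_ell <- (major * minor) /
    sqrt((minor * cos(phi - psi))^2 + (major * sin(phi - psi))^2)
  thc <- atan2(y - yc, x - xc)
  r_env <- sqrt((x - xc)^2 + (y - yc)^2)
  o <- order(thc)
  thc <- thc[o]; r_env <- r_env[o]
  thw <- c(thc - 2 * pi, thc, thc + 2 * pi)
  rw <- rep(r_env, 3)
  r_env_i <- stats::approx(thw, rw, xout = atan2(sin(phi), cos(phi)),
                           ties = mean)$y
  rmse <- sqrt(mean((r_ell - r_env_i)^2))

  structure(list(center = c(rud = xc, fe = yc), a = major, b = minor,
                 orientation_deg = orientation,
                 area_deg2 = pi * major * minor, rmse_deg = rmse,
                 n_vectors = n_vectors),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf(
    "Circumduction ellipse: a %.1f deg, b %.1f deg, area %.0f deg^2, %.1f deg from sagittal, RMSE %.2f deg\n",
    x$a, x$b, x$area_deg2, x$orientation_deg, x$rmse_deg))
  invisible(x)
}

#' @export
plot.ellipse_fit <- function(x, envelope = NULL, ...) {
  phi <- seq(0, 2 * pi, length.out = 361)
  # major-axis direction from the acute orientation off the FE axis
  th <- pi / 2 - x$orientation_deg * .DEG2RAD
  ex <- x$center[1] + x$a * cos(phi) * cos(th) - x$b * sin(phi) * sin(th)
  ey <- x$center[2] + x$a * cos(phi) * sin(th) + x$b * sin(phi) * cos(th)
  graphics::plot(ex, ey, type = "l", xlab = "radial(-)/ulnar(+) deviation (deg)",
                 ylab = "extension(-)/flexion(+) (deg)", asp = 1, ...)
  if (!is.null(envelope)) {
    graphics::lines(envelope$rud_deg, envelope$fe_deg, col = "grey50", lty = 2)
  }
  invisible(x)
}
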