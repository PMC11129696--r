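# Marker-based reconstruction of bone poses from biplanar observations:
# triangulate every bead per frame, group beads into rigid bodies by bone,
# fit a least-squares rigid transform per bone per frame against the
# CT-frame reference centroids, then low-pass the pose series.

#' Reconstruct bone pose series from a trial bundle
#'
#' Runs the full chain on one trial: biplanar triangulation of all beads in
#' every frame, per-bone orthogonal Procrustes fits against the reference
#' centroids, and optional zero-phase Butterworth smoothing. A bone-frame
#' with fewer than three visible beads is left as an explicit gap (NA pose)
#' and flagged, never interpolated.
#'
#' @param bundle A `trial_bundle` (see [make_trial_bundle()]).
#' @param cameras List of two calibrated `dlt_camera`s.
#' @param marker_sets Named list of `marker_set`s giving CT-frame reference
#'   bead centroids.
#' @param smooth Apply [smooth_pose_series()] (default TRUE).
#' @param cutoff_hz Smoothing cut-off (default 2 Hz).
#' @return A `pose_series` with attributes `residuals` (per-bone mean fit
#'   residual, mm), `reprojection_px` (mean triangulation residual) and
#'   `gaps` (data frame of flagged bone-frames).
#' @export
reconstruct_trial <- function(bundle, cameras, marker_sets,
                              smooth = TRUE, cutoff_hz = 2) {
  tab <- bundle$marker_table
  ipa <- bundle$image_points[[1]]
  ipb <- bundle$image_points[[2]]
  n <- dim(ipa)[1]
  nm <- nrow(tab)
  pts3 <- array(NA_real_, c(n, nm, 3))
  reproj <- matrix(NA_real_, n, nm)
  for (k in seq_len(n)) {
    for (j in seq_len(nm)) {
      pa <- ipa[k, j, ]; pb <- ipb[k, j, ]
      if (any(!is.finite(c(pa, pb)))) next
      x <- triangulate(cameras[[1]], cameras[[2]], pa, pb)
      pts3[k, j, ] <- x
      reproj[k, j] <- attr(x, "residual_px")
    }
  }

  gaps <- list()
  bones <- lapply(marker_sets, function(ms) {
    b <- ms$bone_id
    jj <- which(tab$bone == b)
    ref <- ms$reference_positions
    Rarr <- array(NA_real_, c(3, 3, n))
    Tm <- matrix(NA_real_, n, 3)
    res <- numeric(n)
    for (k in seq_len(n)) {
      obs <- pts3[k, jj, , drop = TRUE]
      ok <- which(apply(obs, 1, function(r) all(is.finite(r))))
      if (length(ok) < 3) {
        gaps[[length(gaps) + 1]] <<- data.frame(bone = b, frame = k)
        res[k] <- NA_real_
        next
      }
      fit <- fit_rigid_transform(ref[ok, , drop = FALSE],
                                 obs[ok, , drop = FALSE])
      Rarr[, , k] <- fit$R
      Tm[k, ] <- fit$t
      res[k] <- sqrt(mean(fit$residuals_mm^2))
    }
    list(R = Rarr, t = Tm, residual_mm = res)
  })
  names(bones) <- vapply(marker_sets, `[[`, "", "bone_id")

  series <- pose_series(lapply(bones, function(b) b[c("R", "t")]),
                        fps = bundle$fps)
  if (smooth && length(gaps) == 0) {
    series <- smooth_pose_series(series, cutoff_hz = cutoff_hz)
  }
  attr(series, "residuals") <- vapply(bones, function(b)
    mean(b$residual_mm, na.rm = TRUE), numeric(1))
  attr(series, "reprojection_px") <- mean(reproj, na.rm = TRUE)
  attr(series, "gaps") <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(bone = character(), frame = integer())
  series
}
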