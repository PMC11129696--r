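# Low-pass smoothing of rigid-body pose series. Translations and
# hemisphere-aligned quaternion components are filtered with a zero-phase
# (forward-backward) second-order Butterworth filter and the quaternions
# renormalized, avoiding the wrap and gimbal artifacts of per-Euler-angle
# filtering.

# Zero-phase Butterworth with endpoint detrending and odd-reflection end
# padding: the linear trend between the endpoints is removed before
# filtering and restored afterwards, so constant (DC) series pass through
# exactly and edge transients act only on the detrended residual.
.butter_filtfilt <- function(x, cutoff_hz, fps, order = 2) {
  n <- length(x)
  bf <- signal::butter(order, cutoff_hz / (fps / 2), type = "low")
  trend <- x[1] + (x[n] - x[1]) * (seq_len(n) - 1) / (n - 1)
  xd <- x - trend
  pad <- min(n - 1, ceiling(3 * fps / cutoff_hz))
  head_ref <- 2 * xd[1] - xd[seq(pad + 1, 2)]
  tail_ref <- 2 * xd[n] - xd[seq(n - 1, n - pad)]
  xp <- c(head_ref, xd, tail_ref)
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)] + trend
}

#' Smooth a pose series with a zero-phase Butterworth filter
#'
#' Filters bone pose trajectories at the cut-off frequency used for
#' rigid-body transforms (2 Hz by default). Rotations are filtered in the
#' quaternion domain with hemisphere continuity enforced, then
#' renormalized; translations are filtered componentwise.
#'
#' @param series A `pose_series`.
#' @param cutoff_hz Low-pass cut-off frequency (default 2 Hz).
#' @param fps Sampling rate; defaults to the series' rate.
#' @return A smoothed `pose_series`.
#' @export
smooth_pose_series <- function(series, cutoff_hz = 2, fps = NULL) {
  stopifnot(inherits(series, "pose_series"))
  if (is.null(fps)) fps <- series$fps
  if (fps <= 2 * cutoff_hz) stop("fps must exceed twice the cut-off frequency")
  n <- n_pose_frames(series)
  min_len <- 10  # > 3x filter order with margin for stable end padding
  if (n < min_len) {
    stop(sprintf("pose series too short to filter: %d frames, need >= %d",
                 n, min_len))
  }
  bones <- lapply(series$bones, function(bn) {
    Q <- t(vapply(seq_len(n), function(k) rot_to_quat(bn$R[, , k]),
                  numeric(4)))
    for (k in seq_len(n)[-1]) {              # hemisphere alignment
      if (sum(Q[k, ] * Q[k - 1, ]) < 0) Q[k, ] <- -Q[k, ]
    }
    Qs <- apply(Q, 2, .butter_filtfilt, cutoff_hz = cutoff_hz, fps = fps)
    Ts <- apply(bn$t, 2, .butter_filtfilt, cutoff_hz = cutoff_hz, fps = fps)
    Rs <- array(NA_real_, dim(bn$R))
    for (k in seq_len(n)) Rs[, , k] <- quat_to_rot(Qs[k, ])
    list(R = Rs, t = Ts)
  })
  pose_series(bones, fps)
}
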