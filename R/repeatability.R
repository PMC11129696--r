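# Inter-trial and inter-specimen repeatability RMSEs of wrist angle, tendon
# force and actuator displacement profiles. Tables report the
# axis/tendon/actuator with the maximum error; the per-channel detail is
# kept alongside.

.channel_matrix <- function(x) {
  m <- as.data.frame(x)
  m <- m[vapply(m, is.numeric, TRUE)]
  m <- m[setdiff(colnames(m), c("frame", "time_s"))]
  as.matrix(m)
}

#' Linearly resample a profile over normalized time
#'
#' @param profile Data frame or matrix of channels.
#' @param n Number of output samples (100, or 200 for circumduction).
#' @return Matrix (n x channels).
#' @export
resample_profile <- function(profile, n) {
  M <- .channel_matrix(profile)
  s_in <- seq(0, 1, length.out = nrow(M))
  s_out <- seq(0, 1, length.out = n)
  apply(M, 2, function(col) stats::approx(s_in, col, xout = s_out)$y)
}

#' Inter-trial repeatability RMSE
#'
#' For each specimen, every trial is compared against the specimen's mean
#' profile (trials truncated to the shortest), giving one RMSE per trial
#' and channel. The specimen's reported value is the maximum over trials
#' and channels (the channel with the maximum error); across specimens the
#' mean and standard deviation of that value are reported, alongside the
#' mean per-channel RMSE.
#'
#' @param specimens List of specimens, each a list (>= 2) of trial data
#'   frames/matrices with identical channels (angles, forces or
#'   displacements).
#' @return A `repeatability_report` with `per_specimen` (worst and mean
#'   RMSE, worst channel), `mean`, `sd`, `mean_channel_rmse` and the full
#'   `detail` array.
#' @export
inter_trial_rmse <- function(specimens) {
  per <- lapply(specimens, function(trials) {
    if (length(trials) < 2) stop("inter-trial RMSE needs >= 2 trials per specimen")
    mats <- lapply(trials, .channel_matrix)
    len <- min(vapply(mats, nrow, 1L))
    mats <- lapply(mats, function(m) m[seq_len(len), , drop = FALSE])
    if (length(unique(vapply(mats, ncol, 1L))) != 1) {
      stop("trials have mismatched channels")
    }
    mean_prof <- Reduce(`+`, mats) / length(mats)
    rmse <- do.call(rbind, lapply(mats, function(m)
      sqrt(colMeans((m - mean_prof)^2))))
    colnames(rmse) <- colnames(mean_prof)
    worst <- max(rmse)
    wc <- colnames(rmse)[which(rmse == worst, arr.ind = TRUE)[1, 2]]
    list(rmse = rmse, worst = worst, worst_channel = wc,
         mean = mean(rmse))
  })
  worst <- vapply(per, `[[`, 0, "worst")
  structure(list(
    per_specimen = data.frame(
      specimen = seq_along(per),
      worst_rmse = worst,
      worst_channel = vapply(per, `[[`, "", "worst_channel"),
      mean_rmse = vapply(per, `[[`, 0, "mean")),
    mean = mean(worst), sd = stats::sd(worst),
    mean_channel_rmse = mean(vapply(per, `[[`, 0, "mean")),
    detail = lapply(per, `[[`, "rmse"),
    kind = "inter-trial"), class = "repeatability_report")
}

#' Inter-specimen repeatability RMSE
#'
#' Specimen mean profiles are linearly resampled over normalized time to
#' 100 points (200 for circumduction), an overall mean computed, and each
#' specimen's RMSE against the overall mean taken per channel. Reported is
#' the mean and standard deviation, across specimens, of the channel with
#' the maximum mean error.
#'
#' @param specimen_profiles List (>= 2) of specimen mean profiles.
#' @param motion Motion name; circumduction selects 200 interpolation
#'   points, all others 100.
#' @return A `repeatability_report`.
#' @export
inter_specimen_rmse <- function(specimen_profiles, motion = "flexion") {
  if (length(specimen_profiles) < 2) {
    stop("inter-specimen RMSE needs >= 2 specimens")
  }
  n <- if (identical(motion, "circumduction")) 200L else 100L
  mats <- lapply(specimen_profiles, resample_profile, n = n)
  overall <- Reduce(`+`, mats) / length(mats)
  rmse <- do.call(rbind, lapply(mats, function(m)
    sqrt(colMeans((m - overall)^2))))
  colnames(rmse) <- colnames(overall)
  worst_idx <- which.max(colMeans(rmse))
  vals <- rmse[, worst_idx]
  structure(list(
    per_specimen = data.frame(specimen = seq_along(vals), rmse = vals,
                              channel = colnames(rmse)[worst_idx]),
    mean = mean(vals), sd = stats::sd(vals),
    worst_channel = colnames(rmse)[worst_idx],
    interpolation_points = n,
    detail = rmse, kind = "inter-specimen"), class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("%s repeatability: %.3f +/- %.3f (worst channel%s)\n",
              x$kind, x$mean, x$sd,
              if (!is.null(x$worst_channel))
                paste0(" ", x$worst_channel) else ""))
  invisible(x)
}
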