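# Synthetic tantalum-bead marker sets and their forward motion model.
# Three 1 mm beads per bone in four bones: radius and ulna on the fixed
# proximal (forearm) segment, MCII and MCIII on the moving distal (hand)
# segment. Reference positions are expressed in the CT/reference frame,
# which for the synthetic wrist coincides with the lab frame at neutral.

BONE_NAMES <- c("radius", "ulna", "MCII", "MCIII")
PROXIMAL_BONES <- c("radius", "ulna")
DISTAL_BONES <- c("MCII", "MCIII")

#' Default bead marker sets
#'
#' Three beads per bone with 10-25 mm spacing, non-collinear, placed in
#' plausible dorsal positions relative to the model wrist: radius/ulna beads
#' proximal of the joint center, MCII/MCIII beads distal.
#'
#' @return Named list of `marker_set` objects (`bone_id`,
#'   `reference_positions` 3 x 3 matrix, mm).
#' @export
default_marker_sets <- function() {
  pos <- list(
    radius = rbind(c(-62,  -8,  2), c(-44,   4, 16), c(-26, -14,  5)),
    ulna   = rbind(c(-60,  12, -2), c(-43,  22, 12), c(-27,   6, -5)),
    MCII   = rbind(c( 30, -18,  2), c( 47,  -6, 15), c( 65, -16,  4)),
    MCIII  = rbind(c( 30,  -4,  4), c( 46,   8, 16), c( 64,  -6,  6))
  )
  sets <- lapply(BONE_NAMES, function(b) marker_set(b, pos[[b]]))
  names(sets) <- BONE_NAMES
  sets
}

#' Construct and validate a marker set
#'
#' @param bone_id One of radius, ulna, MCII, MCIII.
#' @param reference_positions Matrix (>= 3 rows) of bead centroids, mm, in
#'   the bone's CT/reference frame.
#' @return A `marker_set` object.
#' @export
marker_set <- function(bone_id, reference_positions) {
  bone_id <- match.arg(bone_id, BONE_NAMES)
  P <- as.matrix(reference_positions)
  if (nrow(P) < 3 || ncol(P) != 3) {
    stop("a marker set needs at least 3 beads with XYZ positions")
  }
  d <- as.matrix(stats::dist(P))
  if (any(d[upper.tri(d)] <= 2)) {
    stop("bead pairwise distances must exceed 2 mm")
  }
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  if (sv[2] <= 0.5) {
    stop("beads are collinear (smallest in-plane extent <= 0.5 mm)")
  }
  colnames(P) <- c("x", "y", "z")
  rownames(P) <- paste0(bone_id, "_", seq_len(nrow(P)))
  structure(list(bone_id = bone_id, reference_positions = P),
            class = "marker_set")
}

#' Forward-model bead trajectories from a motion path
#'
#' Radius and ulna beads are fixed in the lab; MCII and MCIII beads are
#' carried rigidly by the distal-segment pose about the joint center.
#'
#' @param model A `wrist_model`.
#' @param angles A `joint_angles` path.
#' @param marker_sets Named list of `marker_set`s
#'   (default [default_marker_sets()]).
#' @return Named list per bone of arrays `[n_frames, n_markers, 3]` (mm).
#' @export
markers_from_motion <- function(model, angles,
                                marker_sets = default_marker_sets()) {
  A <- angles_matrix(angles)
  n <- nrow(A)
  cc <- model$joint_center
  out <- lapply(marker_sets, function(ms) {
    P <- ms$reference_positions
    arr <- array(NA_real_, c(n, nrow(P), 3),
                 dimnames = list(NULL, rownames(P), c("x", "y", "z")))
    if (ms$bone_id %in% PROXIMAL_BONES) {
      for (k in seq_len(n)) arr[k, , ] <- P
    } else {
      Pl <- sweep(P, 2, cc)  # lever arms about the joint center
      for (k in seq_len(n)) {
        R <- pose_rotation(A[k, ])
        arr[k, , ] <- sweep(Pl %*% t(R), 2, cc, `+`)
      }
    }
    arr
  })
  names(out) <- vapply(marker_sets, `[[`, "", "bone_id")
  out
}

# Smooth low-frequency per-trial angle perturbation: a random two-harmonic
# series per axis with RMS amplitude ~ jitter_deg, pinned to zero at both
# endpoints (trials start from the same equalized position and the same
# displacement command, so trial-to-trial variation vanishes at the ends).
.trial_jitter <- function(n, jitter_deg) {
  s <- seq(0, 1, length.out = n)
  vapply(1:3, function(i) {
    c1 <- stats::rnorm(1, 0, jitter_deg * 0.7)
    c2 <- stats::rnorm(1, 0, jitter_deg * 0.35)
    c1 * sin(pi * s) + c2 * sin(2 * pi * s)
  }, numeric(n))
}

#' Generate repeat motion trials with noise and a static trial
#'
#' Emulates one motion pattern of the capture protocol: `n_trials` repeat
#' trials of the same commanded path with small smooth trial-to-trial angle
#' jitter, Gaussian bead position noise added in 3D before projection, and
#' biplanar 2D observations through the camera rig; plus one static
#' (neutral) trial. Identical seeds give bit-identical bundles.
#'
#' @param model A `wrist_model`.
#' @param angles A `joint_angles` path (the commanded ground truth).
#' @param cameras List of two `dlt_camera`s (default [default_biplanar_rig()]).
#' @param marker_sets Named list of `marker_set`s.
#' @param n_trials Number of repeat trials (protocol default 5).
#' @param noise_sigma_mm Gaussian bead position noise, mm (default 0.1).
#' @param trial_jitter_deg Amplitude of the smooth per-trial angle
#'   perturbation, degrees (default 0.5).
#' @param seed Integer seed; mandatory for reproducibility.
#' @param static_frames Length of the neutral static trial.
#' @return List with `trials` (list of `trial_bundle`s), `static` (one
#'   `trial_bundle` at neutral) and the generation parameters. Each
#'   `trial_bundle` holds `angles_truth`, per-bone noisy 3D trajectories
#'   `marker_3d`, per-camera image-point arrays `image_points`
#'   `[frame, marker, 2]`, a `marker_table` mapping columns to bones, and
#'   `fps`.
#' @export
make_trial_bundle <- function(model, angles, cameras = default_biplanar_rig(),
                              marker_sets = default_marker_sets(),
                              n_trials = 5, noise_sigma_mm = 0.1,
                              trial_jitter_deg = 0.5, seed,
                              static_frames = 25) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(n_trials >= 1, noise_sigma_mm >= 0, trial_jitter_deg >= 0)
  set.seed(as.integer(seed))
  fps <- attr(angles, "fps") %||% 50
  motion <- attr(angles, "motion")

  one_trial <- function(base_angles, jitter) {
    A <- angles_matrix(base_angles)
    if (jitter > 0) A <- A + .trial_jitter(nrow(A), jitter)
    ja <- joint_angles(A[, 1], A[, 2], A[, 3], fps = fps, motion = motion)
    m3d <- markers_from_motion(model, ja, marker_sets)
    if (noise_sigma_mm > 0) {
      m3d <- lapply(m3d, function(a) {
        a + array(stats::rnorm(length(a), 0, noise_sigma_mm), dim(a))
      })
    }
    ip <- project_markers(m3d, cameras)
    structure(list(angles_truth = ja, marker_3d = m3d,
                   image_points = ip$points, marker_table = ip$marker_table,
                   fps = fps, motion = motion,
                   noise_sigma_mm = noise_sigma_mm),
              class = "trial_bundle")
  }

  trials <- lapply(seq_len(n_trials), function(i)
    one_trial(angles, trial_jitter_deg))
  neutral <- joint_angles(numeric(static_frames), numeric(static_frames),
                          numeric(static_frames), fps = fps, motion = "static")
  static <- one_trial(neutral, 0)

  list(trials = trials, static = static, motion = motion, fps = fps,
       n_trials = n_trials, noise_sigma_mm = noise_sigma_mm,
       trial_jitter_deg = trial_jitter_deg, seed = as.integer(seed))
}

# Project per-bone 3D trajectories through each camera; markers are
# flattened into a fixed column order recorded in marker_table.
project_markers <- function(marker_3d, cameras) {
  tab <- do.call(rbind, lapply(names(marker_3d), function(b) {
    data.frame(bone = b, marker = dimnames(marker_3d[[b]])[[2]],
               stringsAsFactors = FALSE)
  }))
  n <- dim(marker_3d[[1]])[1]
  flat <- array(NA_real_, c(n, nrow(tab), 3))
  j <- 0
  for (b in names(marker_3d)) {
    nm <- dim(marker_3d[[b]])[2]
    flat[, j + seq_len(nm), ] <- marker_3d[[b]]
    j <- j + nm
  }
  pts <- lapply(cameras, function(cam) {
    out <- array(NA_real_, c(n, nrow(tab), 2))
    for (k in seq_len(n)) {
      out[k, , ] <- dlt_project(cam, flat[k, , , drop = TRUE])
    }
    out
  })
  list(points = pts, marker_table = tab)
}
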