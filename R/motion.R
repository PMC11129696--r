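# Ground-truth wrist motion paths and the actuator displacement profiles
# recorded from them. Seven motion patterns are supported: the four planar
# motions (flexion, extension, radial and ulnar deviation), the two dart
# thrower's motions (radial extension, ulnar flexion) and circumduction.

MOTION_NAMES <- c("flexion", "extension", "RD", "UD", "RE", "UF", "circumduction")

ACTUATOR_TRAVEL_MM <- 80   # allowed actuator and encoder travel
LOADCELL_CAPACITY_N <- 150

#' Construct a joint angle series
#'
#' @param prosup,fe,rud Per-frame angles in degrees (pronation +,
#'   flexion +, ulnar deviation +).
#' @param fps Sampling rate, Hz.
#' @param motion Optional motion label.
#' @return A `joint_angles` data frame (frame, prosup_deg, fe_deg, rud_deg).
#' @export
joint_angles <- function(prosup, fe, rud, fps = 50, motion = NA_character_) {
  structure(
    data.frame(frame = seq_along(fe),
               prosup_deg = prosup, fe_deg = fe, rud_deg = rud),
    fps = fps, motion = motion,
    class = c("joint_angles", "data.frame"))
}

angles_matrix <- function(angles) {
  as.matrix(angles[, c("prosup_deg", "fe_deg", "rud_deg")])
}

#' Generate a ground-truth wrist motion path
#'
#' Planar motions ramp smoothly from neutral to the commanded amplitude on
#' their axis and return to neutral, attaining the amplitude exactly at the
#' peak sample. Dart thrower's motions (RE, UF) follow the same ramp but lie
#' exactly in an oblique plane at `dtm_angle_deg` from the sagittal (pure
#' flexion-extension) axis. Circumduction traces a full ellipse in the
#' deviation-flexion plane, starting and ending at the extension
#' configuration.
#'
#' @param motion One of `r paste(MOTION_NAMES, collapse=", ")`.
#' @param amplitude_deg Peak angle for non-circumduction motions (> 0,
#'   < 90). Sign conventions are applied internally (extension and RD are
#'   negative rotations).
#' @param n_frames Number of frames (>= 10).
#' @param dtm_angle_deg Plane angle from the sagittal axis, required for RE
#'   and UF.
#' @param ellipse_axes Length-2 vector `(fe_semi_axis, rud_semi_axis)` in
#'   degrees, required for circumduction.
#' @param fps Sampling rate; 50 by default, 30 for circumduction trials.
#' @return A `joint_angles` data frame (frame, prosup_deg, fe_deg, rud_deg).
#' @examples
#' p <- generate_motion_path("flexion", 50, 101)
#' max(p$fe_deg)  # exactly 50
#' @export
generate_motion_path <- function(motion, amplitude_deg = NULL, n_frames = 100,
                                 dtm_angle_deg = NULL, ellipse_axes = NULL,
                                 fps = NULL) {
  if (!motion %in% MOTION_NAMES) {
    stop(sprintf("unknown motion '%s'; expected one of %s", motion,
                 paste(MOTION_NAMES, collapse = ", ")))
  }
  if (n_frames < 10) stop("n_frames must be at least 10")
  if (is.null(fps)) fps <- if (motion == "circumduction") 30 else 50

  s <- seq(0, 1, length.out = n_frames)
  zero <- numeric(n_frames)

  if (motion == "circumduction") {
    if (is.null(ellipse_axes) || length(ellipse_axes) != 2) {
      stop("circumduction requires ellipse_axes = c(fe_semi_axis, rud_semi_axis)")
    }
    if (any(ellipse_axes <= 0) || any(ellipse_axes >= 90)) {
      stop("ellipse semi-axes must be in (0, 90) degrees")
    }
    a <- ellipse_axes[[1]]; b <- ellipse_axes[[2]]
    # extension -> UD -> flexion -> RD -> extension
    fe <- -a * cos(2 * pi * s)
    rud <- b * sin(2 * pi * s)
    return(joint_angles(zero, fe, rud, fps = fps, motion = motion))
  }

  if (is.null(amplitude_deg) || amplitude_deg <= 0) {
    stop("amplitude_deg must be positive")
  }
  if (amplitude_deg >= 90) stop("amplitude_deg must be below 90 degrees")

  ramp <- sin(pi * s)
  ramp <- ramp / max(ramp)           # peak sample is exactly 1
  amp <- amplitude_deg * ramp

  path <- switch(motion,
    flexion   = list(fe = amp,  rud = zero),
    extension = list(fe = -amp, rud = zero),
    RD        = list(fe = zero, rud = -amp),
    UD        = list(fe = zero, rud = amp),
    RE = , UF = {
      if (is.null(dtm_angle_deg)) {
        stop(sprintf("%s requires dtm_angle_deg (plane angle from sagittal)", motion))
      }
      if (dtm_angle_deg < 0 || dtm_angle_deg >= 90) {
        stop("dtm_angle_deg must be in [0, 90)")
      }
      sgn <- if (motion == "UF") 1 else -1  # UF: flexion+ulnar; RE: extension+radial
      fe <- sgn * amp
      list(fe = fe, rud = fe * tan(dtm_angle_deg * .DEG2RAD))
    })
  joint_angles(zero, path$fe, path$rud, fps = fps, motion = motion)
}

#' Record an actuator displacement profile from a motion path
#'
#' Plays the wrist through a ground-truth angle path and records the tendon
#' shortening that each actuator would have to produce:
#' `profile_i(t) = rest_length_i - tendon_length_i(pose_t)`, so positive
#' displacement means actuator pull. Columns follow the actuator axis
#' numbering of the model's handedness. An excursion beyond the 80 mm
#' actuator travel raises an error.
#'
#' @param model A `wrist_model`.
#' @param angles A `joint_angles` path.
#' @param fps Sampling rate recorded into the profile (defaults to the
#'   path's rate).
#' @return An `actuator_profile`: numeric matrix (frames x 5 axes) with
#'   attributes `fps`, `axis_map`, `motion`.
#' @export
record_excursion_profile <- function(model, angles, fps = NULL) {
  stopifnot(inherits(model, "wrist_model"))
  A <- angles_matrix(angles)
  if (is.null(fps)) fps <- attr(angles, "fps") %||% 50
  lens <- t(apply(A, 1, function(p) tendon_lengths(model, p)))
  exc <- sweep(-lens, 2, model$rest_lengths[colnames(lens)], `+`)  # rest - length
  if (max(abs(exc)) > ACTUATOR_TRAVEL_MM) {
    stop(sprintf(
      "actuator-travel violation: excursion %.1f mm exceeds the %d mm travel",
      max(abs(exc)), ACTUATOR_TRAVEL_MM))
  }
  prof <- matrix(0, nrow(exc), 5,
                 dimnames = list(NULL, paste0("axis", 1:5)))
  for (tn in colnames(exc)) prof[, model$axis_map[[tn]]] <- exc[, tn]
  motion <- attr(angles, "motion")
  if (!identical(motion, "circumduction") && !is.na(motion %||% NA) &&
      max(abs(prof[1, ])) > 1e-9) {
    stop("planar profiles must begin at 0 mm of actuator displacement")
  }
  structure(prof, fps = fps, axis_map = model$axis_map,
            motion = motion, class = c("actuator_profile", class(prof)))
}

#' Scale an actuator displacement profile
#'
#' Element-wise scaling used to command different magnitudes of the same
#' wrist motion from one recorded template profile.
#'
#' @param profile An `actuator_profile` (or plain numeric matrix).
#' @param factor Positive scale factor.
#' @return The scaled profile with attributes preserved.
#' @export
scale_profile <- function(profile, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0) {
    stop("scale factor must be a single positive number")
  }
  out <- unclass(profile) * factor
  attributes(out) <- attributes(profile)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
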