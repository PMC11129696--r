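# Two-segment universal-joint wrist: a fixed proximal rod (forearm, carrying
# the radius and ulna beads) and a moving distal rod (hand, carrying the MCII
# and MCIII beads), connected at the joint center. Five Kevlar-like tendons
# run in straight lines from fixed proximal exit points to insertions at the
# base of the distal segment.
#
# Lab frame: right-handed, x along the forearm pointing distal, y the
# radial(-)/ulnar(+) direction, z the volar(-)/dorsal(+) direction. Flexors
# therefore insert at z < 0 and extensors at z > 0; mirroring a left-arm
# model into a right-arm model negates y and remaps the actuator axes.

TENDON_NAMES <- c("ECRL", "ECRB", "ECU", "FCR", "FCU")

# Tendon -> actuator axis, left and right arms (units mounted symmetrically
# around the central axis, so left and right are mirror images).
AXIS_MAP_LEFT  <- c(ECRL = 1L, ECRB = 2L, ECU = 3L, FCR = 5L, FCU = 4L)
AXIS_MAP_RIGHT <- c(ECRL = 3L, ECRB = 2L, ECU = 1L, FCR = 4L, FCU = 5L)

# Azimuth of each tendon around the shaft, degrees measured from +z (dorsal)
# toward +y (ulnar): direction (y, z) = (sin a, cos a). The regular pentagon
# arrangement makes the line-of-action directions sum to zero, so an equal
# preload on all five tendons is in equilibrium exactly at the neutral pose.
.TENDON_AZIMUTH_DEG <- c(ECRL = -72, ECRB = 0, ECU = 72, FCR = -144, FCU = 144)

#' Default geometry of the model wrist
#'
#' Configurable geometry of the two-rod universal-joint wrist. None of the
#' physical rig's dimensions are published, so these defaults describe a
#' plausible bench model and every value can be overridden through the
#' config list.
#'
#' @return Named list of geometry defaults (mm, N/mm).
#' @export
default_wrist_geometry <- function() {
  list(
    proximal_length = 250,  # mm, joint center to tendon exit ring
    distal_length   = 80,   # mm, joint center to distal rod tip
    joint_center    = c(0, 0, 0),
    origin_radius   = 15,   # mm, tendon exit ring radius at the proximal end
    insertion_radius = 15,  # mm, insertion ring radius on the distal segment
    insertion_offset = 0,   # mm, insertions at the base of the distal segment
    stiffness       = 50,   # N/mm, suture + spring series stiffness
    passive_stiffness = 0.01,  # N*mm/deg^2, joint regularizer
    tendon_azimuth_deg = .TENDON_AZIMUTH_DEG  # placement around the shaft
  )
}

#' Build the five-tendon model wrist
#'
#' Constructs the two-segment universal-joint wrist with tendons mimicking
#' the insertions of the five wrist flexors and extensors (ECRL, ECRB, ECU,
#' FCR, FCU). A right-arm model is the mirror image of the left-arm model:
#' radial/ulnar (y) coordinates are negated and the tendon-to-actuator axis
#' map is swapped accordingly.
#'
#' @param handedness "left" or "right".
#' @param config Optional named list overriding [default_wrist_geometry()]
#'   entries.
#' @return An object of class `wrist_model`: segment lengths, joint center,
#'   per-tendon origin/insertion points, stiffnesses, rest lengths (tendon
#'   length at the neutral pose), handedness and actuator axis map.
#' @examples
#' w <- build_default_wrist("left")
#' w$axis_map[["FCU"]]  # actuator 4 on a left arm
#' @export
build_default_wrist <- function(handedness = c("left", "right"), config = list()) {
  handedness <- match.arg(handedness)
  geom <- utils::modifyList(default_wrist_geometry(), config)
  if (geom$proximal_length <= 0 || geom$distal_length <= 0 ||
      geom$origin_radius <= 0 || geom$insertion_radius <= 0) {
    stop("non-physical wrist geometry: lengths and radii must be positive")
  }

  az <- geom$tendon_azimuth_deg[TENDON_NAMES] * .DEG2RAD
  dir_yz <- cbind(sin(az), cos(az))  # (y, z) unit direction per tendon
  origins <- cbind(-geom$proximal_length,
                   geom$origin_radius * dir_yz[, 1],
                   geom$origin_radius * dir_yz[, 2])
  insertions <- cbind(geom$insertion_offset,
                      geom$insertion_radius * dir_yz[, 1],
                      geom$insertion_radius * dir_yz[, 2])
  rownames(origins) <- rownames(insertions) <- TENDON_NAMES
  colnames(origins) <- colnames(insertions) <- c("x", "y", "z")

  axis_map <- AXIS_MAP_LEFT
  if (handedness == "right") {
    origins[, "y"] <- -origins[, "y"]
    insertions[, "y"] <- -insertions[, "y"]
    axis_map <- AXIS_MAP_RIGHT
  }

  stiffness <- rep(geom$stiffness, length.out = 5)
  names(stiffness) <- TENDON_NAMES

  model <- structure(list(
    proximal_length = geom$proximal_length,
    distal_length = geom$distal_length,
    joint_center = as.numeric(geom$joint_center),
    origins = origins,
    insertions = insertions,
    stiffness = stiffness,
    passive_stiffness = geom$passive_stiffness,
    handedness = handedness,
    axis_map = axis_map
  ), class = "wrist_model")

  model$rest_lengths <- tendon_lengths(model, c(0, 0, 0))
  validate_wrist_model(model)
  model
}

validate_wrist_model <- function(model) {
  stopifnot(inherits(model, "wrist_model"))
  if (!identical(sort(rownames(model$insertions)), sort(TENDON_NAMES))) {
    stop("wrist model must have the five uniquely named tendons")
  }
  d <- as.matrix(stats::dist(model$insertions))
  if (any(d[upper.tri(d)] < 1e-6)) stop("tendon insertion points coincide")
  flex <- c("FCR", "FCU"); ext <- c("ECRL", "ECRB", "ECU")
  if (!all(model$insertions[flex, "z"] < 0)) {
    stop("flexor insertions must lie on the volar side of the distal segment")
  }
  if (!all(model$insertions[ext, "z"] > 0)) {
    stop("extensor insertions must lie on the dorsal side of the distal segment")
  }
  expected <- if (model$handedness == "left") AXIS_MAP_LEFT else AXIS_MAP_RIGHT
  if (!identical(model$axis_map[TENDON_NAMES], expected[TENDON_NAMES])) {
    stop("axis map does not match the simulator wiring for this handedness")
  }
  invisible(model)
}

#' @export
print.wrist_model <- function(x, ...) {
  cat(sprintf("Model wrist (%s arm): proximal %g mm, distal %g mm rods\n",
              x$handedness, x$proximal_length, x$distal_length))
  cat(sprintf("Tendons (stiffness %g N/mm):\n", x$stiffness[[1]]))
  for (tn in TENDON_NAMES) {
    cat(sprintf("  %-4s axis %d  insertion (%6.1f,%6.1f,%6.1f) mm  rest %.1f mm\n",
                tn, x$axis_map[[tn]], x$insertions[tn, 1], x$insertions[tn, 2],
                x$insertions[tn, 3], x$rest_lengths[[tn]]))
  }
  invisible(x)
}

pose_rotation <- function(pose) {
  cardan_rotation(pose[[1]], pose[[2]], pose[[3]])
}

check_pose <- function(pose) {
  pose <- as.numeric(pose)
  if (length(pose) != 3 || any(!is.finite(pose))) {
    stop("pose must be three finite angles (prosup, fe, rud) in degrees")
  }
  if (any(abs(pose) >= 90)) {
    stop("pose outside the gimbal-safe range (|angle| < 90 deg)")
  }
  pose
}

#' Straight-line tendon lengths at a wrist pose
#'
#' Each tendon is a straight line from its fixed proximal exit point to its
#' insertion on the distal segment, the insertion being carried by the
#' distal-segment rotation about the joint center.
#'
#' @param model A `wrist_model`.
#' @param pose Numeric triple `(prosup_deg, fe_deg, rud_deg)`.
#' @return Named numeric vector of tendon lengths (mm).
#' @export
tendon_lengths <- function(model, pose) {
  pose <- check_pose(pose)
  .tendon_lengths_raw(model, pose)
}

# unchecked variant used inside the equilibrium solver, whose line searches
# may probe beyond the gimbal-safe box before being clamped back
.tendon_lengths_raw <- function(model, pose) {
  R <- pose_rotation(pose)
  world <- model$insertions %*% t(R)
  world <- sweep(world, 2, model$joint_center, `+`)
  d <- world - model$origins
  len <- sqrt(rowSums(d^2))
  names(len) <- rownames(model$insertions)
  len
}

# Analytic d(length)/d(angle_deg): 5 x 3 matrix (tendons x (prosup, fe, rud)).
tendon_length_gradient <- function(model, pose) {
  pose <- as.numeric(pose)
  ps <- pose[1]; fe <- pose[2]; rud <- pose[3]
  Ry <- rot_y(fe); Rz <- rot_z(rud); Rx <- rot_x(ps)
  R <- Ry %*% Rz %*% Rx
  # derivative generators (degrees)
  dRy <- .drot_y(fe) %*% Rz %*% Rx
  dRz <- Ry %*% .drot_z(rud) %*% Rx
  dRx <- Ry %*% Rz %*% .drot_x(ps)
  world <- model$insertions %*% t(R)
  world <- sweep(world, 2, model$joint_center, `+`)
  diff <- world - model$origins
  len <- sqrt(rowSums(diff^2))
  u <- diff / len
  g <- cbind(
    rowSums(u * (model$insertions %*% t(dRx))),
    rowSums(u * (model$insertions %*% t(dRy))),
    rowSums(u * (model$insertions %*% t(dRz)))
  )
  rownames(g) <- rownames(model$insertions)
  colnames(g) <- c("prosup", "fe", "rud")
  list(length = len, grad = g)
}

.drot_x <- function(deg) {
  a <- deg * .DEG2RAD
  .DEG2RAD * matrix(c(0, 0, 0,
                      0, -sin(a), cos(a),
                      0, -cos(a), -sin(a)), 3, 3)
}
.drot_y <- function(deg) {
  a <- deg * .DEG2RAD
  .DEG2RAD * matrix(c(-sin(a), 0, -cos(a),
                      0, 0, 0,
                      cos(a), 0, -sin(a)), 3, 3)
}
.drot_z <- function(deg) {
  a <- deg * .DEG2RAD
  .DEG2RAD * matrix(c(-sin(a), cos(a), 0,
                      -cos(a), -sin(a), 0,
                      0, 0, 0), 3, 3)
}
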