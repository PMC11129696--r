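# Digital twin of the simulator's three control features: force
# equalization before a motion, closed-loop actuator displacement tracking
# during it, and physiological force-cap enforcement. The rig is modeled
# quasi-statically: at each frame the wrist settles into the minimum of the
# total elastic energy of the five unilateral tendon springs plus a small
# passive joint stiffness; motions are slow and no inertia is modeled.
#
# Actuators have 0-80 mm of absolute travel; the neutral-length position
# sits at mid-travel (40 mm) so that both pulls and releases are possible.

.TRAVEL_ZERO_MM <- 40  # absolute actuator position with the tendon at rest length

#' Physiological tendon force caps
#'
#' Maximum tendon forces, either the rig's defaults or estimated from
#' physiological cross-sectional areas at a specific tension of 32 N/cm^2.
#'
#' @param pcsa_cm2 Optional named vector of PCSAs (cm^2); when supplied the
#'   caps are `pcsa * specific_tension`.
#' @param specific_tension_n_cm2 Specific muscle tension (default 32).
#' @return Named numeric vector of per-tendon caps (N).
#' @export
force_caps <- function(pcsa_cm2 = NULL, specific_tension_n_cm2 = 32) {
  if (!is.null(pcsa_cm2)) {
    caps <- pcsa_cm2[TENDON_NAMES] * specific_tension_n_cm2
  } else {
    caps <- c(ECRL = 80, ECRB = 86, ECU = 74, FCR = 125, FCU = 211)
  }
  if (any(caps <= 0) || any(is.na(caps))) stop("force caps must be positive")
  caps
}

# Tendon forces for a pose and actuator pull p (mm, per tendon): unilateral
# springs, F = k * max(0, stretch), stretch = length + p - rest.
.tendon_forces <- function(model, pose, pull) {
  s <- tendon_lengths(model, pose) + pull - model$rest_lengths
  pmax(0, model$stiffness * s)
}

#' Solve the quasi-static equilibrium pose for actuator pulls
#'
#' Minimizes the total elastic energy
#' `sum(0.5 k_i s_i^2) + 0.5 k_p |pose|^2` with unilateral tendon stretches
#' `s_i = max(0, length_i(pose) + pull_i - rest_i)`, by BFGS with an
#' analytic gradient followed by Newton polishing to a gradient norm below
#' `grad_tol`.
#'
#' @param model A `wrist_model`.
#' @param pull Named or axis-ordered tendon pulls (mm, positive shortens).
#' @param init Starting pose (warm start), degrees.
#' @param grad_tol Gradient norm tolerance (N*mm/deg, default 1e-8).
#' @param max_iter Newton iteration cap.
#' @return List `pose` (prosup, fe, rud deg), `forces` (N, per tendon),
#'   `energy` (N*mm), `grad_norm`.
#' @export
solve_equilibrium_pose <- function(model, pull, init = c(0, 0, 0),
                                   grad_tol = 1e-8, max_iter = 60) {
  pull <- .as_tendon_vector(pull, model)
  kp <- model$passive_stiffness
  k <- model$stiffness

  energy <- function(th) {
    s <- pmax(0, .tendon_lengths_raw(model, th) + pull - model$rest_lengths)
    sum(0.5 * k * s^2) + 0.5 * kp * sum(th^2)
  }
  gradient <- function(th) {
    tg <- tendon_length_gradient(model, th)
    s <- pmax(0, tg$length + pull - model$rest_lengths)
    as.numeric(crossprod(tg$grad, k * s)) + kp * th
  }

  newton <- function(th, iters) {
    h <- 1e-4
    for (it in seq_len(iters)) {
      g <- gradient(th)
      if (max(abs(g)) < grad_tol) break
      H <- matrix(0, 3, 3)
      for (j in 1:3) {
        e <- numeric(3); e[j] <- h
        H[, j] <- (gradient(th + e) - gradient(th - e)) / (2 * h)
      }
      step <- tryCatch(solve(H + diag(1e-10, 3), g), error = function(e) g)
      alpha <- 1
      e0 <- energy(th)
      repeat {
        cand <- th - alpha * step
        if (energy(cand) <= e0 + 1e-12 || alpha < 1e-6) break
        alpha <- alpha / 2
      }
      th <- pmin(pmax(th - alpha * step, -89), 89)
    }
    th
  }

  th <- newton(init, max_iter)   # warm starts converge in a few steps
  if (max(abs(gradient(th))) >= grad_tol) {
    fit <- stats::optim(th, energy, gradient, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-15))
    th <- newton(fit$par, max_iter)
  }
  g <- gradient(th)
  if (max(abs(g)) >= grad_tol * 100) {
    stop(sprintf(
      "equilibrium solver failed to converge: gradient norm %.3g at pose (%.3f, %.3f, %.3f)",
      max(abs(g)), th[1], th[2], th[3]))
  }
  list(pose = stats::setNames(th, c("prosup_deg", "fe_deg", "rud_deg")),
       forces = .tendon_forces(model, th, pull),
       energy = energy(th), grad_norm = max(abs(g)))
}

.as_tendon_vector <- function(x, model) {
  if (!is.null(names(x)) && all(TENDON_NAMES %in% names(x))) {
    return(x[TENDON_NAMES])
  }
  if (length(x) == 5) {
    return(stats::setNames(as.numeric(x), TENDON_NAMES))
  }
  stop("expected five per-tendon values")
}

#' Equalize tendon forces to a target load
#'
#' Feedback loop used before each motion: actuators are repositioned until
#' every tendon force is within `tol_n` of the target (2 N in the
#' protocol), with the wrist free to settle between cycles. On convergence
#' the encoder zeros are set to the current actuator positions.
#'
#' @param model A `wrist_model`.
#' @param initial_forces Optional per-tendon starting forces (N) from which
#'   starting pulls are derived; defaults to slack (0 N).
#' @param target_n Target force (default 2 N).
#' @param tol_n Convergence tolerance (default 0.01 N).
#' @param max_iter Maximum loop cycles.
#' @return An `actuator_state`: list `position` (mm per tendon),
#'   `encoder_zero`, `forces` (N), `pose`, `iterations`.
#' @export
equalize_forces <- function(model, initial_forces = NULL, target_n = 2,
                            tol_n = 0.01, max_iter = 100) {
  stopifnot(target_n >= 0, tol_n > 0)
  k <- model$stiffness
  position <- .TRAVEL_ZERO_MM + if (is.null(initial_forces)) {
    stats::setNames(numeric(5), TENDON_NAMES)
  } else {
    .as_tendon_vector(initial_forces, model) / k
  }
  pose <- c(0, 0, 0)
  for (it in seq_len(max_iter)) {
    eq <- solve_equilibrium_pose(model, position - .TRAVEL_ZERO_MM, init = pose)
    pose <- as.numeric(eq$pose)
    err <- eq$forces - target_n
    if (max(abs(err)) <= tol_n) {
      .check_actuator_state(position, eq$forces)
      return(structure(list(position = position, encoder_zero = position,
                            forces = eq$forces, pose = eq$pose,
                            target_n = target_n, iterations = it),
                       class = "actuator_state"))
    }
    position <- position - err / k
  }
  stop(sprintf(
    "force equalization did not converge in %d cycles; residual errors: %s N",
    max_iter, paste(sprintf("%s %.3f", TENDON_NAMES, err), collapse = ", ")))
}

.check_actuator_state <- function(position, forces) {
  if (any(position < -1e-9) || any(position > ACTUATOR_TRAVEL_MM)) {
    stop("actuator position outside the 0-80 mm travel")
  }
  if (any(forces < 0)) stop("tendon force cannot be negative")
  if (any(forces > LOADCELL_CAPACITY_N)) {
    stop("tendon force exceeds the 150 N load-cell capacity")
  }
  invisible(TRUE)
}

#' Enforce physiological force caps
#'
#' @param forces Numeric matrix (frames x 5 tendons) or vector of tendon
#'   forces (N).
#' @param caps Named per-tendon caps (default [force_caps()]).
#' @param mode `"flag"` reports violations and leaves forces unchanged;
#'   `"clamp"` additionally limits forces to the cap. Caps are inclusive:
#'   a force exactly at its cap is not a violation.
#' @return List `forces`, `violations` (data frame tendon, frame, force,
#'   cap, excess_n).
#' @export
enforce_force_cap <- function(forces, caps = force_caps(),
                              mode = c("flag", "clamp")) {
  mode <- match.arg(mode)
  F <- if (is.null(dim(forces))) matrix(forces, 1,
                                        dimnames = list(NULL, names(forces)))
       else as.matrix(forces)
  if (is.null(colnames(F))) colnames(F) <- TENDON_NAMES
  caps <- caps[colnames(F)]
  over <- which(sweep(F, 2, caps, `>`), arr.ind = TRUE)
  violations <- data.frame(
    tendon = colnames(F)[over[, 2]],
    frame = as.integer(over[, 1]),
    force_n = F[over],
    cap_n = as.numeric(caps[colnames(F)[over[, 2]]]),
    stringsAsFactors = FALSE)
  violations$excess_n <- violations$force_n - violations$cap_n
  if (mode == "clamp" && nrow(violations)) {
    F <- pmin(F, matrix(caps, nrow(F), ncol(F), byrow = TRUE))
  }
  if (is.null(dim(forces))) F <- F[1, ]
  list(forces = F, violations = violations)
}

#' Track an actuator displacement profile
#'
#' Plays a recorded (possibly scaled) displacement profile through the
#' quasi-static wrist: each frame's pulls are the encoder zeros plus the
#' profile row, the equilibrium pose is solved with the previous frame as
#' warm start, and tendon forces are logged at the profile's sampling rate
#' with force-cap checking.
#'
#' @param model A `wrist_model`.
#' @param profile An `actuator_profile` (frames x 5 axes, mm).
#' @param state An `actuator_state` from [equalize_forces()]; equalization
#'   must be performed first.
#' @param fps Sampling rate (default from the profile, else 50).
#' @param caps Per-tendon force caps.
#' @param cap_mode `"flag"` or `"clamp"` (see [enforce_force_cap()]).
#' @return A `motion_log`: list with `log` (data frame: time_s, F_* N,
#'   d_axis* mm), `angles` (`joint_angles`), `violations`.
#' @export
track_profile <- function(model, profile, state, fps = NULL,
                          caps = force_caps(), cap_mode = "flag") {
  stopifnot(inherits(state, "actuator_state"))
  prof <- unclass(profile)
  if (is.null(fps)) fps <- attr(profile, "fps") %||% 50
  axis_map <- attr(profile, "axis_map") %||% model$axis_map
  n <- nrow(prof)
  tendon_prof <- prof[, axis_map[TENDON_NAMES], drop = FALSE]
  colnames(tendon_prof) <- TENDON_NAMES

  F <- matrix(NA_real_, n, 5, dimnames = list(NULL, TENDON_NAMES))
  A <- matrix(NA_real_, n, 3)
  pose <- as.numeric(state$pose)
  for (k in seq_len(n)) {
    position <- state$encoder_zero + tendon_prof[k, ]
    if (any(position < -1e-9) || any(position > ACTUATOR_TRAVEL_MM)) {
      stop(sprintf("actuator travel violation at frame %d", k))
    }
    eq <- solve_equilibrium_pose(model, position - .TRAVEL_ZERO_MM, init = pose)
    pose <- as.numeric(eq$pose)
    F[k, ] <- eq$forces
    A[k, ] <- pose
  }
  capped <- enforce_force_cap(F, caps, mode = cap_mode)
  log <- data.frame(time_s = (seq_len(n) - 1) / fps)
  for (tn in TENDON_NAMES) log[[paste0("F_", tn)]] <- capped$forces[, tn]
  for (ax in 1:5) log[[paste0("d_axis", ax)]] <- prof[, ax]
  structure(list(log = log,
                 angles = joint_angles(A[, 1], A[, 2], A[, 3], fps = fps,
                                       motion = attr(profile, "motion")),
                 violations = capped$violations, fps = fps),
            class = "motion_log")
}

#' @export
print.motion_log <- function(x, ...) {
  cat(sprintf(
    "Motion log: %d frames at %g Hz; peak angles (deg) prosup %.1f, fe %.1f, rud %.1f; %d cap violation(s)\n",
    nrow(x$log), x$fps,
    max(abs(x$angles$prosup_deg)), max(abs(x$angles$fe_deg)),
    max(abs(x$angles$rud_deg)), nrow(x$violations)))
  invisible(x)
}
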