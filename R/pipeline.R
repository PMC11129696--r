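# End-to-end pipeline: simulate -> reconstruct -> analyze. Each stage reads
# and writes the interchange files, so the stages can be run separately (or
# from the command line) and every run is reproducible from its config and
# seed alone.

.motion_fps <- function(config, motion) {
  if (identical(motion, "circumduction")) config$fps_circumduction else config$fps
}

.motion_path <- function(config, motion) {
  spec <- config$motions[[motion]]
  generate_motion_path(
    motion,
    amplitude_deg = spec$amplitude_deg,
    n_frames = spec$n_frames %||% 101,
    dtm_angle_deg = spec$dtm_angle_deg,
    ellipse_axes = spec$ellipse_axes,
    fps = .motion_fps(config, motion))
}

# Circumduction is commanded as two half-profiles (extension-UD-flexion,
# flexion-RD-extension) recorded as separate trials and rejoined in
# analysis; split the generated ellipse at the flexion apex.
.split_circumduction <- function(angles) {
  n <- nrow(angles)
  mid <- which.max(angles$fe_deg)
  fps <- attr(angles, "fps")
  a <- joint_angles(angles$prosup_deg[1:mid], angles$fe_deg[1:mid],
                    angles$rud_deg[1:mid], fps = fps, motion = "circumduction")
  b <- joint_angles(angles$prosup_deg[mid:n], angles$fe_deg[mid:n],
                    angles$rud_deg[mid:n], fps = fps, motion = "circumduction")
  list(a = a, b = b)
}

write_reference_markers <- function(marker_sets, path) {
  rows <- do.call(rbind, lapply(marker_sets, function(ms) {
    data.frame(bone = ms$bone_id, marker = rownames(ms$reference_positions),
               X = ms$reference_positions[, 1],
               Y = ms$reference_positions[, 2],
               Z = ms$reference_positions[, 3])
  }))
  .write_csv_precise(rows, path)
}

read_reference_markers <- function(path) {
  df <- .read_csv_checked(path, c("bone", "marker", "X", "Y", "Z"))
  sets <- lapply(split(df, df$bone), function(d) {
    marker_set(d$bone[1], as.matrix(d[, c("X", "Y", "Z")]))
  })
  sets[intersect(BONE_NAMES, names(sets))]
}

.sim_units <- function(config) {
  # expand circumduction into its two recorded half-trials
  units <- list()
  for (m in names(config$motions)) {
    if (m == "circumduction") {
      halves <- .split_circumduction(.motion_path(config, m))
      units[["circumduction_a"]] <- halves$a
      units[["circumduction_b"]] <- halves$b
    } else {
      units[[m]] <- .motion_path(config, m)
    }
  }
  units
}

#' Simulate a full capture session
#'
#' Generates, for every motion in the protocol, the commanded ground-truth
#' path, the recorded actuator displacement profile, `n_trials` noisy
#' repeat trials (3D bead tables and biplanar 2D observations), a static
#' neutral trial, and the tracked tendon-force/displacement logs; plus the
#' calibration files, reference bead centroids, landmarks, config copy and
#' a reproducibility manifest.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
simulate_experiment <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- build_default_wrist(config$handedness, config$wrist)
  cameras <- do.call(default_biplanar_rig, config$cameras)
  marker_sets <- default_marker_sets()

  write_run_config(config, file.path(out_dir, "config.yaml"))
  cube <- calibration_cube()
  write_calibration_csv(cube, cameras, out_dir)
  write_reference_markers(marker_sets, file.path(out_dir, "reference_markers.csv"))
  write_landmarks_json(default_landmarks(), file.path(out_dir, "landmarks.json"))

  state <- equalize_forces(model, target_n = config$equalize_target_n,
                           tol_n = config$equalize_tol_n)
  units <- .sim_units(config)
  for (i in seq_along(units)) {
    unit <- names(units)[i]
    path <- units[[i]]
    mdir <- file.path(out_dir, unit)
    dir.create(mdir, showWarnings = FALSE)
    write_angles_csv(path, file.path(mdir, "commanded_angles.csv"))
    profile <- record_excursion_profile(model, path)
    write_profile_csv(profile, file.path(mdir, "profile.csv"))

    bundle <- make_trial_bundle(
      model, path, cameras, marker_sets,
      n_trials = config$n_trials,
      noise_sigma_mm = config$noise_sigma_mm,
      trial_jitter_deg = config$trial_jitter_deg,
      seed = config$seed + 101L * i)
    for (k in seq_along(bundle$trials)) {
      tr <- bundle$trials[[k]]
      write_marker_csv(tr$marker_3d,
                       file.path(mdir, sprintf("trial%d_markers3d.csv", k)))
      for (ci in 1:2) {
        write_points2d_csv(tr$image_points[[ci]], tr$marker_table,
                           file.path(mdir, sprintf("trial%d_points_cam%d.csv",
                                                   k, ci)))
      }
      write_angles_csv(tr$angles_truth,
                       file.path(mdir, sprintf("trial%d_truth_angles.csv", k)))
      tprof <- record_excursion_profile(model, tr$angles_truth)
      log <- track_profile(model, tprof, state,
                           fps = .motion_fps(config, sub("_[ab]$", "", unit)))
      write_motion_log_csv(log, file.path(mdir, sprintf("trial%d_log.csv", k)))
    }
    st <- bundle$static
    write_marker_csv(st$marker_3d, file.path(mdir, "static_markers3d.csv"))
    for (ci in 1:2) {
      write_points2d_csv(st$image_points[[ci]], st$marker_table,
                         file.path(mdir, sprintf("static_points_cam%d.csv", ci)))
    }
  }
  invisible(write_manifest(config, out_dir))
}

#' Reconstruct bone poses for a simulated session
#'
#' Calibrates both cameras from the session's calibration files, then
#' triangulates, rigid-body fits and smooths every trial (and static
#' trial), writing one pose CSV per trial into `<dir>/recon`.
#'
#' @param dir Session directory written by [simulate_experiment()].
#' @param config Optional `run_config`; defaults to the session's
#'   `config.yaml`.
#' @param smooth Apply the 2 Hz pose filter (default TRUE).
#' @return Data frame summarizing per-trial mean fit residuals, invisibly.
#' @export
reconstruct_experiment <- function(dir, config = NULL, smooth = TRUE) {
  if (is.null(config)) config <- read_run_config(file.path(dir, "config.yaml"))
  cameras <- read_calibration_csv(dir)
  marker_sets <- read_reference_markers(file.path(dir, "reference_markers.csv"))
  units <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  units <- setdiff(units, c("recon", "report"))
  summary <- list()
  for (unit in units) {
    mdir <- file.path(dir, unit)
    rdir <- file.path(dir, "recon", unit)
    dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
    fps <- .motion_fps(config, sub("_[ab]$", "", unit))
    trials <- sort(list.files(mdir, pattern = "^trial[0-9]+_points_cam1\\.csv$"))
    for (f in c(trials, "static_points_cam1.csv")) {
      base <- sub("_points_cam1\\.csv$", "", f)
      p1 <- read_points2d_csv(file.path(mdir, f))
      p2 <- read_points2d_csv(file.path(mdir, sub("cam1", "cam2", f)))
      bundle <- structure(list(
        image_points = list(p1$points, p2$points),
        marker_table = p1$marker_table, fps = fps), class = "trial_bundle")
      series <- reconstruct_trial(bundle, cameras, marker_sets,
                                  smooth = smooth,
                                  cutoff_hz = config$filter_cutoff_hz)
      write_pose_csv(series, file.path(rdir, paste0(base, "_pose.csv")))
      summary[[length(summary) + 1]] <- data.frame(
        unit = unit, trial = base,
        mean_residual_mm = mean(attr(series, "residuals")),
        reprojection_px = attr(series, "reprojection_px"))
    }
  }
  invisible(do.call(rbind, summary))
}

.read_trial_angles <- function(rdir, base, fps, rcs, mcs) {
  series <- read_pose_csv(file.path(rdir, paste0(base, "_pose.csv")), fps = fps)
  wrist_angles(series, rcs, mcs)
}

#' Analyze a reconstructed session
#'
#' Computes wrist angles for every trial, removes each motion's
#' static-trial neutral offset, averages and truncates the trials, and
#' derives the per-motion metrics: in-/out-of-plane ROM for the planar
#' motions, the DTM plane fit for RE/UF, the joined-envelope ellipse fit
#' for circumduction, and inter-trial repeatability of angles, tendon
#' forces and actuator displacements. Writes `report/report.json` and CSV
#' tables.
#'
#' @param dir Session directory (after [reconstruct_experiment()]).
#' @param config Optional `run_config`; defaults to the session copy.
#' @return A `motion_report` list, invisibly.
#' @export
analyze_experiment <- function(dir, config = NULL) {
  if (is.null(config)) config <- read_run_config(file.path(dir, "config.yaml"))
  landmarks <- read_landmarks_json(file.path(dir, "landmarks.json"))
  rcs <- build_rcs(landmarks$radius)
  mcs <- build_mcs(landmarks$metacarpal)
  repdir <- file.path(dir, "report")
  dir.create(repdir, showWarnings = FALSE)

  units <- list.dirs(file.path(dir, "recon"), recursive = FALSE,
                     full.names = FALSE)
  motions <- unique(sub("_[ab]$", "", units))
  report <- list()
  rom_rows <- list()
  rep_rows <- list()

  angles_for_unit <- function(unit) {
    rdir <- file.path(dir, "recon", unit)
    fps <- .motion_fps(config, sub("_[ab]$", "", unit))
    static_path <- file.path(rdir, "static_pose.csv")
    if (!file.exists(static_path)) {
      stop(sprintf("missing static trial for %s: no neutral position available",
                   unit))
    }
    static_angles <- .read_trial_angles(rdir, "static", fps, rcs, mcs)
    bases <- sub("_pose\\.csv$", "",
                 sort(list.files(rdir, pattern = "^trial[0-9]+_pose\\.csv$")))
    lapply(bases, function(b) {
      neutral_correct(.read_trial_angles(rdir, b, fps, rcs, mcs), static_angles)
    })
  }

  for (motion in motions) {
    if (motion == "circumduction") {
      ta <- angles_for_unit("circumduction_a")
      tb <- angles_for_unit("circumduction_b")
      trials <- Map(join_circumduction, ta, tb)
      mean_prof <- average_trials(trials)
      ell <- fit_circumduction_ellipse(mean_prof, n_vectors = 100)
      report[[motion]] <- list(ellipse = unclass(ell))
      it <- inter_trial_rmse(list(trials))
      rep_rows[[motion]] <- data.frame(
        motion = motion, angle_rmse = it$mean, worst_channel =
          it$per_specimen$worst_channel[1])
      next
    }
    trials <- angles_for_unit(motion)
    mean_prof <- truncate_to_max(average_trials(trials), motion)
    entry <- list()
    if (motion %in% c("flexion", "extension", "RD", "UD")) {
      entry$rom <- extract_rom(mean_prof, motion)
      rom_rows[[motion]] <- data.frame(
        motion = motion,
        in_plane_deg = entry$rom$in_plane_max_deg,
        out_of_plane_deg = entry$rom$out_of_plane_at_max_deg)
    } else {
      entry$dtm <- unclass(fit_dtm_plane(mean_prof))
    }
    it <- inter_trial_rmse(list(trials))
    entry$inter_trial_angle_rmse <- it$mean
    rep_rows[[motion]] <- data.frame(
      motion = motion, angle_rmse = it$mean,
      worst_channel = it$per_specimen$worst_channel[1])
    report[[motion]] <- entry
  }

  # tendon force / actuator displacement repeatability from the motion logs
  log_rep <- list()
  for (unit in setdiff(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                       c("recon", "report"))) {
    logs <- lapply(sort(list.files(file.path(dir, unit),
                                   pattern = "^trial[0-9]+_log\\.csv$",
                                   full.names = TRUE)), read_motion_log_csv)
    if (length(logs) >= 2) {
      forces <- lapply(logs, function(l) l[, paste0("F_", TENDON_NAMES)])
      disps <- lapply(logs, function(l) l[, paste0("d_axis", 1:5)])
      log_rep[[unit]] <- data.frame(
        unit = unit,
        force_rmse_n = inter_trial_rmse(list(forces))$mean,
        displacement_rmse_mm = inter_trial_rmse(list(disps))$mean)
    }
  }

  report$tables <- list(
    rom = if (length(rom_rows)) do.call(rbind, rom_rows),
    repeatability_angles = if (length(rep_rows)) do.call(rbind, rep_rows),
    repeatability_logs = if (length(log_rep)) do.call(rbind, log_rep))
  jsonlite::write_json(report, file.path(repdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  if (!is.null(report$tables$rom)) {
    .write_csv_precise(report$tables$rom, file.path(repdir, "rom.csv"))
  }
  if (!is.null(report$tables$repeatability_angles)) {
    .write_csv_precise(report$tables$repeatability_angles,
                       file.path(repdir, "repeatability_angles.csv"))
  }
  invisible(structure(report, class = "motion_report"))
}

#' Compare the analysis reports of two conditions
#'
#' Produces a paired per-motion table of the headline metrics of two
#' conditions (e.g. two wrist model variants).
#'
#' @param report_a,report_b `motion_report`s from [analyze_experiment()].
#' @param labels Condition labels.
#' @return Data frame with one row per motion and metric.
#' @export
compare_conditions <- function(report_a, report_b,
                               labels = c("condition_a", "condition_b")) {
  metric_of <- function(m, rep) {
    e <- rep[[m]]
    if (!is.null(e$rom)) e$rom$in_plane_max_deg
    else if (!is.null(e$dtm)) e$dtm$plane_angle_deg
    else if (!is.null(e$ellipse)) e$ellipse$area_deg2
    else NA_real_
  }
  motions <- setdiff(union(names(report_a), names(report_b)), "tables")
  out <- data.frame(motion = motions,
                    a = vapply(motions, metric_of, 0, report_a),
                    b = vapply(motions, metric_of, 0, report_b))
  out$difference <- out$b - out$a
  colnames(out)[2:3] <- labels
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' simulate -> reconstruct -> analyze in one call.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return The `motion_report`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  simulate_experiment(config, out_dir)
  reconstruct_experiment(out_dir, config)
  invisible(analyze_experiment(out_dir, config))
}
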