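# Readers and writers for the interchange formats, the run configuration,
# and the reproducibility manifest. All CSVs have mandatory header rows,
# '.' decimal separators, no thousands separators, and numbers written at
# full double precision so that write -> read -> write round-trips
# bit-identically.

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

.write_csv_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- .fmt_num(out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_checked <- function(path, required_cols,
                              text_cols = c("bone", "marker")) {
  if (!file.exists(path)) stop(sprintf("expected file not found: %s", path))
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("corrupt CSV %s: %s",
                                                  path, conditionMessage(e))))
  miss <- setdiff(required_cols, colnames(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns %s", path, paste(miss, collapse = ", ")))
  }
  for (col in setdiff(required_cols, text_cols)) {
    if (!is.numeric(df[[col]])) {
      num <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(num) & !is.na(df[[col]]))
      if (length(bad)) {
        stop(sprintf("%s: malformed data at line %d", path, bad[1] + 1L))
      }
      df[[col]] <- num
    }
  }
  bad <- which(!stats::complete.cases(df[required_cols]))
  if (length(bad)) {
    stop(sprintf("%s: malformed data at line %d", path, bad[1] + 1L))
  }
  df
}

#' Write / read 3D marker trajectories
#'
#' Long format: `frame, bone, marker, X, Y, Z` (mm).
#' @param marker_3d Per-bone list of `[frame, marker, 3]` arrays.
#' @param path CSV path.
#' @return The path (writer) or the per-bone array list (reader).
#' @export
write_marker_csv <- function(marker_3d, path) {
  rows <- do.call(rbind, lapply(names(marker_3d), function(b) {
    a <- marker_3d[[b]]
    do.call(rbind, lapply(seq_len(dim(a)[1]), function(k) {
      data.frame(frame = k, bone = b, marker = dimnames(a)[[2]],
                 X = a[k, , 1], Y = a[k, , 2], Z = a[k, , 3])
    }))
  }))
  .write_csv_precise(rows, path)
}

#' @rdname write_marker_csv
#' @export
read_marker_csv <- function(path) {
  df <- .read_csv_checked(path, c("frame", "bone", "marker", "X", "Y", "Z"))
  out <- lapply(split(df, df$bone), function(d) {
    markers <- unique(d$marker)
    n <- max(d$frame)
    a <- array(NA_real_, c(n, length(markers), 3),
               dimnames = list(NULL, markers, c("x", "y", "z")))
    for (m in seq_along(markers)) {
      dm <- d[d$marker == markers[m], ]
      dm <- dm[order(dm$frame), ]
      a[dm$frame, m, ] <- as.matrix(dm[, c("X", "Y", "Z")])
    }
    a
  })
  out[intersect(BONE_NAMES, names(out))]
}

#' Write / read a wrist angle series
#'
#' Format: `frame, prosup_deg, fe_deg, rud_deg` (degrees).
#' @param angles A `joint_angles` data frame.
#' @param path CSV path.
#' @export
write_angles_csv <- function(angles, path) {
  .write_csv_precise(as.data.frame(angles), path)
}

#' @rdname write_angles_csv
#' @export
read_angles_csv <- function(path) {
  df <- .read_csv_checked(path, c("frame", "prosup_deg", "fe_deg", "rud_deg"))
  joint_angles(df$prosup_deg, df$fe_deg, df$rud_deg)
}

#' Write / read actuator displacement profiles
#'
#' Format: `frame, axis1..axis5` (mm at the profile sampling rate).
#' @param profile An `actuator_profile` matrix.
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(frame = seq_len(nrow(profile)), unclass(profile))
  .write_csv_precise(df, path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- .read_csv_checked(path, c("frame", paste0("axis", 1:5)))
  as.matrix(df[, paste0("axis", 1:5)])
}

#' Write / read a motion log
#'
#' Format: `time_s, F_ECRL..F_FCU` (N), `d_axis1..d_axis5` (mm), 50 Hz rows.
#' @param log A `motion_log` (or its `log` data frame).
#' @param path CSV path.
#' @export
write_motion_log_csv <- function(log, path) {
  df <- if (inherits(log, "motion_log")) log$log else as.data.frame(log)
  .write_csv_precise(df, path)
}

#' @rdname write_motion_log_csv
#' @export
read_motion_log_csv <- function(path) {
  .read_csv_checked(path, c("time_s", paste0("F_", TENDON_NAMES),
                            paste0("d_axis", 1:5)))
}

#' Write / read a bone pose series
#'
#' Format: `frame, bone, r11..r33` (row-major rotation), `tx, ty, tz` (mm).
#' @param series A `pose_series`.
#' @param path CSV path.
#' @export
write_pose_csv <- function(series, path) {
  rows <- do.call(rbind, lapply(names(series$bones), function(b) {
    bn <- series$bones[[b]]
    n <- dim(bn$R)[3]
    Rflat <- t(vapply(seq_len(n), function(k) as.numeric(t(bn$R[, , k])),
                      numeric(9)))
    colnames(Rflat) <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
    data.frame(frame = seq_len(n), bone = b, Rflat,
               tx = bn$t[, 1], ty = bn$t[, 2], tz = bn$t[, 3])
  }))
  .write_csv_precise(rows, path)
}

#' @rdname write_pose_csv
#' @param fps Sampling rate to attach on read.
#' @export
read_pose_csv <- function(path, fps = 50) {
  rcols <- paste0("r", rep(1:3, each = 3), rep(1:3, 3))
  df <- .read_csv_checked(path, c("frame", "bone", rcols, "tx", "ty", "tz"))
  bones <- lapply(split(df, df$bone), function(d) {
    d <- d[order(d$frame), ]
    n <- nrow(d)
    Rarr <- array(NA_real_, c(3, 3, n))
    for (k in seq_len(n)) {
      Rarr[, , k] <- matrix(as.numeric(d[k, rcols]), 3, 3, byrow = TRUE)
    }
    list(R = Rarr, t = as.matrix(d[, c("tx", "ty", "tz")]))
  })
  pose_series(bones[intersect(BONE_NAMES, names(bones))], fps = fps)
}

#' Write / read biplanar 2D observations
#'
#' Wide per-camera table: `frame`, then `<bone>_<marker>_u, _v` column
#' pairs (px).
#' @param points Array `[frame, marker, 2]` for one camera.
#' @param marker_table Data frame `bone, marker` matching the array columns.
#' @param path CSV path.
#' @export
write_points2d_csv <- function(points, marker_table, path) {
  n <- dim(points)[1]
  df <- data.frame(frame = seq_len(n))
  for (j in seq_len(nrow(marker_table))) {
    base <- marker_table$marker[j]
    df[[paste0(base, "_u")]] <- points[, j, 1]
    df[[paste0(base, "_v")]] <- points[, j, 2]
  }
  .write_csv_precise(df, path)
}

#' @rdname write_points2d_csv
#' @export
read_points2d_csv <- function(path) {
  df <- .read_csv_checked(path, "frame")
  ucols <- grep("_u$", colnames(df), value = TRUE)
  base <- sub("_u$", "", ucols)
  pts <- array(NA_real_, c(nrow(df), length(base), 2))
  for (j in seq_along(base)) {
    pts[, j, 1] <- df[[paste0(base[j], "_u")]]
    pts[, j, 2] <- df[[paste0(base[j], "_v")]]
  }
  bone <- sub("_[0-9]+$", "", base)
  list(points = pts,
       marker_table = data.frame(bone = bone, marker = base,
                                 stringsAsFactors = FALSE))
}

#' Write / read DLT calibration files
#'
#' A 3D bead table (`bead_id, X, Y, Z`, mm) plus per-camera 2D observation
#' tables (`bead_id, u, v`, px).
#' @param cube Data frame from [calibration_cube()].
#' @param cameras List of `dlt_camera`s used to image the cube.
#' @param dir Output directory.
#' @param noise_px Optional Gaussian image noise added to the 2D tables.
#' @return Paths of the written files.
#' @export
write_calibration_csv <- function(cube, cameras, dir, noise_px = 0) {
  p3 <- file.path(dir, "calibration_beads.csv")
  .write_csv_precise(cube, p3)
  p2 <- vapply(seq_along(cameras), function(i) {
    uv <- dlt_project(cameras[[i]], as.matrix(cube[, c("X", "Y", "Z")]))
    if (noise_px > 0) uv <- uv + stats::rnorm(length(uv), 0, noise_px)
    p <- file.path(dir, sprintf("calibration_cam%d.csv", i))
    .write_csv_precise(data.frame(bead_id = cube$bead_id,
                                  u = uv[, 1], v = uv[, 2]), p)
    p
  }, "")
  c(p3, p2)
}

#' @rdname write_calibration_csv
#' @export
read_calibration_csv <- function(dir) {
  p3 <- file.path(dir, "calibration_beads.csv")
  cube <- .read_csv_checked(p3, c("bead_id", "X", "Y", "Z"))
  cams <- list()
  i <- 1
  repeat {
    p <- file.path(dir, sprintf("calibration_cam%d.csv", i))
    if (!file.exists(p)) break
    obs <- .read_csv_checked(p, c("bead_id", "u", "v"))
    obs <- obs[match(cube$bead_id, obs$bead_id), ]
    cams[[i]] <- calibrate_dlt(cube[, c("X", "Y", "Z")], obs[, c("u", "v")])
    i <- i + 1
  }
  if (length(cams) < 2) {
    stop(sprintf("missing calibration: expected %s",
                 file.path(dir, "calibration_cam2.csv")))
  }
  cams
}

#' Write / read anatomical landmark files
#'
#' JSON: bone -> landmark name -> `[X, Y, Z]` mm in the bone's CT frame.
#' @param landmarks List as from [default_landmarks()].
#' @param path JSON path.
#' @export
write_landmarks_json <- function(landmarks, path) {
  jsonlite::write_json(landmarks, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("landmark file not found: %s", path))
  lapply(jsonlite::read_json(path, simplifyVector = TRUE),
         function(set) lapply(set, as.numeric))
}

#' Default run configuration
#'
#' All tolerances and protocol constants default to the rig's stated values
#' (2 N equalization, 50/30 fps, 2 Hz filter cut-off, five trials per
#' motion, 110 cm source-to-image distance); motion amplitudes default to
#' the mean wrist angles the rig achieved.
#'
#' @param seed Integer seed; mandatory, drives all randomness.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed) {
  if (missing(seed) || is.null(seed)) stop("run config requires a seed")
  list(
    seed = as.integer(seed),
    handedness = "left",
    wrist = list(),                       # overrides for default_wrist_geometry()
    cameras = list(source_to_image_mm = 1100, source_to_specimen_mm = 760,
                   focal_px = 3000),
    motions = list(
      flexion = list(amplitude_deg = 50.5, n_frames = 101),
      extension = list(amplitude_deg = 57.2, n_frames = 101),
      RD = list(amplitude_deg = 20.9, n_frames = 101),
      UD = list(amplitude_deg = 29.2, n_frames = 101),
      RE = list(amplitude_deg = 40, dtm_angle_deg = 20.4, n_frames = 101),
      UF = list(amplitude_deg = 40, dtm_angle_deg = 26.2, n_frames = 101),
      circumduction = list(ellipse_axes = c(46, 18), n_frames = 180)
    ),
    n_trials = 5,
    noise_sigma_mm = 0.1,
    trial_jitter_deg = 0.5,
    equalize_target_n = 2,
    equalize_tol_n = 0.01,
    filter_cutoff_hz = 2,
    fps = 50,
    fps_circumduction = 30
  )
}

.CONFIG_KEYS <- names(default_run_config(1))

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected and listed exhaustively; omitted keys take
#' their defaults.
#'
#' @param path YAML file path.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .CONFIG_KEYS)
  if (length(unknown)) {
    stop(sprintf("invalid config keys: %s", paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$seed)) stop("config must set a seed")
  base <- default_run_config(cfg$seed)
  cfg <- utils::modifyList(base, cfg)
  bad <- setdiff(names(cfg$motions), MOTION_NAMES)
  if (length(bad)) {
    stop(sprintf("unknown motion name(s) in protocol: %s",
                 paste(bad, collapse = ", ")))
  }
  cfg
}

#' Write a run configuration to YAML
#' @param config A `run_config` list.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Build a reproducibility manifest for a run directory
#'
#' Records the config hash, a file inventory with per-file row counts and
#' md5 hashes, and the package version. Regenerating a run with the same
#' config and seed reproduces identical hashes.
#'
#' @param config The `run_config` used.
#' @param dir Run output directory.
#' @return Manifest list (also written to `manifest.json` in `dir`).
#' @export
write_manifest <- function(config, dir) {
  files <- sort(setdiff(list.files(dir, recursive = TRUE), "manifest.json"))
  inventory <- lapply(files, function(f) {
    p <- file.path(dir, f)
    rows <- if (grepl("\\.csv$", f)) length(readLines(p)) - 1L else NA_integer_
    list(file = f, rows = rows, md5 = unname(tools::md5sum(p)))
  })
  manifest <- list(run_id = config_hash(config),
                   config_hash = config_hash(config),
                   software = as.character(utils::packageVersion("wristsim")),
                   files = inventory)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
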