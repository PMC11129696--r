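test_that("the noiseless chain recovers bone poses to numerical precision", {
  w <- build_default_wrist("left")
  cams <- default_biplanar_rig()
  sets <- default_marker_sets()
  p <- generate_motion_path("flexion", 50, 40)
  bundle <- make_trial_bundle(w, p, cams, sets, n_trials = 1,
                              noise_sigma_mm = 0, trial_jitter_deg = 0,
                              seed = 1)
  series <- reconstruct_trial(bundle$trials[[1]], cams, sets, smooth = FALSE)
  n <- nrow(p)
  truth_R <- array(0, c(3, 3, n))
  for (k in seq_len(n)) {
    truth_R[, , k] <- cardan_rotation(p$prosup_deg[k], p$fe_deg[k], p$rud_deg[k])
  }
  rot_err <- pose_rot_errors(series$bones$MCIII$R, truth_R)
  expect_lt(max(rot_err), 1e-6)
  expect_lt(max(abs(series$bones$MCIII$t)), 1e-6)  # pure rotation about origin
  expect_lt(max(attr(series, "residuals")), 1e-6)
  expect_equal(nrow(attr(series, "gaps")), 0L)
})

test_that("bead noise at the rig geometry leaves sub-mm sub-deg pose errors", {
  w <- build_default_wrist("left")
  cams <- default_biplanar_rig()
  sets <- default_marker_sets()
  p <- generate_motion_path("flexion", 50, 100)
  bundle <- make_trial_bundle(w, p, cams, sets, n_trials = 1,
                              noise_sigma_mm = 0.1, trial_jitter_deg = 0,
                              seed = 2)
  series <- reconstruct_trial(bundle$trials[[1]], cams, sets, smooth = TRUE)
  n <- nrow(p)
  truth_R <- array(0, c(3, 3, n))
  for (k in seq_len(n)) {
    truth_R[, , k] <- cardan_rotation(p$prosup_deg[k], p$fe_deg[k], p$rud_deg[k])
  }
  core <- 10:90   # away from filter end effects
  rot_rms <- sqrt(mean(pose_rot_errors(series$bones$MCIII$R, truth_R)[core]^2))
  trans_rms <- sqrt(mean(series$bones$MCIII$t[core, ]^2))
  expect_lt(rot_rms, 1)    # sub-degree
  expect_lt(trans_rms, 1)  # sub-millimetre
})

test_that("static bones reconstruct as near-constant poses", {
  w <- build_default_wrist("left")
  cams <- default_biplanar_rig()
  sets <- default_marker_sets()
  p <- generate_motion_path("flexion", 50, 60)
  sigma <- 0.1
  bundle <- make_trial_bundle(w, p, cams, sets, n_trials = 1,
                              noise_sigma_mm = sigma, trial_jitter_deg = 0,
                              seed = 3)
  series <- reconstruct_trial(bundle$trials[[1]], cams, sets, smooth = FALSE)
  # radius is fixed: frame-to-frame jitter of the fitted bone centroid is
  # bounded by the bead noise (centroid noise sd = sigma * sqrt(2/3) per axis)
  pbar <- colMeans(sets$radius$reference_positions)
  centroids <- t(vapply(1:60, function(k)
    as.numeric(series$bones$radius$R[, , k] %*% pbar +
                 series$bones$radius$t[k, ]), numeric(3)))
  expect_lt(max(abs(diff(centroids))), 3 * sigma)
  expect_lt(max(pose_rot_errors(series$bones$radius$R,
                                array(diag(3), c(3, 3, 60)))), 1.5)
})

test_that("a bone-frame with fewer than three beads is an explicit gap", {
  w <- build_default_wrist("left")
  cams <- default_biplanar_rig()
  sets <- default_marker_sets()
  p <- generate_motion_path("flexion", 30, 15)
  bundle <- make_trial_bundle(w, p, cams, sets, n_trials = 1,
                              noise_sigma_mm = 0, trial_jitter_deg = 0,
                              seed = 4)
  tr <- bundle$trials[[1]]
  jj <- which(tr$marker_table$bone == "MCIII")[1:2]
  tr$image_points[[1]][7, jj, ] <- NA  # two beads lost in one camera, frame 7
  series <- reconstruct_trial(tr, cams, sets, smooth = FALSE)
  gaps <- attr(series, "gaps")
  expect_true(any(gaps$bone == "MCIII" & gaps$frame == 7))
  expect_true(all(is.na(series$bones$MCIII$R[, , 7])))
  # other frames unaffected
  expect_false(any(is.na(series$bones$MCIII$R[, , 8])))
})
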