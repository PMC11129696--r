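test_that("force equalization reaches the target from arbitrary starts", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w, initial_forces = c(1, 2, 3, 4, 5), target_n = 2)
  expect_true(all(abs(st$forces - 2) <= 0.01))
  expect_equal(st$encoder_zero, st$position)
  expect_true(all(st$position >= 0 & st$position <= 80))
  expect_lt(max(abs(st$pose)), 0.5)   # settles near neutral
  # from the symmetric default start, neutral is the exact fixed point
  st_sym <- equalize_forces(w, target_n = 2)
  expect_lt(max(abs(st_sym$pose)), 1e-6)
})

test_that("equalization is idempotent and handles the slack limit", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w, target_n = 2)
  st2 <- equalize_forces(w, initial_forces = st$forces, target_n = 2)
  expect_lt(max(abs(st2$position - st$position)), 0.01 / min(w$stiffness) + 1e-9)
  st0 <- equalize_forces(w, target_n = 0)
  expect_true(all(st0$forces <= 0.01))
})

test_that("the equilibrium pose minimizes the elastic energy", {
  w <- build_default_wrist("left")
  pull <- c(ECRL = 0.2, ECRB = 0.1, ECU = 0.3, FCR = 2.5, FCU = 2.5)
  eq <- solve_equilibrium_pose(w, pull)
  expect_lt(eq$grad_norm, 1e-8)
  # brute-force sampling oracle: energy at the solution beats 100 random poses
  energy <- function(th) {
    s <- pmax(0, tendon_lengths(w, th) + pull[names(w$rest_lengths)] -
                w$rest_lengths)
    sum(0.5 * w$stiffness * s^2) + 0.5 * w$passive_stiffness * sum(th^2)
  }
  set.seed(12)
  rand <- replicate(100, energy(runif(3, -60, 60)))
  expect_true(all(eq$energy <= rand + 1e-9))
})

test_that("symmetric flexor pulls produce pure flexion", {
  w <- build_default_wrist("left")
  pull <- c(ECRL = 0, ECRB = 0, ECU = 0, FCR = 3, FCU = 3)
  eq <- solve_equilibrium_pose(w, pull)
  expect_lt(abs(eq$pose[["rud_deg"]]), 1e-5)
  expect_gt(eq$pose[["fe_deg"]], 1)
  # dense grid over (fe, rud) confirms the energy valley sits at rud = 0
  energy <- function(fe, rud) {
    s <- pmax(0, tendon_lengths(w, c(0, fe, rud)) + pull[names(w$rest_lengths)] -
                w$rest_lengths)
    sum(0.5 * w$stiffness * s^2) +
      0.5 * w$passive_stiffness * (fe^2 + rud^2)
  }
  fe_star <- eq$pose[["fe_deg"]]
  g <- expand.grid(fe = seq(fe_star - 5, fe_star + 5, by = 0.5),
                   rud = seq(-5, 5, by = 0.5))
  e <- mapply(energy, g$fe, g$rud)
  expect_lt(abs(g$rud[which.min(e)]), 0.26)
})

test_that("tracking a recorded profile reproduces the motion path", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w)
  p <- generate_motion_path("flexion", 50, 61)
  prof <- record_excursion_profile(w, p)
  log <- track_profile(w, prof, st)
  expect_equal(nrow(log$log), nrow(prof))
  expect_lt(max(abs(log$angles$fe_deg - p$fe_deg)), 0.5)
  expect_lt(max(abs(log$angles$rud_deg)), 0.5)
  # identical reruns give identical logs
  log2 <- track_profile(w, prof, st)
  expect_identical(log$log, log2$log)
})

test_that("zero profiles hold the equalized neutral at the target force", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w)
  zero <- record_excursion_profile(
    w, joint_angles(numeric(20), numeric(20), numeric(20)))
  log <- track_profile(w, zero, st)
  expect_lt(max(abs(angles_peak <- as.matrix(log$angles[, -1]))), 1e-6)
  F <- as.matrix(log$log[, paste0("F_", c("ECRL", "ECRB", "ECU", "FCR", "FCU"))])
  expect_true(all(abs(F - 2) <= 0.011))
})

test_that("logged forces respect the physical bounds in every row", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w)
  prof <- record_excursion_profile(w, generate_motion_path("UD", 29, 41))
  log <- track_profile(w, prof, st)
  F <- as.matrix(log$log[, paste0("F_", c("ECRL", "ECRB", "ECU", "FCR", "FCU"))])
  expect_true(all(F >= 0))
  expect_true(all(F <= 150))
  caps <- force_caps()
  over <- sweep(F, 2, caps[c("ECRL", "ECRB", "ECU", "FCR", "FCU")], `>`)
  expect_equal(sum(over), nrow(log$violations))
})

test_that("tracked motion magnitude grows monotonically with profile scale", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w)
  prof <- record_excursion_profile(w, generate_motion_path("flexion", 30, 31))
  peaks <- vapply(c(0.5, 1, 1.5), function(f) {
    max(track_profile(w, scale_profile(prof, f), st)$angles$fe_deg)
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("force caps are enforced inclusively with a full violation report", {
  caps <- force_caps()
  expect_equal(unname(caps), c(80, 86, 74, 125, 211))
  expect_equal(unname(force_caps(pcsa_cm2 = c(ECRL = 2.5, ECRB = 2.5, ECU = 2.5,
                                              FCR = 2.5, FCU = 2.5))),
               rep(80, 5))

  F <- rbind(c(10, 10, 10, 10, 220), c(10, 10, 74, 10, 10))
  colnames(F) <- c("ECRL", "ECRB", "ECU", "FCR", "FCU")
  res <- enforce_force_cap(F, caps, mode = "flag")
  expect_equal(nrow(res$violations), 1L)
  expect_equal(res$violations$tendon, "FCU")
  expect_equal(res$violations$excess_n, 220 - 211)
  expect_equal(res$forces, F)                      # flag mode never modifies
  clamped <- enforce_force_cap(F, caps, mode = "clamp")
  expect_equal(unname(clamped$forces[1, "FCU"]), 211)
  expect_equal(nrow(clamped$violations), 1L)       # the event stays recorded

  none <- enforce_force_cap(F[2, , drop = FALSE], caps)
  expect_equal(nrow(none$violations), 0L)          # 74.0 N at the ECU cap passes
})

test_that("actuator travel violations abort with the frame index", {
  w <- build_default_wrist("left")
  st <- equalize_forces(w)
  prof <- record_excursion_profile(w, generate_motion_path("flexion", 10, 31))
  prof[5, 2] <- 55   # beyond the remaining travel from mid-position
  expect_error(track_profile(w, prof, st), "travel violation at frame 5")
})
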