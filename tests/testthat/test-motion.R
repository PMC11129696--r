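test_that("planar paths ramp to the exact amplitude and back on one axis", {
  for (n in c(100, 101)) {
    p <- generate_motion_path("flexion", 50, n)
    expect_equal(max(p$fe_deg), 50)
    expect_equal(p$fe_deg[c(1, n)], c(0, 0))
    expect_true(all(p$rud_deg == 0) && all(p$prosup_deg == 0))
  }
  expect_equal(min(generate_motion_path("extension", 57.2, 80)$fe_deg), -57.2)
  expect_equal(min(generate_motion_path("RD", 20, 80)$rud_deg), -20)
  expect_equal(max(generate_motion_path("UD", 29, 80)$rud_deg), 29)
})

test_that("dart thrower paths lie exactly in the commanded oblique plane", {
  p <- generate_motion_path("UF", 30, 100, dtm_angle_deg = 25)
  expect_equal(p$rud_deg, p$fe_deg * tan(25 * pi / 180), tolerance = 1e-12)
  expect_true(all(p$fe_deg >= 0) && all(p$rud_deg >= 0))  # ulnar-flexion quadrant
  r <- generate_motion_path("RE", 30, 100, dtm_angle_deg = 20)
  expect_true(all(r$fe_deg <= 0) && all(r$rud_deg <= 0))  # radial-extension quadrant
})

test_that("circumduction traces the exact ellipse from extension", {
  p <- generate_motion_path("circumduction", n_frames = 200,
                            ellipse_axes = c(50, 25))
  expect_lt(max(abs((p$fe_deg / 50)^2 + (p$rud_deg / 25)^2 - 1)), 1e-9)
  expect_equal(p$fe_deg[1], -50)                       # extension configuration
  expect_equal(p$fe_deg[200], -50)
  expect_equal(attr(p, "fps"), 30)
})

test_that("bad motion requests are rejected", {
  expect_error(generate_motion_path("pirouette", 10, 50), "unknown motion")
  expect_error(generate_motion_path("flexion", 95, 50), "below 90")
  expect_error(generate_motion_path("flexion", 50, 5), "at least 10")
  expect_error(generate_motion_path("UF", 30, 50), "dtm_angle_deg")
  expect_error(generate_motion_path("circumduction", n_frames = 50),
               "ellipse_axes")
})

test_that("excursion profiles are zero at neutral and signed by muscle group", {
  w <- build_default_wrist("left")
  still <- joint_angles(numeric(20), numeric(20), numeric(20))
  expect_true(all(record_excursion_profile(w, still) == 0))

  p <- generate_motion_path("flexion", 50, 51)
  prof <- record_excursion_profile(w, p)
  expect_equal(dim(prof), c(51L, 5L))
  expect_true(all(abs(prof[1, ]) < 1e-12))             # begins at 0 mm
  peak <- which.max(p$fe_deg)
  for (tn in c("FCR", "FCU")) {
    expect_gt(prof[peak, w$axis_map[[tn]]], 0)
  }
  for (tn in c("ECRL", "ECRB", "ECU")) {
    expect_lt(prof[peak, w$axis_map[[tn]]], 0)
  }
})

test_that("excursions beyond the 80 mm actuator travel are flagged", {
  w <- build_default_wrist("left", list(insertion_radius = 120,
                                        insertion_offset = 60))
  p <- generate_motion_path("flexion", 60, 51)
  expect_error(record_excursion_profile(w, p), "travel")
})

test_that("profile scaling is element-wise and endpoint-preserving", {
  w <- build_default_wrist("left")
  prof <- record_excursion_profile(w, generate_motion_path("flexion", 40, 51))
  expect_equal(unclass(scale_profile(prof, 1)), unclass(prof))
  half <- scale_profile(prof, 0.5)
  expect_equal(max(half), max(prof) / 2)
  expect_true(all(abs(half[1, ]) < 1e-12))
  expect_error(scale_profile(prof, 0), "positive")
  expect_error(scale_profile(prof, -2), "positive")
})

test_that("right-arm models drive the mirrored wiring with consistent signs", {
  r <- build_default_wrist("right")
  p <- generate_motion_path("flexion", 40, 41)
  prof <- record_excursion_profile(r, p)
  peak <- which.max(p$fe_deg)
  # flexors shorten on a right arm too, through the right-arm axis wiring
  expect_gt(prof[peak, r$axis_map[["FCR"]]], 0)   # axis 4
  expect_gt(prof[peak, r$axis_map[["FCU"]]], 0)   # axis 5
  expect_lt(prof[peak, r$axis_map[["ECU"]]], 0)   # axis 1
  # mirror symmetry: a right arm under radial deviation behaves exactly as
  # a left arm under ulnar deviation, tendon by tendon - the basis of the
  # rule that right-arm data is sign-mirrored so ulnar(+) serves both arms
  l <- build_default_wrist("left")
  pud <- generate_motion_path("UD", 25, 41)
  prd <- generate_motion_path("RD", 25, 41)
  ang <- function(p) as.matrix(p[, c("prosup_deg", "fe_deg", "rud_deg")])
  len_l <- t(apply(ang(pud), 1, function(q) tendon_lengths(l, q)))
  len_r <- t(apply(ang(prd), 1, function(q) tendon_lengths(r, q)))
  exc_l <- sweep(-len_l, 2, l$rest_lengths, `+`)
  exc_r <- sweep(-len_r, 2, r$rest_lengths, `+`)
  expect_equal(exc_l, exc_r, tolerance = 1e-12)
})
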