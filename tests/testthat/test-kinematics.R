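rotate_landmarks <- function(lm, R, shift = c(0, 0, 0)) {
  lapply(lm, function(p) as.numeric(R %*% p + shift))
}

test_that("axis-aligned landmarks give the lab frame", {
  rcs <- build_rcs(default_landmarks()$radius)
  expect_equal(rcs$R, diag(3), tolerance = 1e-12)
  expect_equal(rcs$origin, c(0, 0, 0))
  mcs <- build_mcs(default_landmarks()$metacarpal)
  expect_equal(mcs$R, diag(3), tolerance = 1e-12)
})

test_that("anatomical frames are equivariant under rigid motion", {
  R <- cardan_rotation(15, -25, 10)
  shift <- c(4, -7, 2)
  rcs0 <- build_rcs(default_landmarks()$radius)
  rcs1 <- build_rcs(rotate_landmarks(default_landmarks()$radius, R, shift))
  expect_equal(rcs1$R, R %*% rcs0$R, tolerance = 1e-9)
  mcs0 <- build_mcs(default_landmarks()$metacarpal)
  mcs1 <- build_mcs(rotate_landmarks(default_landmarks()$metacarpal, R, shift))
  expect_equal(mcs1$R, R %*% mcs0$R, tolerance = 1e-9)
})

test_that("degenerate landmark geometry is rejected", {
  lm <- default_landmarks()$radius
  lm$sigmoid_notch_center <- c(5, 0, 0)   # on the shaft axis
  expect_error(build_rcs(lm), "collinear")
  lm2 <- default_landmarks()$radius
  lm2$shaft_distal <- NULL
  expect_error(build_rcs(lm2), "missing landmarks")
})

test_that("metacarpal y-axis follows the centroid line fit toward MCII", {
  lm <- default_landmarks()$metacarpal
  mcs <- build_mcs(lm)
  expect_gt(sum(mcs$R[, 2] * c(0, 1, 0)), 0.99)   # toward the MCII centroid
  # small perpendicular scatter: y equals the principal direction of the
  # centered centroids (independent line-fit oracle via prcomp)
  lm$centroid_MCII <- c(44, 15, 1.5)
  lm$centroid_MCIII <- c(47, 1, -0.5)
  lm$centroid_MCIV <- c(45, -14, 0.8)
  C <- rbind(lm$centroid_MCII, lm$centroid_MCIII, lm$centroid_MCIV)
  pc1 <- stats::prcomp(C)$rotation[, 1]
  if (sum(pc1 * c(0, 1, 0)) < 0) pc1 <- -pc1
  mcs2 <- build_mcs(lm)
  x <- mcs2$R[, 1]
  expected_y <- pc1 - sum(pc1 * x) * x
  expected_y <- expected_y / sqrt(sum(expected_y^2))
  expect_equal(as.numeric(mcs2$R[, 2]), as.numeric(expected_y),
               tolerance = 1e-9)
})

test_that("relative rotation isolates wrist motion from whole-arm motion", {
  rcs <- build_rcs(default_landmarks()$radius)
  mcs <- build_mcs(default_landmarks()$metacarpal)
  I3 <- list(R = diag(3))
  expect_equal(relative_rotation(rcs, mcs, I3, I3), diag(3))
  R30 <- rot_y(30)
  rel <- relative_rotation(rcs, mcs, I3, list(R = R30))
  expect_equal(decompose_angles(rel)[["fe_deg"]], 30, tolerance = 1e-9)
  # the same whole-arm transform applied to both bones cancels out
  G <- cardan_rotation(8, 17, -12)
  expect_equal(relative_rotation(rcs, mcs, list(R = G), list(R = G)), diag(3),
               tolerance = 1e-12)
})

test_that("Cardan decomposition round-trips gimbal-safe rotations", {
  expect_equal(decompose_angles(diag(3)),
               c(prosup_deg = 0, fe_deg = 0, rud_deg = 0))
  expect_equal(decompose_angles(rot_y(50)),
               c(prosup_deg = 0, fe_deg = 50, rud_deg = 0), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    a <- runif(3, -75, 75)
    R <- cardan_rotation(a[1], a[2], a[3])
    b <- decompose_angles(R)
    expect_lt(max(abs(cardan_rotation(b[1], b[2], b[3]) - R)), 1e-9)
  }
  expect_warning(decompose_angles(cardan_rotation(0, 0, 89.7)), "gimbal")
})

test_that("neutral correction removes the static offset in rotation space", {
  p <- generate_motion_path("flexion", 55, 60)
  static0 <- joint_angles(numeric(10), numeric(10), numeric(10))
  expect_equal(neutral_correct(p, static0)$fe_deg, p$fe_deg, tolerance = 1e-9)

  static5 <- joint_angles(numeric(10), rep(5, 10), numeric(10))
  raw <- joint_angles(numeric(60), p$fe_deg / 55 * 55, numeric(60))
  corr <- neutral_correct(raw, static5)
  expect_equal(max(corr$fe_deg), 55 - 5, tolerance = 1e-9)

  # correcting again with the corrected static is the identity
  static_corr <- neutral_correct(static5, static5)
  twice <- neutral_correct(corr, static_corr)
  expect_equal(twice$fe_deg, corr$fe_deg, tolerance = 1e-9)

  expect_error(neutral_correct(p), "static")
})
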