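angles_df <- function(fe, rud = numeric(length(fe)),
                      prosup = numeric(length(fe))) {
  joint_angles(prosup, fe, rud)
}

test_that("trial averaging truncates to the shortest and takes pointwise means", {
  t1 <- data.frame(fe_deg = c(1, 2, 3))
  t2 <- data.frame(fe_deg = c(3, 4, 5))
  m <- average_trials(list(t1, t2))
  expect_equal(m$fe_deg, c(2, 3, 4))

  lens <- c(100, 98, 99)
  trials <- lapply(lens, function(n) data.frame(fe_deg = seq_len(n)))
  expect_equal(nrow(average_trials(trials)), 98L)

  same <- replicate(5, data.frame(fe_deg = sin(1:20)), simplify = FALSE)
  expect_equal(average_trials(same)$fe_deg, sin(1:20))

  expect_error(average_trials(list(t1)), "2 trials")
})

test_that("profiles are truncated at the motion-specific maximum rotation", {
  fe <- c(seq(0, 50, length.out = 80), seq(49, 30, length.out = 20))
  prof <- angles_df(fe)
  cut <- truncate_to_max(prof, "flexion")
  expect_equal(nrow(cut), 80L)
  expect_equal(cut$fe_deg[80], 50)

  # combined-magnitude rule: cut where sqrt(fe^2 + rud^2) peaks even though
  # |fe| alone peaks later
  fe2 <- c(seq(0, 30, length.out = 60), seq(30, 32, length.out = 40))
  rud2 <- c(seq(0, 40, length.out = 60), seq(40, 0, length.out = 40))
  uf <- angles_df(fe2, rud2)
  comb <- sqrt(fe2^2 + rud2^2)
  expect_equal(nrow(truncate_to_max(uf, "UF")), which.max(comb))
  expect_lt(which.max(comb), which.max(abs(fe2)))

  mono <- angles_df(seq(0, 20, length.out = 30))
  expect_equal(nrow(truncate_to_max(mono, "flexion")), 30L)

  circ <- angles_df(c(1, 2, 1), c(0, 1, 0))
  expect_message(out <- truncate_to_max(circ, "circumduction"), "not truncated")
  expect_equal(nrow(out), 3L)
})

test_that("ROM extraction reads the coupled axis at the in-plane extremum", {
  fe <- seq(0, 50, length.out = 60)
  pure <- angles_df(fe)
  rom <- extract_rom(pure, "flexion")
  expect_equal(rom$in_plane_max_deg, 50)
  expect_equal(rom$out_of_plane_at_max_deg, 0)

  coupled <- angles_df(fe, 0.16 * fe)
  rom2 <- extract_rom(coupled, "flexion")
  expect_equal(rom2$in_plane_max_deg, 50)
  expect_equal(rom2$out_of_plane_at_max_deg, 8)

  ext <- angles_df(-fe)
  expect_equal(extract_rom(ext, "extension")$in_plane_max_deg, -50)
  expect_error(extract_rom(pure, "circumduction"), "unknown planar motion")
})

test_that("the DTM plane angle is exact on generated oblique planes", {
  fe <- seq(0, 40, length.out = 50)
  on45 <- angles_df(fe, -fe)          # fe = -rud: the 45 degree plane
  f <- fit_dtm_plane(on45)
  expect_equal(f$plane_angle_deg, 45, tolerance = 1e-9)
  expect_equal(f$r_squared, 1)
  expect_equal(f$fit_rmse_deg, 0, tolerance = 1e-9)
  expect_false(f$excluded)

  for (ang in c(5, 10, 25, 45, 60)) {
    p <- generate_motion_path("UF", 30, 60, dtm_angle_deg = ang)
    fit <- fit_dtm_plane(p)
    expect_lt(abs(fit$plane_angle_deg - ang), 0.1)
    expect_false(fit$excluded)
  }
})

test_that("trend-free scatter is excluded by the R^2 rule", {
  set.seed(21)
  cloud <- angles_df(rnorm(100, 0, 5), rnorm(100, 0, 5))
  f <- fit_dtm_plane(cloud)
  expect_lt(f$r_squared, 0.7)
  expect_true(f$excluded)
  expect_error(fit_dtm_plane(angles_df(1:5)), ">= 10")
})

test_that("ellipse fitting recovers circles and axis-aligned ellipses exactly", {
  th <- seq(0, 2 * pi, length.out = 121)[-121]
  circ <- data.frame(rud_deg = 10 * cos(th), fe_deg = 10 * sin(th))
  f <- fit_circumduction_ellipse(circ)
  expect_equal(f$a, 10, tolerance = 1e-9)
  expect_equal(f$b, 10, tolerance = 1e-9)
  expect_equal(f$area_deg2, 100 * pi, tolerance = 1e-9)
  expect_equal(f$rmse_deg, 0, tolerance = 1e-9)
  expect_equal(f$area_deg2, pi * f$a * f$b, tolerance = 1e-9)

  ell <- data.frame(rud_deg = 25 * cos(th), fe_deg = 50 * sin(th))
  f2 <- fit_circumduction_ellipse(ell)
  expect_equal(f2$a, 50, tolerance = 1e-9)
  expect_equal(f2$b, 25, tolerance = 1e-9)
  expect_equal(f2$orientation_deg, 0, tolerance = 1e-6)
  expect_equal(f2$area_deg2, 1250 * pi, tolerance = 1e-9)
})

test_that("rotated noisy envelopes recover orientation and area", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  rot <- 12 * pi / 180
  set.seed(31)
  for (i in 1:20) {
    x0 <- 25 * cos(th); y0 <- 50 * sin(th)
    x <- x0 * cos(rot) - y0 * sin(rot)
    y <- x0 * sin(rot) + y0 * cos(rot)
    r <- sqrt(x^2 + y^2) + rnorm(length(th), 0, 0.5)
    a <- atan2(y, x)
    f <- fit_circumduction_ellipse(data.frame(rud_deg = r * cos(a),
                                              fe_deg = r * sin(a)))
    expect_lt(abs(f$orientation_deg - 12), 1)
    expect_lt(abs(f$area_deg2 / (1250 * pi) - 1), 0.02)
  }
})

test_that("open paths are rejected by the coverage check", {
  th <- seq(0, pi, length.out = 60)    # half an ellipse
  expect_error(fit_circumduction_ellipse(
    data.frame(rud_deg = 20 * cos(th), fe_deg = 30 * sin(th))), "350")
  expect_error(fit_circumduction_ellipse(
    data.frame(rud_deg = rnorm(10), fe_deg = rnorm(10))), ">= 20")
})

test_that("joining circumduction halves restores the unsplit envelope", {
  p <- generate_motion_path("circumduction", n_frames = 160,
                            ellipse_axes = c(46, 18))
  mid <- which.max(p$fe_deg)
  a <- as.data.frame(p)[1:mid, ]
  b <- as.data.frame(p)[mid:nrow(p), ]
  joined <- join_circumduction(a, b)
  expect_equal(nrow(joined), nrow(a) + nrow(b) - 1L)
  f_joined <- fit_circumduction_ellipse(joined)
  f_whole <- fit_circumduction_ellipse(as.data.frame(p))
  expect_equal(f_joined$area_deg2, f_whole$area_deg2, tolerance = 1e-6)
  expect_equal(f_joined$a, f_whole$a, tolerance = 1e-6)

  b_gap <- b
  b_gap$fe_deg <- b_gap$fe_deg + 5
  expect_error(join_circumduction(a, b_gap), "5\\.00 deg")
})
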