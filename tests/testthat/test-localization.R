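test_that("largest_target_region picks the biggest 8-connected component", {
  m <- matrix(0L, 20, 20)
  m[2:11, 2:11] <- 2L   # 100 px
  m[15:18, 15:19] <- 2L # 20 px
  reg <- largest_target_region(m)
  expect_equal(sum(reg), 100)
  expect_true(all(which(reg) %in% which(m == 2L)))

  # diagonal touching counts as connected (8-connectivity)
  d <- matrix(0L, 6, 6)
  d[1, 1] <- 2L; d[2, 2] <- 2L; d[3, 3] <- 2L
  expect_equal(sum(largest_target_region(d)), 3)

  # equal sizes: earliest first pixel in row-major (reading) order wins
  t2 <- matrix(0L, 10, 10)
  t2[5, 1:3] <- 2L  # first pixel row 5, col 1
  t2[2, 6:8] <- 2L  # first pixel row 2, col 6 -> earlier in reading order
  reg2 <- largest_target_region(t2)
  expect_true(reg2[2, 6])
  expect_false(reg2[5, 1])

  expect_error(largest_target_region(matrix(0L, 5, 5)), "target-not-found")
})

test_that("moment ellipse matches closed-form oracles", {
  # filled circle radius 20 at (50, 60): axes ~ 2r, theta 0 by tie-break
  f <- fit_ellipse(disk_region(120, 120, 50, 60, 20))
  expect_equal(f$cx, 50, tolerance = 0.05)
  expect_equal(f$cy, 60, tolerance = 0.05)
  expect_equal(f$major, 40, tolerance = 40 * 0.02)
  expect_equal(f$minor, 40, tolerance = 40 * 0.02)
  expect_equal(f$theta, 0)

  # axis-aligned 40x10 rectangle: theta 0, major > minor
  rect <- matrix(FALSE, 100, 100)
  rect[40:49, 20:59] <- TRUE
  fr <- fit_ellipse(rect)
  expect_equal(fr$theta, 0)
  expect_gt(fr$major, fr$minor)

  # the same rectangle rotated 30 degrees: theta = 30 +/- 2
  fr30 <- fit_ellipse(rotate_region(rect, 30))
  expect_equal(fr30$theta, 30, tolerance = 2 / 30)

  expect_error(fit_ellipse(matrix(c(TRUE, rep(FALSE, 99)), 10, 10)),
               "at least 5")
})

test_that("ellipse fit is translation-equivariant and scale follows sqrt law", {
  reg <- rotate_region({
    r <- matrix(FALSE, 90, 90); r[40:49, 20:59] <- TRUE; r
  }, 20)
  f0 <- fit_ellipse(reg)
  sh <- matrix(FALSE, 90, 90)
  sh[8:90, 5:90] <- reg[1:83, 1:86]
  fs <- fit_ellipse(sh)
  expect_equal(fs$cx - f0$cx, 4, tolerance = 1e-9)
  expect_equal(fs$cy - f0$cy, 7, tolerance = 1e-9)
  expect_equal(fs$major, f0$major, tolerance = 1e-9)
  expect_equal(fs$theta, f0$theta, tolerance = 1e-9)

  # doubling linear size doubles the scale estimate (+/- 2%)
  small <- disk_region(200, 200, 60, 60, 20)
  big <- disk_region(200, 200, 100, 100, 40)
  ref <- scale_reference_from_fit(fit_ellipse(small), 1)
  expect_equal(estimate_scale(fit_ellipse(big), ref), 2, tolerance = 0.02)
  expect_equal(estimate_scale(fit_ellipse(small), ref), 1, tolerance = 1e-6)

  # rotation equivariance for elongation >= 2
  for (phi in c(10, 45, 75)) {
    fphi <- fit_ellipse(rotate_region({
      r <- matrix(FALSE, 120, 120); r[55:64, 20:99] <- TRUE; r
    }, phi))
    expect_equal(fphi$theta, phi, tolerance = 2 / phi)
  }
})

test_that("position and scale estimates match simulator ground truth", {
  mesh <- test_organ_mesh()
  cfg <- test_organ_config()
  ref <- local({
    s <- render_scene(mesh, pose6d(31.5, 31.5, 1), cfg, seed = 1)
    scale_reference_from_fit(fit_ellipse(largest_target_region(s$mask)), 1)
  })
  pos_err <- scale_err <- numeric(0)
  set.seed(42)
  for (i in 1:25) {
    p <- pose6d(31.5 + runif(1, -4, 4), 31.5 + runif(1, -4, 4),
                runif(1, 0.8, 1.2), runif(1, -10, 10), runif(1, -10, 10),
                runif(1, -10, 10))
    s <- render_scene(mesh, p, cfg, seed = i)
    fit <- fit_ellipse(largest_target_region(s$mask))
    est <- estimate_position(fit)
    pos_err <- c(pos_err, sqrt((est[1] - p$tx)^2 + (est[2] - p$ty)^2))
    scale_err <- c(scale_err, abs(estimate_scale(fit, ref) - p$scale))
  }
  expect_lte(median(pos_err), 2)
  expect_lte(median(scale_err), 0.05)

  # partial occlusion (<= 40%) still localizes within 10 px
  cfg2 <- scene_config(image_size = c(64, 64), n_tools = 2)
  s <- render_scene(mesh, pose6d(31.5, 31.5, 1), cfg2, seed = 3)
  fit <- fit_ellipse(largest_target_region(s$mask))
  est <- estimate_position(fit)
  expect_lt(sqrt((est[1] - 31.5)^2 + (est[2] - 31.5)^2), 10)
})

test_that("mask-derived in-plane rotation recovers the rendered tilt", {
  # identity calibration on a horizontal silhouette gives 0
  rect <- matrix(FALSE, 64, 64)
  rect[30:35, 10:54] <- TRUE
  expect_equal(mask_y_rotation(fit_ellipse(rect)), 0)

  # near-circular silhouette is rejected as axis-ambiguous
  expect_error(mask_y_rotation(fit_ellipse(disk_region(64, 64, 31, 31, 15))),
               "axis-ambiguous")

  # rendered catheter at a known in-plane tilt of 25 degrees:
  # theta_img = atan2(sin rx cos ry, sin ry); choose rx so theta = 25
  cfg <- scene_config_catheter()
  mesh <- make_mesh("instrument-cylinder", cfg$target_params, seed = 0)
  ry <- 50
  rx <- asin(tan(25 * pi / 180) * tan(ry * pi / 180)) * 180 / pi
  s <- render_scene(mesh, pose6d(31.5, 31.5, 1, rx, ry, 0), cfg, seed = 2)
  est <- mask_y_rotation(fit_ellipse(largest_target_region(s$mask)))
  expect_equal(est, 25, tolerance = 3 / 25)
})
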