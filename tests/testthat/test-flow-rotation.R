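# smoothed random texture used by the flow contract tests
smooth_noise <- function(H, W, seed, passes = 3) {
  set.seed(seed)
  m <- matrix(runif(H * W), H, W)
  for (i in seq_len(passes)) {
    m <- (m + rbind(m[1, ], m[-H, ]) + rbind(m[-1, ], m[H, ]) +
            cbind(m[, 1], m[, -W]) + cbind(m[, -1], m[, W])) / 5
  }
  m
}

test_that("dense flow meets its displacement contract", {
  tex <- smooth_noise(96, 96, 1)
  # identical frames: essentially zero magnitude
  f0 <- dense_flow(tex, tex)
  expect_lt(median(f0$magnitude), 0.05)

  # 1-px horizontal shift: median du in [0.8, 1.2], dv in [-0.2, 0.2]
  shifted <- cbind(tex[, 1], tex[, -96])
  fl <- dense_flow(tex, shifted)
  inner <- 17:80
  expect_gt(median(fl$du[inner, inner]), 0.8)
  expect_lt(median(fl$du[inner, inner]), 1.2)
  expect_lt(abs(median(fl$dv[inner, inner])), 0.2)
  expect_equal(fl$magnitude, sqrt(fl$du^2 + fl$dv^2))
  expect_error(dense_flow(tex, tex[1:50, ]), "size mismatch")
})

test_that("pure in-plane rotation of a textured disk recovers the curl", {
  H <- 96; cx <- 47.5
  tex <- smooth_noise(H, H, 2)
  th <- 2 * pi / 180
  rot <- matrix(0, H, H)
  for (r in 1:H) for (c in 1:H) {
    xs <- cos(th) * (c - 1 - cx) + sin(th) * (r - 1 - cx) + cx
    ys <- -sin(th) * (c - 1 - cx) + cos(th) * (r - 1 - cx) + cx
    r0 <- floor(ys); c0 <- floor(xs)
    if (r0 >= 0 && c0 >= 0 && r0 < H - 1 && c0 < H - 1) {
      fy <- ys - r0; fx <- xs - c0
      rot[r, c] <- (1 - fy) * ((1 - fx) * tex[r0 + 1, c0 + 1] + fx * tex[r0 + 1, c0 + 2]) +
        fy * ((1 - fx) * tex[r0 + 2, c0 + 1] + fx * tex[r0 + 2, c0 + 2])
    }
  }
  mask <- matrix(0L, H, H)
  mask[disk_region(H, H, cx, cx, 34)] <- 2L
  fl <- dense_flow(tex, rot)
  d <- decompose_motion(masked_flow(fl, mask), fit_ellipse(mask == 2))
  expect_equal(abs(d$omega), th, tolerance = 0.2)
})

test_that("masked_flow restricts to the target intersection", {
  tex <- smooth_noise(48, 48, 3)
  fl <- dense_flow(tex, tex)
  m1 <- matrix(0L, 48, 48); m1[10:30, 10:30] <- 2L
  m2 <- matrix(0L, 48, 48); m2[15:35, 10:30] <- 2L
  mf <- masked_flow(fl, m1, m2)
  expect_equal(mf$n, 21 * 16)
  expect_error(masked_flow(fl, matrix(0L, 48, 48)), "no-target-flow")
  full <- matrix(2L, 48, 48)
  expect_equal(masked_flow(fl, full)$n, 48 * 48)
  expect_error(masked_flow(fl, matrix(0L, 10, 10)), "shape mismatch")
})

test_that("affine decomposition reproduces analytic fields to 1e-6", {
  H <- 64
  mask <- matrix(0L, H, H)
  mask[disk_region(H, H, 31.5, 31.5, 20)] <- 2L
  fit <- fit_ellipse(mask == 2)
  idx <- which(mask == 2)
  x <- (idx - 1) %/% H; y <- (idx - 1) %% H

  # pure curl omega0 = 0.0349: du = -w(y-cy), dv = w(x-cx)
  w0 <- 0.0349
  fl <- list(du = matrix(0, H, H), dv = matrix(0, H, H))
  fl$du[idx] <- -w0 * (y - fit$cy)
  fl$dv[idx] <- w0 * (x - fit$cx)
  class(fl) <- "flow_field"
  d <- decompose_motion(masked_flow(fl, mask), fit)
  expect_equal(d$omega, w0, tolerance = 1e-6)
  expect_lt(max(abs(d$t)), 1e-6)
  expect_lt(abs(d$s), 1e-6)

  # brute-force normal-equations oracle on a random affine field
  set.seed(4)
  A0 <- matrix(rnorm(4, sd = 0.05), 2, 2)
  t0 <- rnorm(2)
  fl$du[idx] <- A0[1, 1] * (x - fit$cx) + A0[1, 2] * (y - fit$cy) + t0[1]
  fl$dv[idx] <- A0[2, 1] * (x - fit$cx) + A0[2, 2] * (y - fit$cy) + t0[2]
  d2 <- decompose_motion(masked_flow(fl, mask), fit)
  M <- cbind(x - fit$cx, y - fit$cy, 1)
  cu <- solve(t(M) %*% M, t(M) %*% fl$du[idx])
  expect_equal(d2$A[1, 1], cu[1], tolerance = 1e-6)
  expect_equal(unname(d2$t[1]), unname(cu[3]), tolerance = 1e-6)
  expect_equal(d2$A, A0, tolerance = 1e-6)

  # uniform translation with matching centre displacement: no curl, no slip
  fl$du[idx] <- 3; fl$dv[idx] <- 0
  fit2 <- fit; fit2$cx <- fit$cx + 3
  d3 <- decompose_motion(masked_flow(fl, mask), fit, fit2)
  expect_equal(d3$omega, 0, tolerance = 1e-9)
  expect_equal(unname(d3$r), c(0, 0), tolerance = 1e-9)

  # zero field -> all zero
  fl$du[idx] <- 0; fl$dv[idx] <- 0
  d4 <- decompose_motion(masked_flow(fl, mask), fit)
  expect_equal(d4$omega, 0)
  expect_equal(unname(d4$r), c(0, 0))

  # degenerate region
  thin <- matrix(0L, H, H); thin[10, 1:40] <- 2L
  expect_error(decompose_motion(masked_flow(fl, thin), fit), "rank-deficient")
})

test_that("flow_to_rotation converts curl and slip with the fixed signs", {
  d <- structure(list(omega = 0.0349, s = 0, r = c(0, 0)), class = "motion_decomposition")
  inc <- flow_to_rotation(d, list(kx = 1, ky = 1))
  expect_equal(unname(inc), c(0, 0, -2.0), tolerance = 1e-3)

  d2 <- structure(list(omega = 0, s = 0, r = c(2, 0)), class = "motion_decomposition")
  expect_equal(unname(flow_to_rotation(d2, list(kx = 1, ky = 0.5))),
               c(0, 1.0, 0))

  d0 <- structure(list(omega = 0, s = 0, r = c(0, 0)), class = "motion_decomposition")
  expect_equal(unname(flow_to_rotation(d0, list(kx = 1, ky = 1))), c(0, 0, 0))
  expect_error(flow_to_rotation(d0, list(kx = -1, ky = 1)), "> 0")
  # dead-band zeroes sub-threshold slip
  dsmall <- structure(list(omega = 0, s = 0, r = c(0.01, 0.01)),
                      class = "motion_decomposition")
  expect_equal(unname(flow_to_rotation(dsmall, list(kx = 5, ky = 5))), c(0, 0, 0))
})

test_that("static sequences produce zero drift and calibration refuses them", {
  mesh <- test_organ_mesh()
  cfg <- test_organ_config()
  sq <- generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0, 0, 0), 12,
                          cfg, seed = 5)
  est <- track_sequence(sq, init_pose = pose6d(31.5, 31.5, 1),
                        calib = list(kx = 5, ky = 5))
  expect_true(all(abs(est$angles) <= 1e-9))
  expect_error(calibrate_flow(seq_y = sq), "dead-band")
  expect_error(track_sequence(sq$frames[1], list(sq$frames[[1]]$mask),
                              pose6d(31.5, 31.5, 1), list(kx = 1, ky = 1)),
               "at least 2")
})

test_that("tracking additivity: whole sequence equals its two halves", {
  mesh <- test_organ_mesh()
  cfg <- test_organ_config(ranges = rotation_ranges(z = c(-5, 30)))
  sq <- generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0, 0, 0.8), 13,
                          cfg, seed = 6)
  cal <- list(kx = 5, ky = 5)
  init <- pose6d(31.5, 31.5, 1)
  whole <- track_sequence(sq, init_pose = init, calib = cal)
  frames <- lapply(sq$frames, `[[`, "image")
  masks <- lapply(sq$frames, `[[`, "mask")
  first <- track_sequence(frames[1:7], masks[1:7], init, cal)
  mid <- pose6d(31.5, 31.5, 1, first$angles[7, 1], first$angles[7, 2],
                first$angles[7, 3])
  second <- track_sequence(frames[7:13], masks[7:13], mid, cal)
  expect_equal(whole$angles[13, ], second$angles[7, ], tolerance = 1e-9)
})

test_that("reversing a sequence negates the accumulated Z rotation", {
  mesh <- test_organ_mesh()
  cfg <- test_organ_config(ranges = rotation_ranges(z = c(-5, 30)))
  sq <- generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0, 0, 0.8), 13,
                          cfg, seed = 6)
  cal <- list(kx = 5, ky = 5)
  fwd <- track_sequence(sq, init_pose = pose6d(31.5, 31.5, 1), calib = cal)
  rv <- sq
  rv$frames <- rev(sq$frames)
  bwd <- track_sequence(rv, init_pose = pose6d(31.5, 31.5, 1), calib = cal)
  dz_f <- fwd$angles[13, "rz"]
  dz_b <- bwd$angles[13, "rz"]
  expect_lt(abs(dz_f + dz_b), 0.1 * abs(dz_f))
})

test_that("trajectory evaluation samples every 10th frame", {
  est <- structure(list(angles = matrix(0, 31, 3,
                                        dimnames = list(NULL, c("rx", "ry", "rz"))),
                        sample_idx = seq(1, 31, 10), flagged = logical(31)),
                   class = "trajectory_estimate")
  truth <- matrix(0, 31, 3, dimnames = list(NULL, c("rx", "ry", "rz")))
  ev <- evaluate_trajectory(est, truth)
  expect_true(all(ev$accuracy == 1))
  # constant +7 offset: 0 at tol 5, 1 at tol 10
  est$angles <- est$angles + 7
  ev2 <- evaluate_trajectory(est, truth)
  expect_true(all(ev2$accuracy[ev2$tol == 5] == 0))
  expect_true(all(ev2$accuracy[ev2$tol == 10] == 1))
  expect_error(evaluate_trajectory(est, truth[1:10, ]), "cover")
})
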