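test_that("built-in meshes are centred, closed and correctly sized", {
  m <- make_mesh("organ-ellipsoid", list(semi_axes = c(1, 0.8, 0.7)), seed = 0)
  expect_true(all(abs(colMeans(m$vertices)) < 1e-10))
  expect_silent(validate_mesh(m))

  cyl <- make_mesh("instrument-cylinder", list(radius = 0.1, length = 2.0))
  ext <- apply(cyl$vertices, 2, function(v) diff(range(v)))
  expect_equal(unname(ext), c(0.2, 0.2, 2.0), tolerance = 1e-10)
  expect_silent(validate_mesh(cyl))

  expect_error(make_mesh("organ-ellipsoid", list(semi_axes = c(1, -1, 1))),
               "positive")
  expect_error(make_mesh("instrument-cylinder", list(radius = 0, length = 1)),
               "positive")
  expect_error(make_mesh("banana"), "unknown")
})

test_that("rendering is bit-deterministic and masks carry the right classes", {
  mesh <- test_organ_mesh()
  cfg <- scene_config(image_size = c(64, 64))
  p <- pose6d(31.5, 31.5, 1, -5, 3, 8)
  s1 <- render_scene(mesh, p, cfg, seed = 3)
  s2 <- render_scene(mesh, p, cfg, seed = 3)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  expect_true(all(s1$mask %in% 0:2))
  expect_identical(dim(s1$image)[1:2], dim(s1$mask))

  # zero tools -> classes {0, 2} only
  s0 <- render_scene(mesh, p, test_organ_config(), seed = 3)
  expect_true(all(s0$mask %in% c(0L, 2L)))
  expect_gt(sum(s0$mask == 2), 0)
})

test_that("target mask area follows the square scale law", {
  mesh <- test_organ_mesh()
  cfg <- test_organ_config()
  a1 <- sum(render_scene(mesh, pose6d(31.5, 31.5, 1), cfg, seed = 5)$mask == 2)
  a05 <- sum(render_scene(mesh, pose6d(31.5, 31.5, 0.5), cfg, seed = 5)$mask == 2)
  expect_gt(a1 / a05, 4 * 0.95)
  expect_lt(a1 / a05, 4 * 1.05)

  areas <- vapply(seq(0.5, 1.5, by = 0.25), function(sc) {
    sum(render_scene(mesh, pose6d(31.5, 31.5, sc), cfg, seed = 5)$mask == 2)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("a pose outside the frame raises target-out-of-view", {
  mesh <- test_organ_mesh()
  expect_error(
    render_scene(mesh, pose6d(5000, 5000, 1), test_organ_config(), seed = 1),
    "target-out-of-view")
})

test_that("tool occlusion never exceeds the configured cap", {
  mesh <- test_organ_mesh()
  cfg <- scene_config(image_size = c(64, 64), n_tools = 2)
  for (sd in 1:8) {
    s <- render_scene(mesh, pose6d(31.5, 31.5, 1), cfg, seed = sd)
    occ <- 1 - s$meta$visible_px / s$meta$silhouette_px
    expect_lte(occ, cfg$occlusion_cap + 1e-9)
  }
})

test_that("generate_dataset splits 70/15/15, draws labels in range, reproduces", {
  cfg <- scene_config_catheter(image_size = c(48, 48))
  man <- generate_dataset(20, config = cfg, seed = 3, out_dir = tempfile())
  expect_equal(as.integer(table(man$split)[c("train", "val", "test")]),
               c(14L, 3L, 3L))
  expect_true(all(man$rx >= -40 & man$rx <= 10))
  man2 <- generate_dataset(20, config = cfg, seed = 3, out_dir = tempfile())
  expect_equal(man$rx, man2$rx)
  expect_equal(man$split, man2$split)
  # n = 10 -> 7/1/2 by floor arithmetic with the remainder in test
  man10 <- generate_dataset(10, config = cfg, seed = 1, out_dir = tempfile())
  expect_equal(as.integer(table(man10$split)[c("train", "val", "test")]),
               c(7L, 1L, 2L))
  expect_error(generate_dataset(5, config = cfg, seed = 1), "at least 10")
})

test_that("dataset files round-trip through PNG with literal class IDs", {
  man <- test_seg_dataset()
  dir <- attr(man, "dir")
  msk <- read_mask(file.path(dir, man$mask[1]))
  expect_true(all(msk %in% 0:2))
  img <- read_image(file.path(dir, man$image[1]))
  expect_true(all(img >= 0 & img <= 255))
  expect_identical(read_manifest(dir)$image, man$image)
})

test_that("sequences accumulate, clamp to range with a warning, stay static", {
  mesh <- test_organ_mesh()
  cfg <- test_organ_config()
  sq <- generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0.2, 0, 0), 20,
                          cfg, seed = 2)
  expect_equal(nrow(sq$trajectory), 20)
  expect_true(all(abs(diff(sq$trajectory[, "rx"]) - 0.2) < 1e-12))

  # static: identical poses and constant trajectory
  sq0 <- generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0, 0, 0), 5,
                           cfg, seed = 2)
  expect_true(all(sq0$trajectory == sq0$trajectory[1, col(sq0$trajectory)]))
  expect_identical(sq0$frames[[1]]$image, sq0$frames[[5]]$image)

  # leaving the configured range clamps and warns
  cfgz <- test_organ_config(ranges = rotation_ranges(z = c(-10, 10)))
  expect_warning(
    sqc <- generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0, 0, 0.5), 60,
                             cfgz, seed = 2),
    "clamped")
  expect_equal(max(sqc$trajectory[, "rz"]), 10)
  expect_error(generate_sequence(mesh, pose6d(31.5, 31.5, 1), c(0, 0, 0), 1,
                                 cfg, seed = 1), "at least 2")
})

test_that("scene config round-trips through YAML", {
  cfg <- scene_config_catheter()
  f <- tempfile(fileext = ".yaml")
  write_scene_config(cfg, f)
  cfg2 <- read_scene_config(f)
  expect_equal(cfg2$image_size, cfg$image_size)
  expect_equal(cfg2$ranges$x, cfg$ranges$x)
  expect_equal(cfg2$ranges$y, "mask-derived")
  expect_equal(cfg2$mask_axis_base, cfg$mask_axis_base)
})
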