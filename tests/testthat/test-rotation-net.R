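test_that("angle binning arithmetic matches the bin oracle", {
  b <- make_binning(-40, 10, 1)
  expect_equal(b$n, 50L)

  b2 <- make_binning(-10, 10, 1)
  expect_equal(b2$n, 20L)
  expect_equal(encode_angle(b2, 0.0), 10L)
  expect_equal(decode_angle(b2, 10L), 0.5)
  expect_equal(encode_angle(b2, b2$lo), 0L)
  expect_equal(decode_angle(b2, 0L), b2$lo + b2$w / 2)

  expect_error(make_binning(5, 5), "invalid range")
  expect_error(make_binning(0, 10, -1), "invalid bin width")
})

test_that("encode/decode round-trip error is at most half a bin (property)", {
  for (spec in list(c(-40, 10, 1), c(-15, 20, 1), c(-5, 15, 0.5), c(0, 7, 2))) {
    b <- make_binning(spec[1], spec[2], spec[3])
    a <- seq(spec[1], spec[2] - 1e-9, length.out = 200)
    back <- decode_angle(b, encode_angle(b, a))
    expect_true(all(abs(back - a) <= b$w / 2 + 1e-9))
  }
})

test_that("tolerance accuracy counts correctly and is monotone in tol", {
  expect_equal(tolerance_accuracy(c(0, 7, -3), c(0, 0, 0), 5), 2 / 3)
  expect_equal(tolerance_accuracy(c(0, 7, -3), c(0, 0, 0), 10), 1)
  expect_error(tolerance_accuracy(1:3, 1:2, 5), "length mismatch")
  expect_error(tolerance_accuracy(1, 1, -1), ">= 0")
  set.seed(2)
  for (i in 1:10) {
    pred <- runif(50, -40, 10)
    tru <- runif(50, -40, 10)
    accs <- vapply(c(0, 1, 2, 5, 10, 25), function(tol)
      tolerance_accuracy(pred, tru, tol), numeric(1))
    expect_true(all(diff(accs) >= 0))
  }
})

test_that("head count follows the range specification", {
  man <- test_rot_dataset()
  cfg <- rot_config(epochs = 1, width = 4, head_width = 16, seed = 0)
  m1 <- train_rotation_net(man, man, ranges_catheter(), cfg)
  expect_equal(length(m1$axes), 1)
  expect_equal(m1$axes, "x")
  expect_equal(m1$arch$n_classes, 50L)

  # three-axis organ spec -> three heads (relabel the same frames)
  man3 <- man
  man3$ry <- runif(nrow(man3), -10, 10)
  man3$rz <- runif(nrow(man3), -10, 10)
  man3$rx <- runif(nrow(man3), -10, 10)
  attr(man3, "dir") <- attr(man, "dir")
  m3 <- train_rotation_net(man3, man3, ranges_kidney(), cfg)
  expect_equal(length(m3$axes), 3)
  expect_equal(m3$arch$n_classes, rep(20L, 3))
})

test_that("training is seed-reproducible and rejects out-of-range labels", {
  man <- test_rot_dataset()
  cfg <- rot_config(epochs = 2, width = 4, head_width = 16, seed = 1)
  m1 <- train_rotation_net(man, man, ranges_catheter(), cfg)
  m2 <- train_rotation_net(man, man, ranges_catheter(), cfg)
  expect_equal(m1$log$val_acc5, m2$log$val_acc5)
  expect_equal(m1$log$loss, m2$log$loss)

  bad <- man
  bad$rx[1] <- 55
  attr(bad, "dir") <- attr(man, "dir")
  expect_error(train_rotation_net(bad, man, ranges_catheter(), cfg),
               "outside its range")
})

test_that("prediction decodes bin centres deterministically with softmax heads", {
  man <- test_rot_dataset()
  m <- train_rotation_net(man, man, ranges_catheter(),
                          rot_config(epochs = 1, width = 4, head_width = 16))
  img <- load_split(man, "test")$images[[1]]
  p1 <- predict_rotation(m, img)
  p2 <- predict_rotation(m, img)
  expect_identical(p1$angles, p2$angles)
  expect_equal(sum(p1$probs$x), 1, tolerance = 1e-6)
  centres <- decode_angle(m$binnings[[1]], 0:(m$binnings[[1]]$n - 1))
  expect_true(p1$angles[["x"]] %in% centres)
  expect_error(predict_rotation(m, img[1:10, 1:10, , drop = FALSE]),
               "resolution mismatch")
})

test_that("trained single-axis model beats the majority-class baseline", {
  man <- test_rot_dataset()
  all_rows <- load_split(man)
  m <- train_rotation_net(all_rows, all_rows, ranges_catheter(),
                          rot_config(epochs = 60, width = 8, head_width = 64,
                                     augment_shift = 0, seed = 0))
  te <- all_rows
  x <- endopose:::stack_images(te$images)
  dec <- endopose:::decode_rotnet(m$ptr, x, m$binnings)
  acc <- tolerance_accuracy(dec[, 1], te$labels$rx, 5)
  # majority baseline: predict the most common bin centre everywhere
  maj <- decode_angle(m$binnings[[1]],
                      as.integer(names(which.max(table(
                        encode_angle(m$binnings[[1]], te$labels$rx))))))
  base <- tolerance_accuracy(rep(maj, nrow(dec)), te$labels$rx, 5)
  expect_gte(acc - base, 0.5)
})

test_that("rotation checkpoints round-trip through save_model/load_model", {
  man <- test_rot_dataset()
  m <- train_rotation_net(man, man, ranges_catheter(),
                          rot_config(epochs = 1, width = 4, head_width = 16))
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  img <- load_split(man, "test")$images[[1]]
  expect_identical(predict_rotation(m, img)$angles,
                   predict_rotation(m2, img)$angles)
  expect_equal(m2$binnings[[1]]$n, 50L)
  expect_equal(m2$axes, "x")
})

test_that("zero-epoch fine-tune is the identity; label checks still apply", {
  man <- test_rot_dataset()
  m <- train_rotation_net(man, man, ranges_catheter(),
                          rot_config(epochs = 1, width = 4, head_width = 16))
  cfg0 <- m$config
  cfg0$epochs <- 0
  m0 <- fine_tune(m, man, cfg0)
  img <- load_split(man, "test")$images[[1]]
  expect_identical(predict_rotation(m, img)$angles,
                   predict_rotation(m0, img)$angles)

  bad <- man
  bad$rx[2] <- 99
  attr(bad, "dir") <- attr(man, "dir")
  expect_error(fine_tune(m, bad), "outside its range")
})

test_that("fine-tuning on domain-shifted frames improves shifted accuracy", {
  base_cfg <- scene_config_catheter(image_size = c(48, 48))
  shift_cfg <- scene_config_catheter(image_size = c(48, 48),
                                     domain_shift = TRUE)
  tr <- generate_dataset(160, config = base_cfg, seed = 21,
                         out_dir = tempfile())
  extra <- generate_dataset(100, config = shift_cfg, seed = 22,
                            out_dir = tempfile())
  test_sh <- generate_dataset(150, config = shift_cfg, seed = 23,
                              out_dir = tempfile())
  m <- train_rotation_net(tr, tr, ranges_catheter(),
                          rot_config(epochs = 12, width = 8, head_width = 64,
                                     seed = 0))
  before <- evaluate_rotation(m, load_split(test_sh))
  ft_cfg <- m$config
  ft_cfg$epochs <- 15
  ft_cfg$learning_rate <- m$config$learning_rate / 2
  mft <- fine_tune(m, load_split(extra), ft_cfg)
  after <- evaluate_rotation(mft, load_split(test_sh))
  expect_gt(after$accuracy[after$tol == 10], before$accuracy[before$tol == 10])
})
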