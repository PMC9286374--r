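test_that("toy training is seed-reproducible and beats the untrained model", {
  man <- test_seg_dataset()
  cfg <- seg_config(epochs = 3, width = 4, seed = 0)
  m1 <- train_segmenter(man, man, cfg)
  m2 <- train_segmenter(man, man, cfg)
  expect_equal(m1$best_val_miou, m2$best_val_miou)
  expect_equal(m1$log$loss, m2$log$loss)

  # training sanity: final val mIoU strictly above the untrained network's
  untrained <- train_segmenter(man, man, seg_config(epochs = 1,
                                                    learning_rate = 0,
                                                    width = 4, seed = 0))
  expect_gt(m1$best_val_miou, untrained$best_val_miou)
  expect_equal(nrow(m1$log), 3)
})

test_that("prediction is deterministic, full-size and resolution-checked", {
  man <- test_seg_dataset()
  m <- train_segmenter(man, man, seg_config(epochs = 1, width = 4, seed = 0))
  img <- load_split(man, "test")$images[[1]]
  p1 <- predict_mask(m, img)
  p2 <- predict_mask(m, img)
  expect_identical(p1, p2)
  expect_identical(dim(p1), dim(img)[1:2])
  expect_true(all(p1 %in% 0:2))
  expect_error(predict_mask(m, img[1:24, 1:24, , drop = FALSE]),
               "resolution mismatch")
})

test_that("training rejects mismatched and empty inputs", {
  man <- test_seg_dataset()
  tr <- load_split(man, "train")
  broken <- tr
  broken$masks[[1]] <- broken$masks[[1]][1:10, 1:10]
  expect_error(train_segmenter(broken, tr, seg_config(epochs = 1, width = 4)),
               "mismatch")
  empty <- list(images = list(), masks = list())
  expect_error(train_segmenter(empty, tr, seg_config(epochs = 1)), "empty")
})

test_that("checkpoints round-trip through save_model/load_model", {
  man <- test_seg_dataset()
  m <- train_segmenter(man, man, seg_config(epochs = 1, width = 4, seed = 0))
  f <- tempfile(fileext = ".json")
  save_model(m, f)
  m2 <- load_model(f)
  img <- load_split(man, "test")$images[[1]]
  expect_identical(predict_mask(m, img), predict_mask(m2, img))
  expect_equal(m2$arch$width, 4)
})
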