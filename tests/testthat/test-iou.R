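test_that("iou matches hand-counted oracles and flags empty unions", {
  a <- matrix(0L, 8, 8)
  b <- matrix(0L, 8, 8)
  a[2:3, 2:3] <- 2L
  b[2:3, 3:4] <- 2L          # overlap 2 px, union 6 px
  expect_equal(iou(a, b, 2), 1 / 3)
  expect_equal(iou(a, a, 2), 1)
  expect_equal(iou(b, a, 2), iou(a, b, 2))  # symmetry

  disj <- matrix(0L, 8, 8)
  disj[6:7, 6:7] <- 2L
  expect_equal(iou(a, disj, 2), 0)

  expect_true(is.na(iou(a, b, 1)))  # tool absent from both -> undefined
  expect_error(iou(a, matrix(0L, 4, 4), 2), "shape mismatch")
  expect_error(iou(a, b, 7), "unknown class")
})

test_that("iou is symmetric and exact over random masks (property)", {
  set.seed(1)
  for (i in 1:20) {
    a <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    b <- matrix(sample(0:2, 64, replace = TRUE), 8, 8)
    for (k in 0:2) {
      # brute-force pixel counter oracle
      inter <- 0; un <- 0
      for (p in 1:64) {
        pa <- a[p] == k; pb <- b[p] == k
        inter <- inter + (pa && pb)
        un <- un + (pa || pb)
      }
      want <- if (un == 0) NA_real_ else inter / un
      expect_equal(iou(a, b, k), want)
      expect_equal(iou(b, a, k), iou(a, b, k))
    }
  }
})

test_that("evaluate_segmentation pools intersections/unions over the set", {
  truth <- list(matrix(0L, 6, 6), matrix(0L, 6, 6))
  truth[[1]][1:2, 1:2] <- 2L
  truth[[2]][1:3, 1:3] <- 2L
  pred <- list(truth[[1]], matrix(0L, 6, 6))
  pred[[2]][1:3, 1:2] <- 2L   # 6 of 9 target px
  rep <- evaluate_segmentation(seg_oracle(pred),
                               list(images = as.list(1:2), masks = truth))
  # pooled target IoU = (4 + 6) / (4 + 9) = 10/13
  expect_equal(unname(rep$per_class["target"]), 10 / 13)
  expect_true(all(rep$per_image >= 0 & rep$per_image <= 1, na.rm = TRUE))
  expect_equal(rep$mean, mean(rep$per_class, na.rm = TRUE))

  # perfect predictions -> all ones
  rep1 <- evaluate_segmentation(seg_oracle(truth),
                                list(images = as.list(1:2), masks = truth))
  expect_true(all(rep1$per_class[c("background", "target")] == 1))
})
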