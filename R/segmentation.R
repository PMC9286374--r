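#' Training configuration for the segmentation network
#'
#' The architecture is an encoder-decoder with skip connections and a
#' residual-block encoder (two 2x downsamplings, channel widths
#' `width, 2*width, 4*width`). The `"desk"` profile is sized to train on one
#' CPU in minutes at 96 x 96; the `"paper"` profile keeps the reference
#' hyper-parameters (50 epochs, batch 4, Adam, learning rate 1e-4) with a
#' wider encoder.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param epochs,batch_size,learning_rate,width,seed overrides.
#' @param patience epochs without validation improvement before early stop.
#' @param verbose print per-epoch progress.
#' @return a `seg_config` list.
#' @export
seg_config <- function(profile = "desk", epochs = NULL, batch_size = 4,
                       learning_rate = 1e-4, width = NULL, seed = 0,
                       patience = Inf, verbose = FALSE) {
  profile <- match.arg(profile, c("desk", "paper"))
  if (is.null(width)) width <- if (profile == "desk") 8 else 32
  if (is.null(epochs)) epochs <- if (profile == "desk") 12 else 50
  structure(list(profile = profile, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, width = width, seed = seed,
                 patience = patience, verbose = verbose),
            class = "seg_config")
}

stack_images <- function(images) {
  d <- dim(images[[1]])
  arr <- array(0, dim = c(d[1], d[2], 3, length(images)))
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == d)) stop("image size mismatch")
    arr[, , , i] <- images[[i]] / 255
  }
  arr
}

stack_masks <- function(masks, d) {
  arr <- array(0L, dim = c(d[1], d[2], length(masks)))
  for (i in seq_along(masks)) {
    if (!all(dim(masks[[i]]) == d[1:2])) stop("image/mask size mismatch")
    arr[, , i] <- masks[[i]]
  }
  arr
}

#' Train the three-class segmentation network
#'
#' Minimises pixel-wise cross-entropy with Adam and returns the checkpoint
#' with the best validation mean IoU. Training is bit-reproducible for a
#' fixed seed. The per-epoch loss and validation IoU are kept in the model's
#' training log.
#'
#' @param train_set,val_set manifest `data.frame`s (with attribute `dir`) or
#'   lists with `images` and `masks`.
#' @param config a [seg_config()].
#' @return a `seg_model`.
#' @export
train_segmenter <- function(train_set, val_set, config = seg_config()) {
  if (is.data.frame(train_set)) train_set <- load_split(train_set, "train")
  if (is.data.frame(val_set)) val_set <- load_split(val_set, "val")
  if (length(train_set$images) == 0 || length(val_set$images) == 0)
    stop("empty dataset")
  d <- dim(train_set$images[[1]])
  x_tr <- stack_images(train_set$images)
  y_tr <- stack_masks(train_set$masks, d)
  x_va <- stack_images(val_set$images)

  ptr <- cpp_unet_create(3L, as.integer(config$width), 3L, as.integer(config$seed))
  n <- dim(x_tr)[4]
  bs <- config$batch_size
  log <- data.frame(epoch = integer(), loss = numeric(), val_miou = numeric())
  best <- -Inf
  best_w <- NULL
  stale <- 0

  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      nb <- 0
      for (s in seq(1, n, by = bs)) {
        idx <- ord[s:min(s + bs - 1, n)]
        loss <- cpp_unet_train_batch(ptr,
          x_tr[, , , idx, drop = FALSE],
          y_tr[, , idx, drop = FALSE],
          config$learning_rate, numeric(0))
        tot <- tot + loss
        nb <- nb + 1
      }
      vm <- pooled_miou(cpp_unet_predict(ptr, x_va), val_set$masks)
      log[nrow(log) + 1, ] <- list(ep, tot / nb, vm)
      if (config$verbose)
        message(sprintf("epoch %d  loss %.4f  val mIoU %.4f", ep, tot / nb, vm))
      if (vm > best) {
        best <- vm
        best_w <- cpp_unet_weights(ptr)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= config$patience) break
      }
    }
  })
  cpp_unet_set_weights(ptr, best_w)
  structure(list(ptr = ptr,
                 arch = list(kind = "unet", in_ch = 3L, width = config$width,
                             n_classes = 3L, input_size = d[1:2]),
                 config = config, log = log, best_val_miou = best),
            class = "seg_model")
}

# pooled mean IoU of predicted mask stack vs list of truth masks
pooled_miou <- function(pred_arr, truths) {
  inter <- un <- numeric(3)
  for (i in seq_along(truths)) {
    pred <- pred_arr[, , i]
    truth <- truths[[i]]
    for (k in 0:2) {
      p <- pred == k
      t <- truth == k
      inter[k + 1] <- inter[k + 1] + sum(p & t)
      un[k + 1] <- un[k + 1] + sum(p | t)
    }
  }
  mean(ifelse(un > 0, inter / un, NA_real_), na.rm = TRUE)
}

#' Predict a label mask for one frame
#'
#' Argmax over the per-class scores; deterministic at inference.
#'
#' @param model a `seg_model` or `seg_oracle`.
#' @param image `H x W x 3` integer array (0-255) at the trained resolution.
#' @param frame frame index, used by the oracle model.
#' @return integer label mask.
#' @export
predict_mask <- function(model, image, frame = NULL) UseMethod("predict_mask")

#' @export
predict_mask.seg_model <- function(model, image, frame = NULL) {
  d <- dim(image)
  if (!all(d[1:2] == model$arch$input_size)) stop("resolution mismatch")
  arr <- array(image / 255, dim = c(d[1], d[2], 3, 1))
  cpp_unet_predict(model$ptr, arr)[, , 1]
}

#' Oracle segmentation model backed by ground-truth masks
#'
#' Stands in for a trained `seg_model` in pipeline tests: `predict_mask`
#' returns the stored ground-truth mask for the requested frame.
#'
#' @param masks list of ground-truth masks.
#' @return a `seg_oracle`.
#' @export
seg_oracle <- function(masks) structure(list(masks = masks), class = "seg_oracle")

#' @export
predict_mask.seg_oracle <- function(model, image, frame = NULL) {
  if (is.null(frame)) stop("seg_oracle needs a frame index")
  model$masks[[frame]]
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("seg_model: width %d, input %dx%d, best val mIoU %.4f (%d epochs)\n",
              x$arch$width, x$arch$input_size[1], x$arch$input_size[2],
              x$best_val_miou, nrow(x$log)))
  invisible(x)
}

#' Save or load a model checkpoint
#'
#' Checkpoints are JSON files embedding the architecture descriptor, the
#' training log and all weights.
#'
#' @param model a `seg_model` or `rot_model`.
#' @param path checkpoint path.
#' @return `load_model` returns the restored model.
#' @export
save_model <- function(model, path) {
  extra <- model[setdiff(names(model), c("ptr", "arch", "log", "config"))]
  if (!is.null(extra$binnings))
    extra$binnings <- lapply(extra$binnings, unclass)
  obj <- list(format = 1L, arch = model$arch, log = model$log,
              config = unclass(model$config),
              extra = extra,
              weights = lapply(if (model$arch$kind == "unet")
                                 cpp_unet_weights(model$ptr)
                               else cpp_rotnet_weights(model$ptr),
                               function(w) list(dim = dim(w), v = as.numeric(w))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = 9)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  arch <- obj$arch
  w <- lapply(seq_len(nrow(obj$weights)), function(i) {
    array(obj$weights$v[[i]], dim = obj$weights$dim[[i]])
  })
  if (arch$kind == "unet") {
    ptr <- cpp_unet_create(arch$in_ch, arch$width, arch$n_classes, 0L)
    cpp_unet_set_weights(ptr, w)
    out <- c(list(ptr = ptr, arch = arch, log = obj$log, config = obj$config),
             obj$extra)
    class(out) <- "seg_model"
  } else {
    ptr <- cpp_rotnet_create(arch$in_ch, arch$width, arch$head_width,
                             as.integer(arch$n_classes),
                             arch$input_size[1], arch$input_size[2],
                             arch$dropout, 0L)
    cpp_rotnet_set_weights(ptr, w)
    out <- c(list(ptr = ptr, arch = arch, log = obj$log, config = obj$config),
             obj$extra)
    bs <- out$binnings
    out$binnings <- if (is.data.frame(bs)) {
      lapply(seq_len(nrow(bs)), function(i) make_binning(bs$lo[i], bs$hi[i], bs$w[i]))
    } else {
      lapply(bs, function(b) make_binning(b$lo, b$hi, b$w))
    }
    class(out) <- "rot_model"
  }
  out
}
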