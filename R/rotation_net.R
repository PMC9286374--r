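#' Discretise a rotation range into angle classes
#'
#' The range `[lo, hi)` is split into `N = ceiling((hi - lo) / w)` half-open
#' bins of width `w`; class `k` covers `[lo + k w, lo + (k+1) w)` and decodes
#' to its centre `lo + (k + 0.5) w`. Encoding then decoding any angle in the
#' range moves it by at most `w / 2`.
#'
#' @param lo,hi range in degrees (`lo < hi`).
#' @param w bin width in degrees (default 1).
#' @return an `angle_binning` with fields `lo, hi, w, n`.
#' @examples
#' b <- make_binning(-40, 10)   # 50 classes, 1-degree bins
#' decode_angle(b, encode_angle(b, -12.3))
#' @export
make_binning <- function(lo, hi, w = 1) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) stop("invalid range")
  if (!is.finite(w) || w <= 0) stop("invalid bin width")
  structure(list(lo = lo, hi = hi, w = w, n = as.integer(ceiling((hi - lo) / w))),
            class = "angle_binning")
}

#' @rdname make_binning
#' @param binning an `angle_binning`.
#' @param a angle(s) in degrees.
#' @export
encode_angle <- function(binning, a) {
  k <- floor((a - binning$lo) / binning$w)
  as.integer(clamp(k, 0, binning$n - 1))
}

#' @rdname make_binning
#' @param k 0-based class index (or vector).
#' @export
decode_angle <- function(binning, k) binning$lo + (k + 0.5) * binning$w

#' Training configuration for the rotation classifier
#'
#' The network is a shared residual convolutional backbone with one branch
#' per predicted axis; each branch is dense -> batch normalisation ->
#' dropout -> dense(N) -> softmax. The `"paper"` profile keeps the reference
#' constants (4096-unit branch dense layer, batch 32, Adam, learning rate
#' 1e-5, ~15 epochs, 50-layer-class backbone width); the `"desk"` profile is
#' a shallow variant that trains from scratch on one CPU in minutes.
#'
#' @param profile `"desk"` or `"paper"`.
#' @param epochs,batch_size,learning_rate,width,head_width,dropout,seed
#'   overrides; `width` is the backbone base channel count.
#' @param bin_width angle bin width in degrees.
#' @param patience early-stop patience on validation accuracy.
#' @param verbose print per-epoch progress.
#' @return a `rot_config`.
#' @export
rot_config <- function(profile = "desk", epochs = NULL, batch_size = 32,
                       learning_rate = NULL, width = NULL, head_width = NULL,
                       dropout = 0.5, bin_width = 1, lr_decay = NULL,
                       label_sigma = NULL, augment_shift = NULL, seed = 0,
                       patience = Inf, verbose = FALSE) {
  profile <- match.arg(profile, c("desk", "paper"))
  if (is.null(width)) width <- if (profile == "desk") 16 else 32
  if (is.null(head_width)) head_width <- if (profile == "desk") 512 else 4096
  if (is.null(learning_rate)) learning_rate <- if (profile == "desk") 1e-3 else 1e-5
  if (is.null(epochs)) epochs <- if (profile == "desk") 30 else 15
  if (is.null(lr_decay)) lr_decay <- if (profile == "desk") 0.93 else 1
  if (is.null(label_sigma)) label_sigma <- if (profile == "desk") 1.5 else 0
  if (is.null(augment_shift)) augment_shift <- if (profile == "desk") 3L else 0L
  structure(list(profile = profile, epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, width = width,
                 head_width = head_width, dropout = dropout,
                 bin_width = bin_width, lr_decay = lr_decay,
                 label_sigma = label_sigma, augment_shift = augment_shift,
                 seed = seed, patience = patience, verbose = verbose),
            class = "rot_config")
}

# random integer translations (edge-replicated); rotation labels are
# translation-invariant, so this augments without relabelling
shift_augment <- function(xb, s) {
  d <- dim(xb)
  for (j in seq_len(d[4])) {
    dy <- sample(-s:s, 1)
    dx <- sample(-s:s, 1)
    if (dy == 0 && dx == 0) next
    rows <- clamp(seq_len(d[1]) - dy, 1, d[1])
    cols <- clamp(seq_len(d[2]) - dx, 1, d[2])
    xb[, , , j] <- xb[rows, cols, , j]
  }
  xb
}

rot_labels <- function(set, axes, binnings) {
  lab <- matrix(0L, length(set$images), length(axes))
  for (j in seq_along(axes)) {
    vals <- set$labels[[paste0("r", axes[j])]]
    b <- binnings[[j]]
    if (any(vals < b$lo | vals > b$hi)) stop("rotation label outside its range")
    lab[, j] <- encode_angle(b, vals)
  }
  lab
}

#' Train the multi-branch rotation classifier
#'
#' One classification head per axis declared as a numeric range in `ranges`;
#' per-axis cross-entropy on the encoded classes is summed over heads. The
#' checkpoint with the best validation tolerance accuracy (+/-5 degrees,
#' averaged over axes) is returned. Bit-reproducible for a fixed seed.
#'
#' @param train_set,val_set manifests (attribute `dir`) or `load_split()`
#'   lists with `images` and `labels`.
#' @param ranges a [rotation_ranges()]; exactly the numeric-range axes get a
#'   prediction head.
#' @param config a [rot_config()].
#' @return a `rot_model`.
#' @export
train_rotation_net <- function(train_set, val_set, ranges,
                               config = rot_config()) {
  if (is.data.frame(train_set)) train_set <- load_split(train_set, "train")
  if (is.data.frame(val_set)) val_set <- load_split(val_set, "val")
  if (length(train_set$images) == 0 || length(val_set$images) == 0)
    stop("empty dataset")
  axes <- range_axes(ranges)
  if (length(axes) == 0) stop("no range axis to predict")
  binnings <- lapply(axes, function(ax) {
    e <- ranges[[ax]]
    make_binning(e[1], e[2], config$bin_width)
  })
  d <- dim(train_set$images[[1]])
  x_tr <- stack_images(train_set$images)
  y_tr <- rot_labels(train_set, axes, binnings)
  x_va <- stack_images(val_set$images)
  truth_va <- as.matrix(val_set$labels[paste0("r", axes)])

  ptr <- cpp_rotnet_create(3L, as.integer(config$width),
                           as.integer(config$head_width),
                           vapply(binnings, function(b) b$n, integer(1)),
                           d[1], d[2], config$dropout, as.integer(config$seed))
  n <- dim(x_tr)[4]
  bs <- config$batch_size
  log <- data.frame(epoch = integer(), loss = numeric(), val_acc5 = numeric())
  best <- -Inf
  best_acc5 <- NA_real_
  best_w <- NULL
  stale <- 0
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      tot <- 0
      nb <- 0
      lr_ep <- config$learning_rate * (config$lr_decay %||% 1)^(ep - 1)
      for (s in seq(1, n, by = bs)) {
        idx <- ord[s:min(s + bs - 1, n)]
        xb <- x_tr[, , , idx, drop = FALSE]
        if (config$augment_shift > 0) xb <- shift_augment(xb, config$augment_shift)
        loss <- cpp_rotnet_train_batch(ptr, xb, y_tr[idx, , drop = FALSE],
                                       lr_ep, config$label_sigma)
        tot <- tot + loss
        nb <- nb + 1
      }
      dec <- decode_rotnet(ptr, x_va, binnings)
      acc <- mean(vapply(seq_along(axes), function(j) {
        tolerance_accuracy(dec[, j], truth_va[, j], 5)
      }, numeric(1)))
      # fine-band accuracy breaks ties once the 5-degree band saturates
      acc1 <- mean(vapply(seq_along(axes), function(j) {
        tolerance_accuracy(dec[, j], truth_va[, j], 1)
      }, numeric(1)))
      score <- acc + 0.01 * acc1
      log[nrow(log) + 1, ] <- list(ep, tot / nb, acc)
      if (config$verbose)
        message(sprintf("epoch %d  loss %.4f  val acc(5) %.4f acc(1) %.4f",
                        ep, tot / nb, acc, acc1))
      if (score > best) {
        best <- score
        best_acc5 <- acc
        best_w <- cpp_rotnet_weights(ptr)
        stale <- 0
      } else {
        stale <- stale + 1
        if (stale >= config$patience) break
      }
    }
  })
  cpp_rotnet_set_weights(ptr, best_w)
  structure(list(ptr = ptr,
                 arch = list(kind = "rotnet", in_ch = 3L, width = config$width,
                             head_width = config$head_width,
                             n_classes = vapply(binnings, function(b) b$n, integer(1)),
                             input_size = d[1:2], dropout = config$dropout),
                 axes = axes, binnings = binnings, config = config, log = log,
                 best_val_acc5 = best_acc5),
            class = "rot_model")
}

decode_rotnet <- function(ptr, x, binnings) {
  probs <- cpp_rotnet_predict(ptr, x)
  out <- matrix(0, dim(x)[4], length(binnings))
  for (j in seq_along(binnings)) {
    k <- max.col(probs[[j]], ties.method = "first") - 1L
    out[, j] <- decode_angle(binnings[[j]], k)
  }
  out
}

#' Predict per-axis rotation for one frame
#'
#' Softmax over each head; the decoded angle is the centre of the argmax bin
#' (ties broken toward the lower class index).
#'
#' @param model a `rot_model`.
#' @param image `H x W x 3` integer array (0-255) at the trained resolution.
#' @return a `rotation_prediction`: list with `angles` (named by axis) and
#'   `probs` (list of per-axis class probabilities).
#' @export
predict_rotation <- function(model, image) {
  d <- dim(image)
  if (!all(d[1:2] == model$arch$input_size)) stop("resolution mismatch")
  arr <- array(image / 255, dim = c(d[1], d[2], 3, 1))
  probs <- cpp_rotnet_predict(model$ptr, arr)
  angles <- numeric(length(model$axes))
  names(angles) <- model$axes
  pl <- list()
  for (j in seq_along(model$axes)) {
    p <- probs[[j]][1, ]
    k <- which.max(p) - 1L
    angles[j] <- decode_angle(model$binnings[[j]], k)
    pl[[model$axes[j]]] <- p
  }
  structure(list(angles = angles, probs = pl), class = "rotation_prediction")
}

#' Fraction of predictions within an angular tolerance band
#'
#' @param predicted,truth equal-length vectors of degrees.
#' @param tol tolerance in degrees (>= 0).
#' @return fraction in `[0, 1]`.
#' @examples
#' tolerance_accuracy(c(0, 7, -3), c(0, 0, 0), 5) # 2/3
#' @export
tolerance_accuracy <- function(predicted, truth, tol) {
  if (length(predicted) != length(truth)) stop("length mismatch")
  if (tol < 0) stop("tol must be >= 0")
  mean(abs(predicted - truth) <= tol)
}

#' Evaluate a rotation model on a test set
#'
#' @param model a `rot_model`.
#' @param test_set manifest or `load_split()` list.
#' @param tolerances tolerance bands in degrees.
#' @param report_csv optional CSV path (columns axis, tol, accuracy).
#' @return data.frame of per-axis accuracies.
#' @export
evaluate_rotation <- function(model, test_set, tolerances = c(5, 10),
                              report_csv = NULL) {
  if (is.data.frame(test_set)) test_set <- load_split(test_set)
  x <- stack_images(test_set$images)
  dec <- decode_rotnet(model$ptr, x, model$binnings)
  truth <- as.matrix(test_set$labels[paste0("r", model$axes)])
  out <- expand.grid(axis = model$axes, tol = tolerances,
                     stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(ax, tol) {
    j <- match(ax, model$axes)
    tolerance_accuracy(dec[, j], truth[, j], tol)
  }, out$axis, out$tol)
  if (!is.null(report_csv)) write.csv(out, report_csv, row.names = FALSE)
  out
}

#' Continue training a rotation model on extra data
#'
#' Clones the model and continues optimisation at a reduced learning rate
#' (default one tenth of the original), e.g. on the simulator's
#' domain-shifted variant emulating real intraoperative frames. Zero epochs
#' return an identical copy.
#'
#' @param model a trained `rot_model`.
#' @param extra_set manifest or `load_split()` list; labels must lie within
#'   the model's ranges.
#' @param config optional [rot_config()]; defaults to the model's with
#'   `learning_rate / 10` and 5 epochs.
#' @return a new `rot_model`.
#' @export
fine_tune <- function(model, extra_set, config = NULL) {
  if (is.data.frame(extra_set)) extra_set <- load_split(extra_set)
  base <- model$config
  if (is.null(config)) {
    config <- base
    config$learning_rate <- base$learning_rate / 10
    config$epochs <- 5
  }
  ptr <- cpp_rotnet_create(3L, as.integer(model$arch$width),
                           as.integer(model$arch$head_width),
                           as.integer(model$arch$n_classes),
                           model$arch$input_size[1], model$arch$input_size[2],
                           model$arch$dropout, as.integer(config$seed))
  cpp_rotnet_set_weights(ptr, cpp_rotnet_weights(model$ptr))
  new <- model
  new$ptr <- ptr
  new$config <- config
  if (config$epochs == 0) return(new)
  x <- stack_images(extra_set$images)
  y <- rot_labels(extra_set, model$axes, model$binnings)
  n <- dim(x)[4]
  with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (s in seq(1, n, by = config$batch_size)) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        xb <- x[, , , idx, drop = FALSE]
        if ((config$augment_shift %||% 0) > 0)
          xb <- shift_augment(xb, config$augment_shift)
        cpp_rotnet_train_batch(ptr, xb, y[idx, , drop = FALSE],
                               config$learning_rate,
                               config$label_sigma %||% 0)
      }
    }
  })
  new
}

#' @export
print.rot_model <- function(x, ...) {
  cat(sprintf("rot_model: axes [%s], width %d, head %d, best val acc(5) %.4f\n",
              paste(x$axes, collapse = ","), x$arch$width, x$arch$head_width,
              x$best_val_acc5))
  invisible(x)
}
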