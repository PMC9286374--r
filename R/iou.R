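#' Intersection-over-Union for one class
#'
#' `|pred ∩ truth| / |pred ∪ truth|` over pixels of `class_id`. If the union
#' is empty (class absent from both masks) the score is undefined and
#' `NA_real_` is returned; such entries are excluded from means rather than
#' scored 0, so frames without tools do not penalise the tool class.
#'
#' @param pred,truth integer label masks of equal shape.
#' @param class_id class ID (0 background, 1 tool, 2 target).
#' @return score in `[0, 1]`, or `NA_real_` when undefined.
#' @examples
#' a <- matrix(0L, 8, 8); a[2:3, 2:3] <- 2L
#' b <- matrix(0L, 8, 8); b[2:3, 3:4] <- 2L
#' iou(a, b, 2) # 2 / 6
#' @export
iou <- function(pred, truth, class_id) {
  if (!all(dim(pred) == dim(truth))) stop("mask shape mismatch")
  if (!class_id %in% 0:2) stop("unknown class: ", class_id)
  p <- pred == class_id
  t <- truth == class_id
  u <- sum(p | t)
  if (u == 0) return(NA_real_)
  sum(p & t) / u
}

#' Evaluate a segmentation model over a test set
#'
#' Predicts a mask for every image and reports per-class and mean IoU. The
#' headline per-class scores are pooled over the whole set (summed
#' intersections over summed unions); per-image scores are kept alongside.
#' Classes absent from both prediction and truth on every frame are reported
#' as `NA` and excluded from the mean.
#'
#' @param model a `seg_model` (or any object with a [predict_mask()] method).
#' @param test_set list with `images` and `masks` (as from `load_split()`), or
#'   a manifest `data.frame` with attribute `dir`.
#' @param report_csv optional path for a CSV report.
#' @return an `iou_report`: list with `per_class` (named numeric), `mean`,
#'   and `per_image` (data.frame).
#' @export
evaluate_segmentation <- function(model, test_set, report_csv = NULL) {
  if (is.data.frame(test_set)) test_set <- load_split(test_set)
  n <- length(test_set$images)
  if (n == 0) stop("empty test set")
  inter <- un <- numeric(3)
  per_image <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("background", "tool", "target")))
  for (i in seq_len(n)) {
    pred <- predict_mask(model, test_set$images[[i]], frame = i)
    truth <- test_set$masks[[i]]
    for (k in 0:2) {
      p <- pred == k
      t <- truth == k
      inter[k + 1] <- inter[k + 1] + sum(p & t)
      un[k + 1] <- un[k + 1] + sum(p | t)
      if (sum(p | t) > 0) per_image[i, k + 1] <- sum(p & t) / sum(p | t)
    }
  }
  per_class <- ifelse(un > 0, inter / un, NA_real_)
  names(per_class) <- c("background", "tool", "target")
  rep <- structure(list(per_class = per_class,
                        mean = mean(per_class, na.rm = TRUE),
                        per_image = as.data.frame(per_image),
                        pooled = TRUE),
                   class = "iou_report")
  if (!is.null(report_csv)) {
    write.csv(data.frame(class = c(names(per_class), "mean"),
                         iou = c(per_class, rep$mean)),
              report_csv, row.names = FALSE)
  }
  rep
}

#' @export
print.iou_report <- function(x, ...) {
  cat("IoU report (pooled over test set)\n")
  for (k in names(x$per_class))
    cat(sprintf("  %-10s %.4f\n", k, x$per_class[k]))
  cat(sprintf("  %-10s %.4f\n", "mean", x$mean))
  invisible(x)
}
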