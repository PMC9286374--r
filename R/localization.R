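#' Largest connected region of a class in a label mask
#'
#' Extracts the largest 8-connected component of `class_id` pixels. Ties are
#' broken in favour of the component whose first pixel comes earliest in
#' row-major (reading) order.
#'
#' @param mask integer label mask.
#' @param class_id class to extract (default 2, the target).
#' @return logical matrix marking the region.
#' @export
largest_target_region <- function(mask, class_id = 2L) {
  lab <- cpp_label_components(mask, as.integer(class_id))
  if (max(lab) == 0) stop("target-not-found")
  sizes <- tabulate(lab[lab > 0])
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    # labels are assigned in row-major discovery order, but R matrices are
    # column-major; resolve the tie by explicit row-major first-pixel scan
    first_rm <- vapply(best, function(l) {
      idx <- which(lab == l)
      r <- (idx - 1) %% nrow(lab)
      c2 <- (idx - 1) %/% nrow(lab)
      min(r * ncol(lab) + c2)
    }, numeric(1))
    best <- best[which.min(first_rm)]
  }
  lab == best
}

#' Moment-equivalent ellipse of a binary region
#'
#' Fits the ellipse with the same zeroth, first and second central moments as
#' the region: centre = centroid, axis lengths `4 * sqrt(eigenvalues)` of the
#' second-central-moment matrix, orientation
#' `theta = 0.5 * atan2(2 mu11, mu20 - mu02)` in degrees. Coordinates are
#' 0-based pixel centres (x = column, y = row, y downward); `theta` is
#' measured from the +x axis toward +y and lies in (-90, 90]. Isotropic
#' regions report `theta = 0` by tie-break.
#'
#' @param region logical (or 0/1) matrix.
#' @return an `ellipse_fit`: list with `cx, cy, major, minor, theta, area_px`.
#' @examples
#' reg <- matrix(FALSE, 32, 32); reg[10:20, 8:28] <- TRUE
#' fit_ellipse(reg)
#' @export
fit_ellipse <- function(region) {
  idx <- which(region != 0)
  if (length(idx) < 5) stop("region must have at least 5 pixels")
  H <- nrow(region)
  y <- (idx - 1) %% H
  x <- (idx - 1) %/% H
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2)
  mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  tr <- mu20 + mu02
  dd <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- tr / 2 + dd
  l2 <- max(tr / 2 - dd, 0)
  iso <- dd < 1e-9 * max(tr, 1e-12)
  theta <- if (iso) 0 else rad2deg(0.5 * atan2(2 * mu11, mu20 - mu02))
  if (theta <= -90) theta <- theta + 180
  if (theta > 90) theta <- theta - 180
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  if (minor < 1) {
    warning("degenerate region; minor axis floored at 1 px")
    minor <- 1
  }
  structure(list(cx = cx, cy = cy, major = major, minor = minor,
                 theta = theta, area_px = length(idx)),
            class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat(sprintf("ellipse_fit: centre (%.1f, %.1f), axes %.1f x %.1f px, theta %.1f deg\n",
              x$cx, x$cy, x$major, x$minor, x$theta))
  invisible(x)
}

#' Target position from an ellipse fit
#'
#' The ellipse centre is taken as the image-plane anchor for the 3D model's
#' centre of mass.
#'
#' @param fit an `ellipse_fit`.
#' @return `c(tx, ty)` in pixels.
#' @export
estimate_position <- function(fit) c(tx = fit$cx, ty = fit$cy)

#' Scale reference for a registered frame
#'
#' @param area reference ellipse area in pixels^2 (`pi * major/2 * minor/2`).
#' @param scale scale factor of the reference frame (default 1).
#' @return a `scale_reference`.
#' @export
scale_reference <- function(area, scale = 1) {
  if (!is.finite(area) || area <= 0) stop("reference area must be > 0")
  structure(list(area = area, scale = scale), class = "scale_reference")
}

#' @rdname scale_reference
#' @param fit an `ellipse_fit` taken on the registration frame.
#' @export
scale_reference_from_fit <- function(fit, scale = 1) {
  scale_reference(pi * (fit$major / 2) * (fit$minor / 2), scale)
}

#' Scale factor from ellipse area
#'
#' Projected linear size is proportional to `scale`, so silhouette area goes
#' with `scale^2`; the estimate is `sqrt(area / reference area)` times the
#' reference scale.
#'
#' @param fit an `ellipse_fit`.
#' @param ref a [scale_reference()].
#' @return scale estimate.
#' @export
estimate_scale <- function(fit, ref) {
  area <- pi * (fit$major / 2) * (fit$minor / 2)
  sqrt(area / ref$area) * ref$scale
}

#' In-plane rotation of an elongated target from its ellipse fit
#'
#' For rigid elongated targets (the catheter) the major-axis angle of the mask
#' ellipse tracks the target's in-plane orientation; a per-target calibration
#' (sign and offset, fixed once on a registered frame) maps it to the reported
#' Y-axis rotation. Near-circular silhouettes are rejected: below the
#' elongation gate the axis direction is ambiguous.
#'
#' @param fit an `ellipse_fit`.
#' @param calibration list with `sign` (+1/-1) and `offset` (degrees).
#' @param gate minimum major/minor elongation (default 1.2).
#' @return rotation in degrees, wrapped to (-90, 90].
#' @export
mask_y_rotation <- function(fit, calibration = list(sign = 1, offset = 0),
                            gate = 1.2) {
  if (fit$major / fit$minor < gate) stop("axis-ambiguous")
  v <- calibration$sign * fit$theta + calibration$offset
  v <- ((v + 90) %% 180) - 90
  if (v == -90) v <- 90
  v
}
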