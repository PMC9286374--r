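#' Rigid 6D pose of the target in a frame
#'
#' A pose bundles the image-plane centre of the target (`tx`, `ty`, pixels,
#' origin at the top-left pixel centre, x rightward, y downward), a
#' dimensionless scale factor (1 = the reference camera distance; projected
#' linear size is proportional to `scale`), and three rotations in degrees.
#' Rotations are intrinsic, applied in X then Y then Z order about the model's
#' own axes (rotation matrix `Rx %*% Ry %*% Rz`); the camera looks along -Z.
#'
#' @param tx,ty image-plane centre, pixels.
#' @param scale positive scale factor.
#' @param rx,ry,rz rotations about the model X, Y, Z axes, degrees.
#' @return an object of class `pose6d`.
#' @examples
#' pose6d(48, 48, 1, rx = -20)
#' @export
pose6d <- function(tx = 0, ty = 0, scale = 1, rx = 0, ry = 0, rz = 0) {
  stopifnot(is.finite(c(tx, ty, scale, rx, ry, rz)))
  if (scale <= 0) stop("scale must be > 0")
  structure(list(tx = tx, ty = ty, scale = scale, rx = rx, ry = ry, rz = rz),
            class = "pose6d")
}

#' @export
print.pose6d <- function(x, ...) {
  cat(sprintf("pose6d: t=(%.1f, %.1f) px  scale=%.3f  r=(%.1f, %.1f, %.1f) deg\n",
              x$tx, x$ty, x$scale, x$rx, x$ry, x$rz))
  invisible(x)
}

rot_x <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rot_y <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rot_z <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Rotation matrix for intrinsic X-Y-Z rotations
#'
#' @param rx,ry,rz rotations in degrees.
#' @return 3x3 rotation matrix `Rx %*% Ry %*% Rz`.
#' @export
pose_rotation <- function(rx, ry, rz) rot_x(rx) %*% rot_y(ry) %*% rot_z(rz)

#' Per-axis rotation range specification
#'
#' Each axis is either a numeric range `c(lo, hi)` in degrees (the axis is a
#' label predicted by the rotation network), the string `"mask-derived"` (the
#' axis is recovered from the segmentation mask, e.g. the catheter's in-plane
#' angle), or `"irrelevant"` (rotational symmetry makes the axis unobservable).
#'
#' @param x,y,z per-axis entries.
#' @return an object of class `rotation_ranges`.
#' @examples
#' rotation_ranges(x = c(-40, 10), y = "mask-derived", z = "irrelevant")
#' @export
rotation_ranges <- function(x = c(-10, 10), y = c(-10, 10), z = c(-10, 10)) {
  spec <- list(x = x, y = y, z = z)
  for (ax in names(spec)) {
    e <- spec[[ax]]
    if (is.character(e)) {
      if (!e %in% c("mask-derived", "irrelevant"))
        stop("unknown axis entry: ", e)
    } else {
      if (length(e) != 2 || !is.numeric(e) || e[1] >= e[2])
        stop("range entry for axis ", ax, " must be c(lo, hi) with lo < hi")
    }
  }
  structure(spec, class = "rotation_ranges")
}

#' @rdname rotation_ranges
#' @export
ranges_catheter <- function() {
  rotation_ranges(x = c(-40, 10), y = "mask-derived", z = "irrelevant")
}

#' @rdname rotation_ranges
#' @export
ranges_prostate <- function() {
  rotation_ranges(x = c(-15, 20), y = c(-25, 25), z = c(-5, 15))
}

#' @rdname rotation_ranges
#' @export
ranges_kidney <- function() {
  rotation_ranges(x = c(-10, 10), y = c(-10, 10), z = c(-10, 10))
}

# axes predicted by the rotation network (those given as numeric ranges)
range_axes <- function(ranges) {
  names(ranges)[vapply(ranges, is.numeric, logical(1))]
}
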