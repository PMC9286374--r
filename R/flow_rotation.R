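#' Dense optical flow between two frames
#'
#' Coarse-to-fine iterative Lucas-Kanade flow on the grayscale images.
#' Returns per-pixel displacements mapping the first frame onto the second,
#' plus derived magnitude and direction fields.
#'
#' @param frame_prev,frame_next `H x W x 3` integer arrays (0-255) or
#'   grayscale matrices in `[0, 1]`, equal sizes.
#' @param levels,iters,radius,lambda estimator parameters: pyramid levels,
#'   iterations per level, integration window radius (pixels), Tikhonov
#'   regulariser on the structure tensor.
#' @return a `flow_field`: list with matrices `du`, `dv`, `magnitude`,
#'   `direction` (radians).
#' @export
dense_flow <- function(frame_prev, frame_next, levels = 3, iters = 3,
                       radius = 4, lambda = 1e-4) {
  g1 <- if (length(dim(frame_prev)) == 3) to_gray(frame_prev) else frame_prev
  g2 <- if (length(dim(frame_next)) == 3) to_gray(frame_next) else frame_next
  if (!all(dim(g1) == dim(g2))) stop("frame size mismatch")
  fl <- cpp_lk_flow(g1, g2, levels, iters, radius, lambda)
  structure(list(du = fl$du, dv = fl$dv,
                 magnitude = sqrt(fl$du^2 + fl$dv^2),
                 direction = atan2(fl$dv, fl$du)),
            class = "flow_field")
}

#' Restrict a flow field to target pixels
#'
#' Keeps flow vectors at pixels labelled target (class 2) in both frames'
#' masks (their intersection), so limb pixels that appear/disappear with the
#' motion are excluded.
#'
#' @param flow a [dense_flow()] `flow_field`.
#' @param mask label mask of the first frame.
#' @param mask_next optional label mask of the second frame.
#' @return a `masked_flow`: list with pixel coordinates `x`, `y` (0-based),
#'   displacements `du`, `dv`, and `n`.
#' @export
masked_flow <- function(flow, mask, mask_next = NULL) {
  if (!all(dim(mask) == dim(flow$du))) stop("mask/flow shape mismatch")
  sel <- mask == 2L
  if (!is.null(mask_next)) sel <- sel & (mask_next == 2L)
  idx <- which(sel)
  if (length(idx) == 0) stop("no-target-flow")
  H <- nrow(mask)
  structure(list(x = (idx - 1) %/% H, y = (idx - 1) %% H,
                 du = flow$du[idx], dv = flow$dv[idx], n = length(idx)),
            class = "masked_flow")
}

#' Affine decomposition of masked target flow
#'
#' Least-squares fit of `d(p) = A (p - c) + t` over the target pixels, with
#' `c` the ellipse centre. The fit splits into curl
#' `omega = (A21 - A12) / 2` (in-plane rotation, radians/frame), divergence
#' `s = (A11 + A22) / 2` (approach/recede scaling), and residual slip
#' `r = t - dc`: the motion of the surface texture at the centre relative to
#' the silhouette centre displacement `dc`, the signature of out-of-plane
#' rotation.
#'
#' @param mflow a [masked_flow()].
#' @param fit ellipse fit of the first frame's target region.
#' @param fit_next ellipse fit of the second frame's region (defaults to
#'   `fit`, i.e. a stationary silhouette).
#' @return a `motion_decomposition`: list with `A` (2x2), `t`, `omega`, `s`,
#'   `r`, `center`.
#' @export
decompose_motion <- function(mflow, fit, fit_next = fit) {
  if (mflow$n < 20) stop("need at least 20 masked pixels")
  X <- mflow$x - fit$cx
  Y <- mflow$y - fit$cy
  M <- cbind(X, Y, 1)
  qrm <- qr(M)
  if (qrm$rank < 3) stop("rank-deficient fit (collinear pixels)")
  cu <- unname(qr.coef(qrm, mflow$du))
  cv <- unname(qr.coef(qrm, mflow$dv))
  A <- rbind(c(cu[1], cu[2]), c(cv[1], cv[2]))
  t <- c(cu[3], cv[3])
  dc <- c(fit_next$cx - fit$cx, fit_next$cy - fit$cy)
  structure(list(A = A, t = t,
                 omega = (A[2, 1] - A[1, 2]) / 2,
                 s = (A[1, 1] + A[2, 2]) / 2,
                 r = t - dc, center = c(fit$cx, fit$cy)),
            class = "motion_decomposition")
}

#' Rotation increments from a motion decomposition
#'
#' The curl maps to the Z increment (`-omega` in degrees, the sign fixed by
#' the simulator's y-down image convention); horizontal residual slip maps to
#' Y and vertical slip to X through the calibration constants (degrees per
#' pixel of slip). Components whose slip magnitude is below the dead-band are
#' zeroed to suppress flow noise on static scenes.
#'
#' @param decomp a [decompose_motion()] result.
#' @param calib list with positive `kx`, `ky` (degrees/pixel).
#' @param deadband slip dead-band in pixels (default 0.05); the curl term
#'   uses the equivalent rim displacement `|omega| * major/2`.
#' @param semi_major ellipse semi-major axis (pixels) for the curl dead-band;
#'   default 20.
#' @return named vector `c(drx, dry, drz)` in degrees.
#' @export
flow_to_rotation <- function(decomp, calib, deadband = 0.05, semi_major = 20) {
  if (calib$kx <= 0 || calib$ky <= 0) stop("calibration constants must be > 0")
  drz <- -rad2deg(decomp$omega)
  if (abs(decomp$omega) * semi_major < deadband) drz <- 0
  dry <- if (abs(decomp$r[1]) < deadband) 0 else calib$ky * decomp$r[1]
  drx <- if (abs(decomp$r[2]) < deadband) 0 else calib$kx * decomp$r[2]
  c(drx = drx, dry = dry, drz = drz)
}

# One frame pair -> decomposition (shared by calibrate/track). The dense-flow
# affine fit seeds a parametric Gauss-Newton refinement of the same affine
# model directly on brightness constancy over the target pixels, which
# recovers sub-pixel curl/slip far more accurately than the pixel-wise flow.
# binary erosion (4-neighbourhood), k iterations
erode_mask <- function(m, k) {
  H <- nrow(m)
  W <- ncol(m)
  for (i in seq_len(k)) {
    m <- m & rbind(m[-1, ], FALSE) & rbind(FALSE, m[-H, ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -W])
  }
  m
}

# log-chromaticity channel: Lambertian shading multiplies all channels by the
# same factor, so log R - log G cancels it exactly, leaving the object-anchored
# chromatic surface texture that motion estimation needs
chroma_channel <- function(img) {
  if (length(dim(img)) != 3) return(img)
  log1p(img[, , 1]) - log1p(img[, , 2])
}

pair_decomposition <- function(img1, img2, mask1, mask2, refine = TRUE, ...) {
  g1 <- chroma_channel(img1)
  g2 <- chroma_channel(img2)
  # mild high-pass removes any residual smooth trend (e.g. specular bleed)
  g1h <- g1 - cpp_box_blur(g1, 8L)
  g2h <- g2 - cpp_box_blur(g2, 8L)
  fl <- dense_flow(g1h, g2h, ...)
  # Erode the target region past the high-pass radius: the filtered images
  # carry a strong stationary ring where the blur crossed the silhouette
  # edge, and near-limb pixels of a turning body violate the affine model.
  sel <- (mask1 == 2L) & (mask2 == 2L)
  for (k in c(5L, 3L, 1L, 0L)) {
    er <- if (k > 0) erode_mask(sel, k) else sel
    if (sum(er) >= 50) break
  }
  mask1e <- mask1
  mask1e[!er] <- 0L
  mf <- masked_flow(fl, mask1e)
  f1 <- fit_ellipse(largest_target_region(mask1))
  f2 <- fit_ellipse(largest_target_region(mask2))
  d <- decompose_motion(mf, f1, f2)
  if (refine) {
    th0 <- c(d$A[1, 1], d$A[1, 2], d$A[2, 1], d$A[2, 2], d$t[1], d$t[2])
    th <- cpp_affine_refine(g1h, g2h, mf$x, mf$y, f1$cx, f1$cy, th0, 10L)$theta
    d$A <- rbind(th[1:2], th[3:4])
    d$t <- c(th[5], th[6])
    d$omega <- (d$A[2, 1] - d$A[1, 2]) / 2
    d$s <- (d$A[1, 1] + d$A[2, 2]) / 2
    d$r <- d$t - c(f2$cx - f1$cx, f2$cy - f1$cy)
  }
  list(decomp = d, fit = f1)
}

#' Calibrate the slip-to-rotation constants on single-axis sequences
#'
#' Runs flow + decomposition over a sequence with known constant per-frame
#' rotation about exactly one of X or Y, and sets the constant to
#' `mean(true increment / slip component)` over frames whose slip exceeds
#' the dead-band.
#'
#' @param seq_x,seq_y `scene_sequence`s rotating about X resp. Y only (either
#'   may be `NULL` to calibrate a single axis).
#' @param deadband slip dead-band in pixels.
#' @return list with `kx`, `ky` (degrees/pixel; `NA` for uncalibrated axes).
#' @export
calibrate_flow <- function(seq_x = NULL, seq_y = NULL, deadband = 0.05) {
  one <- function(sq, comp, axis) {
    rates <- diff(sq$trajectory[, axis])
    vals <- numeric(0)
    for (i in seq_len(length(sq$frames) - 1)) {
      pd <- pair_decomposition(sq$frames[[i]]$image, sq$frames[[i + 1]]$image,
                               sq$frames[[i]]$mask, sq$frames[[i + 1]]$mask)
      slip <- pd$decomp$r[comp]
      if (abs(slip) > deadband) vals <- c(vals, rates[i] / slip)
    }
    if (length(vals) == 0) stop("slip never exceeds the dead-band; cannot calibrate")
    mean(vals)
  }
  list(kx = if (is.null(seq_x)) NA_real_ else one(seq_x, 2, "rx"),
       ky = if (is.null(seq_y)) NA_real_ else one(seq_y, 1, "ry"))
}

#' Track accumulated rotation over a frame sequence
#'
#' Computes per-frame rotation increments from masked optical flow between
#' consecutive frames and accumulates them from the initial pose (predicted
#' by the rotation network or supplied manually). Every 10th frame is marked
#' as a sample frame for evaluation. Frame pairs without target overlap hold
#' the last pose and are flagged.
#'
#' @param frames list of images, or a `scene_sequence`.
#' @param masks list of label masks (ignored when `frames` is a sequence).
#' @param init_pose a [pose6d()] giving the initial rotations.
#' @param calib calibration list from [calibrate_flow()].
#' @param deadband slip dead-band in pixels.
#' @param sample_step evaluation sampling step (default 10 frames).
#' @return a `trajectory_estimate`: list with `angles` (n x 3 matrix of
#'   accumulated degrees), `sample_idx`, `flagged`.
#' @export
track_sequence <- function(frames, masks = NULL, init_pose, calib,
                           deadband = 0.05, sample_step = 10) {
  if (inherits(frames, "scene_sequence")) {
    masks <- lapply(frames$frames, `[[`, "mask")
    frames <- lapply(frames$frames, `[[`, "image")
  }
  n <- length(frames)
  if (n < 2) stop("need at least 2 frames")
  ang <- matrix(0, n, 3, dimnames = list(NULL, c("rx", "ry", "rz")))
  ang[1, ] <- c(init_pose$rx, init_pose$ry, init_pose$rz)
  flagged <- logical(n)
  for (i in seq_len(n - 1)) {
    inc <- c(0, 0, 0)
    ok <- TRUE
    pd <- tryCatch(pair_decomposition(frames[[i]], frames[[i + 1]],
                                      masks[[i]], masks[[i + 1]]),
                   error = function(e) {
                     recoverable <- c("no-target-flow", "target-not-found",
                                      "at least 5 pixels", "at least 20",
                                      "rank-deficient")
                     if (any(vapply(recoverable, grepl,
                                    logical(1), conditionMessage(e)))) NULL
                     else stop(e)
                   })
    if (is.null(pd)) {
      ok <- FALSE
    } else {
      inc <- flow_to_rotation(pd$decomp, calib, deadband,
                              semi_major = pd$fit$major / 2)
    }
    ang[i + 1, ] <- ang[i, ] + inc
    flagged[i + 1] <- !ok
  }
  structure(list(angles = ang,
                 sample_idx = seq(1, n, by = sample_step),
                 flagged = flagged),
            class = "trajectory_estimate")
}

#' Tolerance accuracies of a tracked trajectory at sample frames
#'
#' Compares estimated and true accumulated rotations at the sample frames
#' (every 10th frame) and reports per-axis tolerance accuracy.
#'
#' @param est a [track_sequence()] `trajectory_estimate`.
#' @param truth n x 3 matrix of true per-frame rotations (or a
#'   `scene_sequence`).
#' @param tolerances tolerance bands in degrees.
#' @param report_csv optional CSV path (columns axis, tol, accuracy).
#' @return data.frame of per-axis accuracies, with the per-sample trend
#'   (estimated vs tagged values) in attribute `"trend"`.
#' @export
evaluate_trajectory <- function(est, truth, tolerances = c(5, 10),
                                report_csv = NULL) {
  if (inherits(truth, "scene_sequence")) truth <- truth$trajectory
  if (nrow(truth) < max(est$sample_idx)) stop("truth does not cover sample frames")
  si <- est$sample_idx
  out <- expand.grid(axis = c("rx", "ry", "rz"), tol = tolerances,
                     stringsAsFactors = FALSE)
  out$accuracy <- mapply(function(ax, tol) {
    tolerance_accuracy(est$angles[si, ax], truth[si, ax], tol)
  }, out$axis, out$tol)
  trend <- data.frame(frame = si,
                      est = est$angles[si, , drop = FALSE],
                      true = truth[si, , drop = FALSE])
  attr(out, "trend") <- trend
  if (!is.null(report_csv)) write.csv(out, report_csv, row.names = FALSE)
  out
}
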