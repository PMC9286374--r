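#' Case-study mode configuration for the video pipeline
#'
#' Three registration modes mirror the case studies: `"rigid-instrument"`
#' (rotation network recursively per frame for X, in-plane Y from the mask
#' ellipse, Z fixed by symmetry), `"organ-auto"` (network registration on the
#' first frame, optical-flow tracking afterwards) and `"organ-manual"`
#' (manually supplied initial pose, then optical-flow tracking).
#'
#' @param mode one of `"rigid-instrument"`, `"organ-auto"`, `"organ-manual"`.
#' @param seg_model segmentation model (or [seg_oracle()]).
#' @param rot_model rotation model; required unless mode is `"organ-manual"`.
#' @param calib flow calibration ([calibrate_flow()]); required for the organ
#'   modes.
#' @param init_pose initial [pose6d()] for `"organ-manual"` (a one-line init
#'   file or CLI flag stands in for interactive registration).
#' @param y_calibration sign/offset mapping the mask ellipse angle to the
#'   logged Y rotation.
#' @param fixed_z Z value logged in rigid-instrument mode.
#' @param scene_config the [scene_config()] describing the camera (used for
#'   overlay rendering and scale registration).
#' @param alpha overlay opacity in `[0, 1]`.
#' @return a `mode_config`.
#' @export
mode_config <- function(mode, seg_model, rot_model = NULL, calib = NULL,
                        init_pose = NULL,
                        y_calibration = list(sign = 1, offset = 0),
                        fixed_z = 0, scene_config = NULL, alpha = 0.5) {
  mode <- match.arg(mode, c("rigid-instrument", "organ-auto", "organ-manual"))
  if (mode != "organ-manual" && is.null(rot_model))
    stop("mode '", mode, "' requires a rotation model")
  if (mode == "organ-manual" && is.null(init_pose))
    stop("organ-manual mode requires init_pose")
  if (mode != "rigid-instrument" && is.null(calib))
    stop("organ modes require a flow calibration")
  structure(list(mode = mode, seg_model = seg_model, rot_model = rot_model,
                 calib = calib, init_pose = init_pose,
                 y_calibration = y_calibration, fixed_z = fixed_z,
                 scene_config = scene_config, alpha = alpha),
            class = "mode_config")
}

#' Composite the posed mesh over a frame
#'
#' Rasterizes the mesh at the given pose with the simulator's camera
#' convention and alpha-blends it over the frame. Deterministic.
#'
#' @param frame `H x W x 3` integer array (0-255).
#' @param mesh target `mesh_model`.
#' @param pose a [pose6d()].
#' @param alpha overlay opacity in `[0, 1]`.
#' @param config [scene_config()] fixing the camera geometry.
#' @return an `augmented_frame`: list with `image`, `pose`, `silhouette`
#'   (logical matrix) and `flag` (`TRUE` when the pose fell out of view and
#'   the raw frame was passed through).
#' @export
overlay <- function(frame, mesh, pose, alpha = 0.5, config = scene_config()) {
  stopifnot(alpha >= 0, alpha <= 1, all(is.finite(unlist(pose))))
  cam <- scene_camera(config, mesh)
  nuis <- list(light = list(dir = normalize3(c(0.35, 0.45, 0.9)),
                            intensity = 1, ambient = config$ambient,
                            ks = 0, shininess = 12),
               tex_phase = c(0, 0, 0), bg_phase = c(0, 0))
  target <- make_target_object(mesh, pose, config, cam, nuis)
  out <- cpp_render(list(target), cam$H, cam$W, cam$f, cam$cx, cam$cy,
                    nuis$light, scene_background(config, nuis), shade = TRUE)
  sil <- out$mask == 2L
  if (!any(sil)) {
    return(structure(list(image = frame, pose = pose,
                          silhouette = sil, flag = TRUE),
                     class = "augmented_frame"))
  }
  img <- frame
  for (k in 1:3) {
    ch <- img[, , k]
    rch <- out$image[, , k]
    ch[sil] <- as.integer(round((1 - alpha) * ch[sil] + alpha * rch[sil]))
    img[, , k] <- ch
  }
  structure(list(image = img, pose = pose, silhouette = sil, flag = FALSE),
            class = "augmented_frame")
}

#' Run the registration pipeline over a video
#'
#' Per frame: predict the label mask, localize the target (position + scale
#' from the ellipse fit), infer rotation according to the mode, composite the
#' posed mesh, and append a pose record tagged with the source of every
#' field. Frames whose target is not found emit the raw frame and a flagged
#' record holding the last pose.
#'
#' @param frames list of `H x W x 3` integer frames, a `scene_sequence`, or a
#'   frame directory.
#' @param mc a [mode_config()].
#' @param mesh the target `mesh_model` used for the overlay.
#' @param out_dir if non-`NULL`, augmented frames and a JSON-lines pose log
#'   (`pose_log.jsonl`) are written there.
#' @return a `pipeline_run`: list with `frames` (augmented), `masks`
#'   (predicted), `pose_log` (data.frame with per-field source tags).
#' @export
run_video <- function(frames, mc, mesh, out_dir = NULL) {
  if (inherits(frames, "scene_sequence")) {
    frames <- lapply(frames$frames, `[[`, "image")
  } else if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    paths <- sort(list.files(frames, pattern = "^frame_.*\\.png$", full.names = TRUE))
    frames <- lapply(paths, read_image)
  }
  n <- length(frames)
  if (n == 0) stop("empty input")
  cfg <- mc$scene_config %||% scene_config(image_size = dim(frames[[1]])[1:2])

  log <- vector("list", n)
  aug <- vector("list", n)
  msk <- vector("list", n)
  last <- mc$init_pose %||% pose6d(dim(frames[[1]])[2] / 2, dim(frames[[1]])[1] / 2)
  last_y <- NULL
  scale_ref <- NULL
  prev_ok <- FALSE

  for (i in seq_len(n)) {
    frame <- frames[[i]]
    mask <- predict_mask(mc$seg_model, frame, frame = i)
    msk[[i]] <- mask
    rec <- list(frame = i, flagged = FALSE)
    fit <- tryCatch(fit_ellipse(largest_target_region(mask)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      pose <- last
      rec <- c(rec, as.list(unclass(pose)),
               src_t = "held", src_scale = "held",
               src_rx = "held", src_ry = "held", src_rz = "held")
      rec$flagged <- TRUE
      aug[[i]] <- structure(list(image = frame, pose = pose,
                                 silhouette = NULL, flag = TRUE),
                            class = "augmented_frame")
      log[[i]] <- rec
      prev_ok <- FALSE
      next
    }
    pos <- estimate_position(fit)
    if (is.null(scale_ref)) {
      ref_scale <- if (!is.null(mc$init_pose)) mc$init_pose$scale else 1
      scale_ref <- scale_reference_from_fit(fit, ref_scale)
    }
    sc <- estimate_scale(fit, scale_ref)

    rot <- c(rx = last$rx, ry = last$ry, rz = last$rz)
    src <- c(rx = "held", ry = "held", rz = "held")
    if (mc$mode == "rigid-instrument") {
      pr <- predict_rotation(mc$rot_model, frame)
      rot["rx"] <- pr$angles[["x"]]
      src["rx"] <- "network"
      ym <- tryCatch(mask_y_rotation(fit, mc$y_calibration),
                     error = function(e) NULL)
      if (!is.null(ym)) {
        rot["ry"] <- ym
        src["ry"] <- "mask"
        last_y <- ym
      } else if (!is.null(last_y)) {
        rot["ry"] <- last_y
        src["ry"] <- "held"
        rec$flagged <- TRUE
      }
      rot["rz"] <- mc$fixed_z
      src["rz"] <- "fixed"
    } else if (i == 1 || !prev_ok) {
      if (mc$mode == "organ-auto") {
        pr <- predict_rotation(mc$rot_model, frame)
        for (ax in names(pr$angles)) {
          rot[paste0("r", ax)] <- pr$angles[[ax]]
          src[paste0("r", ax)] <- "network"
        }
      } else {
        rot <- c(rx = mc$init_pose$rx, ry = mc$init_pose$ry, rz = mc$init_pose$rz)
        src[] <- "manual-init"
      }
    } else {
      inc <- tryCatch({
        pd <- pair_decomposition(frames[[i - 1]], frame, msk[[i - 1]], mask)
        flow_to_rotation(pd$decomp, mc$calib, semi_major = pd$fit$major / 2)
      }, error = function(e) c(drx = 0, dry = 0, drz = 0))
      rot <- c(rx = last$rx + inc[["drx"]], ry = last$ry + inc[["dry"]],
               rz = last$rz + inc[["drz"]])
      src[] <- "flow"
    }

    pose <- pose6d(pos[["tx"]], pos[["ty"]], sc, rot[["rx"]], rot[["ry"]], rot[["rz"]])
    aug[[i]] <- overlay(frame, mesh, pose, mc$alpha, cfg)
    rec <- c(rec, as.list(unclass(pose)),
             src_t = "mask", src_scale = "mask",
             src_rx = src[["rx"]], src_ry = src[["ry"]], src_rz = src[["rz"]])
    log[[i]] <- rec
    last <- pose
    prev_ok <- TRUE
  }
  pose_log <- do.call(rbind, lapply(log, function(r) as.data.frame(r)))
  run <- structure(list(frames = aug, masks = msk, pose_log = pose_log,
                        mode = mc$mode), class = "pipeline_run")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n))
      write_image(aug[[i]]$image, file.path(out_dir, sprintf("aug_%04d.png", i)))
    con <- file(file.path(out_dir, "pose_log.jsonl"), "w")
    for (i in seq_len(n))
      writeLines(jsonlite::toJSON(log[[i]], auto_unbox = TRUE, digits = 6), con)
    close(con)
  }
  run
}

#' Score a pipeline run against simulator ground truth
#'
#' Aggregates segmentation IoU (pooled per-class and mean), median position
#' and scale errors, per-axis rotation tolerance accuracies (for the axes the
#' mode actually estimated) and sample-frame trajectory accuracies into one
#' report.
#'
#' @param run a [run_video()] `pipeline_run`.
#' @param truth a `scene_sequence`, or a list with `poses` (data.frame with
#'   `tx, ty, scale, rx, ry, rz`) and optionally `masks`.
#' @param tolerances tolerance bands in degrees.
#' @param report_json,report_csv optional output paths.
#' @return a `pipeline_report` list.
#' @export
evaluate_pipeline <- function(run, truth, tolerances = c(5, 10),
                              report_json = NULL, report_csv = NULL) {
  if (inherits(truth, "scene_sequence")) {
    truth <- list(poses = data.frame(
      tx = vapply(truth$frames, function(f) f$pose$tx, 0),
      ty = vapply(truth$frames, function(f) f$pose$ty, 0),
      scale = vapply(truth$frames, function(f) f$pose$scale, 0),
      truth$trajectory),
      masks = lapply(truth$frames, `[[`, "mask"))
  }
  pl <- run$pose_log
  if (nrow(pl) != nrow(truth$poses)) stop("frame-count mismatch")
  rep <- list(mode = run$mode, n_frames = nrow(pl))

  if (!is.null(truth$masks)) {
    inter <- un <- numeric(3)
    for (i in seq_along(truth$masks)) {
      for (k in 0:2) {
        p <- run$masks[[i]] == k
        t <- truth$masks[[i]] == k
        inter[k + 1] <- inter[k + 1] + sum(p & t)
        un[k + 1] <- un[k + 1] + sum(p | t)
      }
    }
    pc <- ifelse(un > 0, inter / un, NA_real_)
    names(pc) <- c("background", "tool", "target")
    rep$iou <- list(per_class = pc, mean = mean(pc, na.rm = TRUE))
  }
  ok <- !pl$flagged
  rep$position_px <- median(sqrt((pl$tx - truth$poses$tx)^2 +
                                 (pl$ty - truth$poses$ty)^2)[ok])
  rep$scale_err <- median(abs(pl$scale - truth$poses$scale)[ok])

  axes <- c("rx", "ry", "rz")
  active <- vapply(axes, function(ax) {
    any(pl[[paste0("src_", ax)]] %in% c("network", "mask", "flow"))
  }, TRUE)
  rot <- expand.grid(axis = axes[active], tol = tolerances,
                     stringsAsFactors = FALSE)
  if (nrow(rot) > 0) {
    rot$accuracy <- mapply(function(ax, tol) {
      tolerance_accuracy(pl[[ax]][ok], truth$poses[[ax]][ok], tol)
    }, rot$axis, rot$tol)
  }
  rep$rotation <- rot
  si <- seq(1, nrow(pl), by = 10)
  rep$trajectory <- data.frame(
    axis = rep(axes, each = length(tolerances)),
    tol = rep(tolerances, 3),
    accuracy = unlist(lapply(axes, function(ax) {
      vapply(tolerances, function(tol)
        tolerance_accuracy(pl[[ax]][si], truth$poses[[ax]][si], tol), 0)
    })))
  class(rep) <- "pipeline_report"
  if (!is.null(report_json))
    jsonlite::write_json(unclass(rep), report_json, auto_unbox = TRUE,
                         digits = 6, force = TRUE)
  if (!is.null(report_csv)) write.csv(rot, report_csv, row.names = FALSE)
  rep
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline_report (%s, %d frames)\n", x$mode, x$n_frames))
  if (!is.null(x$iou)) cat(sprintf("  mean IoU     %.4f\n", x$iou$mean))
  cat(sprintf("  median pos   %.2f px\n  median scale %.4f\n",
              x$position_px, x$scale_err))
  if (nrow(x$rotation) > 0) {
    for (i in seq_len(nrow(x$rotation)))
      cat(sprintf("  %s acc(%g)   %.4f\n", x$rotation$axis[i],
                  x$rotation$tol[i], x$rotation$accuracy[i]))
  }
  invisible(x)
}
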