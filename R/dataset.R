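#' Generate a labelled synthetic dataset with a 70/15/15 split
#'
#' Renders `n` frames with rotations drawn uniformly within each axis range,
#' writes images and class-ID masks as PNGs plus a manifest CSV, and assigns
#' disjoint train/validation/test splits of sizes
#' `floor(0.70 n) / floor(0.15 n) / remainder`. The whole dataset is
#' reproducible from `seed`.
#'
#' @param n number of frames (>= 10).
#' @param ranges a [rotation_ranges()]; axes given as numeric ranges become
#'   uniformly drawn labels, `"mask-derived"` axes take the config's
#'   `mask_axis_base` (+/- `mask_axis_jitter`), `"irrelevant"` axes are 0.
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @param out_dir output directory (created).
#' @return the manifest `data.frame` (columns `image, mask, rx, ry, rz, scale,
#'   tx, ty, split`), invisibly carrying the directory as attribute `dir`.
#' @export
generate_dataset <- function(n, ranges = NULL, config = scene_config(),
                             seed = 0, out_dir = tempfile("scenes")) {
  if (n < 10) stop("n must be at least 10")
  if (is.null(ranges)) ranges <- config$ranges
  config$ranges <- ranges
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mesh <- make_mesh(config$target_kind, config$target_params,
                    seed = config$mesh_seed)
  H <- config$image_size[1]; W <- config$image_size[2]
  mind <- min(H, W)

  draw_axis <- function(e, n) {
    if (is.numeric(e)) return(runif(n, e[1], e[2]))
    if (identical(e, "mask-derived"))
      return(config$mask_axis_base + runif(n, -1, 1) * config$mask_axis_jitter)
    rep(0, n)
  }
  plan <- with_seed(seed, {
    data.frame(
      rx = draw_axis(ranges$x, n), ry = draw_axis(ranges$y, n),
      rz = draw_axis(ranges$z, n),
      scale = runif(n, config$scale_range[1], config$scale_range[2]),
      tx = (W - 1) / 2 + runif(n, -1, 1) * config$center_jitter * mind,
      ty = (H - 1) / 2 + runif(n, -1, 1) * config$center_jitter * mind,
      frame_seed = sample.int(2^30, n),
      split = local({
        idx <- sample.int(n)
        sp <- character(n)
        n_tr <- floor(0.70 * n); n_va <- floor(0.15 * n)
        sp[idx[seq_len(n_tr)]] <- "train"
        sp[idx[n_tr + seq_len(n_va)]] <- "val"
        sp[idx[(n_tr + n_va + 1):n]] <- "test"
        sp
      })
    )
  })

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    pose <- pose6d(plan$tx[i], plan$ty[i], plan$scale[i],
                   plan$rx[i], plan$ry[i], plan$rz[i])
    smp <- render_scene(mesh, pose, config, seed = plan$frame_seed[i])
    img_rel <- sprintf("img_%05d.png", i)
    msk_rel <- sprintf("mask_%05d.png", i)
    write_image(smp$image, file.path(out_dir, img_rel))
    write_mask(smp$mask, file.path(out_dir, msk_rel))
    rows[[i]] <- data.frame(image = img_rel, mask = msk_rel,
                            rx = plan$rx[i], ry = plan$ry[i], rz = plan$rz[i],
                            scale = plan$scale[i], tx = plan$tx[i],
                            ty = plan$ty[i], split = plan$split[i])
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path manifest CSV path or dataset directory.
#' @return manifest `data.frame` with attribute `dir`.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- read.csv(path, stringsAsFactors = FALSE)
  attr(m, "dir") <- dirname(path)
  m
}

#' Render a smooth video sequence with known rotation trajectory
#'
#' Starting from `start_pose`, each axis advances by a constant per-frame
#' angular rate. The trajectory is clamped to the configured rotation ranges
#' (with a warning) for axes declared as ranges. Lighting, texture phase and
#' tool placement are drawn once at the first frame and held fixed, so
#' frame-to-frame optical flow reflects target motion only.
#'
#' @param mesh target `mesh_model`.
#' @param start_pose initial [pose6d()].
#' @param angular_rates `c(rx, ry, rz)` degrees per frame.
#' @param n_frames number of frames (>= 2).
#' @param config a [scene_config()].
#' @param seed integer seed.
#' @param out_dir if non-`NULL`, frames/masks are written as a numbered frame
#'   directory plus `trajectory.csv`.
#' @return a `scene_sequence`: list with `frames` (list of `scene_sample`),
#'   `fps`, and `trajectory` (n_frames x 3 matrix of degrees).
#' @export
generate_sequence <- function(mesh, start_pose, angular_rates, n_frames,
                              config = scene_config(), seed = 0,
                              out_dir = NULL) {
  if (n_frames < 2) stop("n_frames must be at least 2")
  k <- 0:(n_frames - 1)
  traj <- cbind(rx = start_pose$rx + k * angular_rates[1],
                ry = start_pose$ry + k * angular_rates[2],
                rz = start_pose$rz + k * angular_rates[3])
  clamped <- FALSE
  for (j in 1:3) {
    e <- config$ranges[[c("x", "y", "z")[j]]]
    if (is.numeric(e)) {
      cl <- clamp(traj[, j], e[1], e[2])
      if (any(cl != traj[, j])) clamped <- TRUE
      traj[, j] <- cl
    }
  }
  if (clamped) warning("trajectory left the configured rotation range; clamped")

  nuis <- scene_nuisance(config, seed)
  frames <- vector("list", n_frames)
  tool_params <- NULL
  for (i in seq_len(n_frames)) {
    pose <- pose6d(start_pose$tx, start_pose$ty, start_pose$scale,
                   traj[i, 1], traj[i, 2], traj[i, 3])
    smp <- render_scene(mesh, pose, config, seed = seed, nuisance = nuis,
                        tool_params = tool_params)
    if (i == 1) {
      tool_params <- smp$meta$tool_params
      if (is.null(tool_params)) tool_params <- matrix(numeric(0), 0, 5)
    }
    frames[[i]] <- smp
  }
  seqc <- structure(list(frames = frames, fps = config$fps, trajectory = traj),
                    class = "scene_sequence")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_frames)) {
      write_image(frames[[i]]$image, file.path(out_dir, sprintf("frame_%04d.png", i)))
      write_mask(frames[[i]]$mask, file.path(out_dir, sprintf("mask_%04d.png", i)))
    }
    write.csv(data.frame(frame = seq_len(n_frames), traj),
              file.path(out_dir, "trajectory.csv"), row.names = FALSE)
  }
  seqc
}

#' @export
print.scene_sequence <- function(x, ...) {
  rng <- apply(x$trajectory, 2, range)
  cat(sprintf("scene_sequence: %d frames @ %g fps; rx [%g, %g], ry [%g, %g], rz [%g, %g] deg\n",
              length(x$frames), x$fps, rng[1, 1], rng[2, 1], rng[1, 2],
              rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Load the images, masks and labels of one manifest split
#'
#' @param manifest manifest `data.frame` (attribute `dir`) from
#'   [generate_dataset()] or [read_manifest()].
#' @param split `"train"`, `"val"`, `"test"`, or `NULL` for all rows.
#' @param dir dataset directory.
#' @return list with `images`, `masks`, `labels` (`rx, ry, rz`), `rows`.
#' @export
load_split <- function(manifest, split = NULL, dir = attr(manifest, "dir")) {
  rows <- if (is.null(split)) manifest else manifest[manifest$split == split, ]
  if (nrow(rows) == 0) stop("empty split: ", split)
  imgs <- lapply(file.path(dir, rows$image), read_image)
  msks <- lapply(file.path(dir, rows$mask), read_mask)
  list(images = imgs, masks = msks, labels = rows[, c("rx", "ry", "rz")],
       rows = rows)
}
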