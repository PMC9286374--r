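#' Scene simulator configuration
#'
#' Collects every knob of the synthetic scene renderer: image size, camera,
#' target mesh, rotation ranges, pose jitter, tool count, lighting and texture.
#' The defaults describe the organ (kidney-like) scenario; presets for the
#' rigid-instrument (catheter) scenario are provided.
#'
#' @param image_size `c(H, W)` in pixels, at least 32 x 32.
#' @param view_span fraction of `min(H, W)` spanned by the target's diameter
#'   at scale 1.
#' @param cam_distance reference camera distance (model units) at scale 1.
#' @param target_kind,target_params mesh kind and parameters, see
#'   [make_mesh()].
#' @param ranges a [rotation_ranges()] object.
#' @param mask_axis_base fixed value (degrees) used for axes declared
#'   `"mask-derived"` (the instrument's sitting tilt); `mask_axis_jitter`
#'   adds uniform jitter around it.
#' @param mask_axis_jitter uniform half-width in degrees.
#' @param scale_range range the scale factor is drawn from.
#' @param center_jitter target-centre jitter as a fraction of `min(H, W)`.
#' @param n_tools maximum number of occluding rod-shaped tools (0-2); the
#'   per-frame count is drawn uniformly from `0:n_tools`.
#' @param tool_radius,tool_length tool cylinder dimensions relative to the
#'   target radius.
#' @param occlusion_cap maximum fraction of the target silhouette a tool may
#'   occlude; placements violating it are redrawn.
#' @param light_jitter,intensity_jitter,ambient lighting parameters.
#' @param tex_freq,tex_amp procedural texture frequency and contrast on the
#'   target.
#' @param domain_shift if `TRUE`, renders the domain-shifted variant (stronger
#'   lighting jitter, specular highlights, mild mask-boundary noise) used to
#'   emulate real-image appearance for fine-tuning experiments.
#' @param mesh_seed,tex_seed seeds for mesh irregularity and texture hashing.
#' @param fps nominal frames per second for sequences.
#' @return a `scene_config` list.
#' @export
scene_config <- function(image_size = c(96, 96),
                         view_span = 0.55,
                         cam_distance = 5,
                         target_kind = "organ-ellipsoid",
                         target_params = list(semi_axes = c(1, 0.8, 0.7), bump = 0.06),
                         ranges = ranges_kidney(),
                         mask_axis_base = 0,
                         mask_axis_jitter = 0,
                         scale_range = c(0.85, 1.15),
                         center_jitter = 0.06,
                         n_tools = 2,
                         tool_radius = 0.09,
                         tool_length = 3.5,
                         occlusion_cap = 0.4,
                         light_jitter = 0.25,
                         intensity_jitter = 0.15,
                         ambient = 0.35,
                         tex_freq = 2.5,
                         tex_amp = 0.45,
                         domain_shift = FALSE,
                         mesh_seed = 1,
                         tex_seed = 7,
                         fps = 30) {
  if (any(image_size < 32)) stop("image size must be at least 32 x 32")
  structure(as.list(environment()), class = "scene_config")
}

#' @rdname scene_config
#' @export
scene_config_catheter <- function(image_size = c(64, 64), ...) {
  scene_config(image_size = image_size,
               view_span = 0.8,
               target_kind = "instrument-cylinder",
               target_params = list(radius = 0.18, length = 2.6),
               ranges = ranges_catheter(),
               mask_axis_base = 50,
               scale_range = c(0.9, 1.1),
               center_jitter = 0.04,
               n_tools = 0,
               tex_freq = 3,
               tex_amp = 0.5,
               ...)
}

#' @rdname scene_config
#' @export
scene_config_organ <- function(image_size = c(96, 96), ...) {
  scene_config(image_size = image_size, ...)
}

#' Read or write a scene configuration as YAML
#'
#' @param path YAML file path.
#' @param config a `scene_config`.
#' @return `read_scene_config` returns a `scene_config`.
#' @export
read_scene_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ranges)) {
    rr <- lapply(raw$ranges, function(e) if (is.character(e)) e else as.numeric(e))
    raw$ranges <- rotation_ranges(x = rr$x, y = rr$y, z = rr$z)
  }
  base <- scene_config()
  known <- intersect(names(raw), names(base))
  base[known] <- raw[known]
  class(base) <- "scene_config"
  base
}

#' @rdname read_scene_config
#' @export
write_scene_config <- function(config, path) {
  out <- unclass(config)
  out$ranges <- lapply(unclass(out$ranges), function(e) e)
  yaml::write_yaml(out, path)
  invisible(path)
}

# camera model derived from config + target mesh radius
scene_camera <- function(config, mesh) {
  H <- config$image_size[1]
  W <- config$image_size[2]
  rref <- mesh_radius(mesh)
  f <- config$view_span * min(H, W) / 2 * config$cam_distance / rref
  list(H = H, W = W, f = f, cx = (W - 1) / 2, cy = (H - 1) / 2,
       d0 = config$cam_distance, rref = rref)
}
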