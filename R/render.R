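#' Render one synthetic scene frame
#'
#' Software-rasterizes the target mesh at the given pose (pinhole camera,
#' z-buffer, Lambertian shading, procedural value-noise texture) together with
#' 0-2 rod-shaped occluding tools, and returns the 8-bit RGB frame, the
#' class-ID label mask (0 background, 1 tool, 2 target) and the ground-truth
#' pose. Identical `(mesh, pose, config, seed)` produce bit-identical output.
#'
#' @param mesh a [make_mesh()] `mesh_model` (the target).
#' @param pose a [pose6d()].
#' @param config a [scene_config()].
#' @param seed integer seed for per-frame nuisance (lighting, texture phase,
#'   tool placement).
#' @param nuisance,tool_params internal: precomputed nuisance draws and fixed
#'   tool placements, used by [generate_sequence()] to keep tools and lighting
#'   static across frames.
#' @return a `scene_sample`: list with `image` (H x W x 3 integer, 0-255),
#'   `mask` (integer matrix), `pose`, and `meta`.
#' @export
render_scene <- function(mesh, pose, config = scene_config(), seed = 0,
                         nuisance = NULL, tool_params = NULL) {
  stopifnot(inherits(mesh, "mesh_model"), inherits(pose, "pose6d"))
  if (!all(is.finite(c(pose$rx, pose$ry, pose$rz)))) stop("pose rotations must be finite")
  cam <- scene_camera(config, mesh)
  if (is.null(nuisance)) nuisance <- scene_nuisance(config, seed)
  target <- make_target_object(mesh, pose, config, cam, nuisance)

  sil <- cpp_render(list(target), cam$H, cam$W, cam$f, cam$cx, cam$cy,
                    nuisance$light, scene_background(config, nuisance),
                    shade = FALSE)
  count0 <- sil$counts[1]
  if (count0 == 0) stop("target-out-of-view")

  if (is.null(tool_params)) {
    placed <- place_tools(mesh, pose, config, cam, nuisance, target, count0)
  } else {
    placed <- list(params = tool_params,
                   objects = lapply(seq_len(nrow(tool_params)), function(i) {
                     make_tool_object(tool_params[i, ], mesh, pose, config, cam, nuisance)
                   }))
  }

  out <- cpp_render(c(list(target), placed$objects), cam$H, cam$W,
                    cam$f, cam$cx, cam$cy, nuisance$light,
                    scene_background(config, nuisance), shade = TRUE)
  mask <- out$mask
  if (isTRUE(config$domain_shift)) {
    mask <- mask_boundary_noise(mask, nuisance$mask_noise_seed)
  }
  structure(list(
    image = out$image, mask = mask, pose = pose,
    meta = list(seed = seed, light = nuisance$light,
                tex_phase = nuisance$tex_phase,
                n_tools = length(placed$objects),
                tool_params = placed$params,
                silhouette_px = count0,
                visible_px = out$counts[1])
  ), class = "scene_sample")
}

#' @export
print.scene_sample <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("scene_sample %dx%d: target %d px, tool %d px (%d tool(s)), pose ",
              d[1], d[2], sum(x$mask == 2L), sum(x$mask == 1L),
              x$meta$n_tools))
  print(x$pose)
  invisible(x)
}

# per-frame nuisance draws; all randomness of a frame funnels through here
scene_nuisance <- function(config, seed) {
  ds <- isTRUE(config$domain_shift)
  with_seed(seed, {
    jit <- config$light_jitter * (if (ds) 2 else 1)
    ijit <- config$intensity_jitter * (if (ds) 2 else 1)
    light <- list(
      dir = normalize3(c(0.35, 0.45, 0.9) + jit * rnorm(3)),
      intensity = 1 + ijit * runif(1, -1, 1),
      ambient = config$ambient,
      ks = if (ds) 0.25 else 0,
      shininess = 12
    )
    n_tools <- if (config$n_tools > 0) sample(0:config$n_tools, 1) else 0L
    proposals <- NULL
    if (n_tools > 0) {
      proposals <- lapply(seq_len(n_tools), function(i) {
        cbind(phi = runif(6, 0, 2 * pi), rho = runif(6, 0.55, 1.15),
              ang = runif(6, -0.5, 0.5), tilt = runif(6, -15, 15),
              zoff = runif(6, 0.8, 1.4))
      })
    }
    list(light = light, tex_phase = runif(3, 0, 97),
         bg_phase = runif(2, 0, 97), n_tools = n_tools,
         tool_proposals = proposals,
         mask_noise_seed = sample.int(2^30, 1))
  })
}

scene_background <- function(config, nuisance) {
  list(color = c(0.36, 0.13, 0.11), amp = 0.5, freq = 3,
       phase = nuisance$bg_phase, seed = config$tex_seed + 13L,
       intensity = nuisance$light$intensity)
}

# world-space placement of the target from its pose
pose_world_center <- function(pose, cam) {
  d <- cam$d0 / pose$scale
  c((pose$tx - cam$cx) * d / cam$f, (cam$cy - pose$ty) * d / cam$f, -d)
}

make_target_object <- function(mesh, pose, config, cam, nuisance) {
  R <- pose_rotation(pose$rx, pose$ry, pose$rz)
  ctr <- pose_world_center(pose, cam)
  wv <- mesh$vertices %*% t(R)
  wv <- sweep(wv, 2, ctr, `+`)
  cyl <- mesh$kind == "instrument-cylinder"
  list(wverts = wv, mverts = mesh$vertices, faces = mesh$faces,
       class_id = 2L,
       color = if (cyl) c(0.88, 0.84, 0.55) else c(0.82, 0.46, 0.44),
       tex_amp = config$tex_amp, tex_freq = config$tex_freq,
       tex_kind = if (cyl) 2L else 1L,
       tex_phase = nuisance$tex_phase, tex_seed = config$tex_seed)
}

make_tool_object <- function(p, mesh, pose, config, cam, nuisance) {
  rw <- mesh_radius(mesh)
  ctr <- pose_world_center(pose, cam)
  tool_mesh <- make_mesh("instrument-cylinder",
                         list(radius = config$tool_radius * rw,
                              length = config$tool_length * rw,
                              n_seg = 12, n_axial = 8))
  psi <- p[["phi"]] + pi / 2 + p[["ang"]]
  tl <- deg2rad(p[["tilt"]])
  axis <- c(cos(psi) * cos(tl), sin(psi) * cos(tl), sin(tl))
  # rotation taking +Z to `axis` (Rodrigues)
  z <- c(0, 0, 1)
  v <- c(z[2] * axis[3] - z[3] * axis[2],
         z[3] * axis[1] - z[1] * axis[3],
         z[1] * axis[2] - z[2] * axis[1])
  cth <- sum(z * axis)
  if (abs(cth + 1) < 1e-9) {
    R <- diag(c(1, -1, -1))
  } else {
    vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
    R <- diag(3) + vx + vx %*% vx / (1 + cth)
  }
  tc <- ctr + c(p[["rho"]] * rw * cos(p[["phi"]]),
                p[["rho"]] * rw * sin(p[["phi"]]), p[["zoff"]])
  wv <- tool_mesh$vertices %*% t(R)
  wv <- sweep(wv, 2, tc, `+`)
  list(wverts = wv, mverts = tool_mesh$vertices, faces = tool_mesh$faces,
       class_id = 1L, color = c(0.55, 0.58, 0.66),
       tex_amp = 0.15, tex_freq = 2, tex_kind = 2L,
       tex_phase = nuisance$tex_phase, tex_seed = config$tex_seed + 31L)
}

# sequentially accept tool placements keeping cumulative occlusion under cap
place_tools <- function(mesh, pose, config, cam, nuisance, target, count0) {
  objects <- list()
  params <- NULL
  if (nuisance$n_tools == 0) return(list(params = params, objects = objects))
  bg <- scene_background(config, nuisance)
  for (k in seq_len(nuisance$n_tools)) {
    props <- nuisance$tool_proposals[[k]]
    for (a in seq_len(nrow(props))) {
      cand <- make_tool_object(props[a, ], mesh, pose, config, cam, nuisance)
      chk <- cpp_render(c(list(target), objects, list(cand)), cam$H, cam$W,
                        cam$f, cam$cx, cam$cy, nuisance$light, bg, shade = FALSE)
      occ <- 1 - chk$counts[1] / count0
      if (occ <= config$occlusion_cap) {
        objects[[length(objects) + 1]] <- cand
        params <- rbind(params, props[a, , drop = FALSE])
        break
      }
    }
  }
  list(params = params, objects = objects)
}

# domain-shift annotation noise: boundary pixels flip to a neighbour's class
mask_boundary_noise <- function(mask, seed, p = 0.15) {
  H <- nrow(mask); W <- ncol(mask)
  up <- rbind(mask[1, ], mask[-H, ])
  dn <- rbind(mask[-1, ], mask[H, ])
  lf <- cbind(mask[, 1], mask[, -W])
  rt <- cbind(mask[, -1], mask[, W])
  boundary <- (mask != up) | (mask != dn) | (mask != lf) | (mask != rt)
  with_seed(seed, {
    flip <- boundary & (matrix(runif(H * W), H, W) < p)
    out <- mask
    out[flip] <- up[flip]
    out
  })
}
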