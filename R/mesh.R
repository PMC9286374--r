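#' Build a triangulated target or instrument mesh
#'
#' Generates a closed, centred triangle mesh in model units. Built-in kinds:
#' `"organ-ellipsoid"` (a UV-triangulated ellipsoid with an optional smooth
#' seeded bump perturbation emulating organ surface irregularity) and
#' `"instrument-cylinder"` (a capped cylinder whose long axis is the model Z
#' axis, so rotation about Z is the instrument's symmetry spin). A `"custom"`
#' kind accepts explicit `vertices` and `faces`.
#'
#' @param kind one of `"organ-ellipsoid"`, `"instrument-cylinder"`, `"custom"`.
#' @param params shape parameters. Ellipsoid: `semi_axes` (3 positive),
#'   `bump` (relative radial perturbation amplitude, default 0.06), `n_lat`,
#'   `n_lon`. Cylinder: `radius`, `length`, `n_seg`, `n_axial`. Custom:
#'   `vertices` (V x 3), `faces` (F x 3, 1-based).
#' @param seed integer seed controlling the bump perturbation.
#' @return an object of class `mesh_model` with fields `vertices`, `faces`,
#'   `kind`.
#' @examples
#' m <- make_mesh("organ-ellipsoid", list(semi_axes = c(1, 0.8, 0.7)), seed = 0)
#' range(m$vertices)
#' @export
make_mesh <- function(kind, params = list(), seed = 0) {
  mesh <- switch(kind,
    "organ-ellipsoid" = mesh_ellipsoid(params, seed),
    "instrument-cylinder" = mesh_cylinder(params),
    "custom" = {
      if (is.null(params$vertices) || is.null(params$faces))
        stop("custom mesh needs vertices and faces")
      list(vertices = as.matrix(params$vertices),
           faces = as.matrix(params$faces))
    },
    stop("unknown mesh kind: ", kind)
  )
  v <- mesh$vertices
  f <- mesh$faces
  if (max(f) > nrow(v) || min(f) < 1) stop("face index out of range")
  v <- sweep(v, 2, colMeans(v)) # centre at vertex centroid
  structure(list(vertices = v, faces = f, kind = kind), class = "mesh_model")
}

#' @export
print.mesh_model <- function(x, ...) {
  cat(sprintf("mesh_model '%s': %d vertices, %d faces\n",
              x$kind, nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

mesh_ellipsoid <- function(params, seed) {
  ax <- params$semi_axes %||% c(1, 0.8, 0.7)
  if (length(ax) != 3 || any(!is.finite(ax)) || any(ax <= 0))
    stop("ellipsoid semi-axes must be three positive numbers")
  bump <- params$bump %||% 0.06
  n_lat <- params$n_lat %||% 20
  n_lon <- params$n_lon %||% 28
  # unit sphere grid (poles + rings), then per-vertex radial bump, then scale
  theta <- seq(0, pi, length.out = n_lat + 2)[2:(n_lat + 1)]
  lam <- seq(0, 2 * pi, length.out = n_lon + 1)[1:n_lon]
  dirs <- rbind(
    c(0, 0, 1),
    do.call(rbind, lapply(theta, function(th) {
      cbind(sin(th) * cos(lam), sin(th) * sin(lam), cos(th))
    })),
    c(0, 0, -1)
  )
  r <- rep(1, nrow(dirs))
  if (bump > 0) {
    pert <- with_seed(seed, {
      k <- 4
      d <- matrix(rnorm(3 * k), k, 3)
      d <- d / sqrt(rowSums(d^2))
      fr <- runif(k, 1.5, 4)
      ph <- runif(k, 0, 2 * pi)
      am <- runif(k, 0.4, 1)
      list(d = d, fr = fr, ph = ph, am = am)
    })
    s <- rep(0, nrow(dirs))
    for (j in seq_along(pert$fr)) {
      s <- s + pert$am[j] *
        cos(pert$fr[j] * (dirs %*% pert$d[j, ])[, 1] + pert$ph[j])
    }
    r <- 1 + bump * s / sum(pert$am)
  }
  v <- dirs * r
  v <- sweep(v, 2, ax, `*`)
  # faces: top fan, rings, bottom fan
  idx <- function(i, j) 1 + (i - 1) * n_lon + ((j - 1) %% n_lon) + 1
  faces <- list()
  for (j in 1:n_lon) faces[[length(faces) + 1]] <- c(1, idx(1, j), idx(1, j + 1))
  for (i in 1:(n_lat - 1)) {
    for (j in 1:n_lon) {
      a <- idx(i, j); b <- idx(i, j + 1); c2 <- idx(i + 1, j); d2 <- idx(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, c2, b)
      faces[[length(faces) + 1]] <- c(b, c2, d2)
    }
  }
  bot <- nrow(v)
  for (j in 1:n_lon) faces[[length(faces) + 1]] <- c(bot, idx(n_lat, j + 1), idx(n_lat, j))
  list(vertices = v, faces = do.call(rbind, faces))
}

mesh_cylinder <- function(params) {
  r <- params$radius %||% 0.1
  L <- params$length %||% 2
  if (!is.finite(r) || !is.finite(L) || r <= 0 || L <= 0)
    stop("cylinder radius and length must be positive")
  n_seg <- params$n_seg %||% 20
  n_ax <- params$n_axial %||% 12
  lam <- seq(0, 2 * pi, length.out = n_seg + 1)[1:n_seg]
  zs <- seq(-L / 2, L / 2, length.out = n_ax + 1)
  rings <- do.call(rbind, lapply(zs, function(z) {
    cbind(r * cos(lam), r * sin(lam), z)
  }))
  v <- rbind(rings, c(0, 0, -L / 2), c(0, 0, L / 2))
  nb <- nrow(rings) + 1
  nt <- nrow(rings) + 2
  idx <- function(i, j) (i - 1) * n_seg + ((j - 1) %% n_seg) + 1
  faces <- list()
  for (i in 1:n_ax) {
    for (j in 1:n_seg) {
      a <- idx(i, j); b <- idx(i, j + 1); c2 <- idx(i + 1, j); d2 <- idx(i + 1, j + 1)
      faces[[length(faces) + 1]] <- c(a, b, c2)
      faces[[length(faces) + 1]] <- c(b, d2, c2)
    }
  }
  for (j in 1:n_seg) {
    faces[[length(faces) + 1]] <- c(nb, idx(1, j + 1), idx(1, j))
    faces[[length(faces) + 1]] <- c(nt, idx(n_ax + 1, j), idx(n_ax + 1, j + 1))
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

#' Validate mesh invariants
#'
#' Checks face indices, closedness for built-in kinds (every edge shared by
#' exactly two faces) and that all triangles have positive area.
#'
#' @param mesh a `mesh_model`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  if (max(f) > nrow(v)) stop("face index exceeds vertex count")
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  e1 <- p2 - p1
  e2 <- p3 - p1
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  if (any(areas <= 1e-12)) stop("degenerate (zero-area) triangle")
  if (mesh$kind != "custom") {
    edges <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    if (any(table(key) != 2)) stop("mesh is not closed")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# largest vertex distance from the origin; sets the camera focal length so a
# target of this radius spans view_span * min(H, W) pixels at scale 1
mesh_radius <- function(mesh) max(sqrt(rowSums(mesh$vertices^2)))
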