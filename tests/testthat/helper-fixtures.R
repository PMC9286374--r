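# Shared fixtures, built in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

test_organ_mesh <- function() {
  fixture("organ_mesh",
          make_mesh("organ-ellipsoid", list(semi_axes = c(1, 0.8, 0.7)), seed = 1))
}

test_organ_config <- function(...) {
  scene_config(image_size = c(64, 64), n_tools = 0, ...)
}

# small organ dataset (n = 16 at 48x48) reused by segmentation tests
test_seg_dataset <- function() {
  fixture("seg_dataset", {
    generate_dataset(16, config = scene_config(image_size = c(48, 48)),
                     seed = 7, out_dir = tempfile("segfix"))
  })
}

# small catheter dataset for rotation tests (n = 24 at 48x48)
test_rot_dataset <- function() {
  fixture("rot_dataset", {
    generate_dataset(24, config = scene_config_catheter(image_size = c(48, 48)),
                     seed = 11, out_dir = tempfile("rotfix"))
  })
}

# draw a filled disk region (0-based centre coordinates)
disk_region <- function(H, W, cx, cy, r) {
  reg <- matrix(FALSE, H, W)
  for (row in seq_len(H)) {
    for (col in seq_len(W)) {
      if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) reg[row, col] <- TRUE
    }
  }
  reg
}

# rotate a binary region about its centroid by `deg` (nearest-neighbour)
rotate_region <- function(reg, deg) {
  H <- nrow(reg); W <- ncol(reg)
  idx <- which(reg)
  y <- (idx - 1) %% H
  x <- (idx - 1) %/% H
  cx <- mean(x); cy <- mean(y)
  th <- deg * pi / 180
  out <- matrix(FALSE, H, W)
  for (row in seq_len(H)) {
    for (col in seq_len(W)) {
      xs <- cos(th) * (col - 1 - cx) + sin(th) * (row - 1 - cy) + cx
      ys <- -sin(th) * (col - 1 - cx) + cos(th) * (row - 1 - cy) + cy
      rr <- round(ys) + 1; cc <- round(xs) + 1
      if (rr >= 1 && rr <= H && cc >= 1 && cc <= W && reg[rr, cc])
        out[row, col] <- TRUE
    }
  }
  out
}
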