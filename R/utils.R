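# internal helpers

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulator calls do not disturb user code.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(0, 0, 1) else v / n
}

#' Read and write simulator images and masks
#'
#' Images are 8-bit RGB PNGs stored as `H x W x 3` integer arrays (0-255);
#' label masks are single-channel PNGs whose bytes are the literal class IDs
#' (0 background, 1 tool, 2 target).
#'
#' @param path file path.
#' @param image `H x W x 3` integer array with values in 0-255.
#' @param mask integer matrix of class IDs.
#' @return `read_image` returns an integer `H x W x 3` array; `read_mask` an
#'   integer matrix. The writers return `path` invisibly.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
  storage.mode(a) <- "double"
  array(as.integer(round(a * 255)), dim = dim(a))
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  matrix(as.integer(round(a * 255)), nrow = nrow(a))
}

#' @rdname read_image
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask / 255, path)
  invisible(path)
}

# image int array -> [0,1] double array (network input)
image_to_unit <- function(image) image / 255

# grayscale double matrix in [0,1] from an int RGB array
to_gray <- function(image) {
  (0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]) / 255
}
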