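#' Symmetric patch index
#'
#' For a patch whose `n = (2s+1)^2` pixels are numbered `v = 1..n` row-major
#' (left to right, top to bottom), the symmetric index is the point
#' reflection through the patch center: `n + 1 - v`.  For a 3 x 3 patch,
#' `v = 4` maps to `6` and `v = 1` maps to `9`.  It is used when aggregating
#' estimates over shifted processing blocks: the pixel under study occupies
#' position `v_hat` in the patch centered at its offset-`v` neighbour.
#'
#' @param v patch index in `1..n` (vectorized).
#' @param n patch pixel count; must be the square of an odd number.
#' @return the symmetric indices, same length as `v`.
#' @export
symmetric_index <- function(v, n) {
  side <- sqrt(n)
  if (side != floor(side) || side %% 2 != 1)
    stop("`n` must be the square of an odd patch side")
  if (any(v < 1 | v > n | v != floor(v)))
    stop("`v` must be integer in 1..n")
  n + 1 - v
}

#' Patch geometry specification
#'
#' @param s patch radius; the patch side is `2s + 1` and the patch holds
#'   `n = (2s+1)^2` pixels.
#' @return list with components `s`, `side`, `n`.
#' @export
patch_spec <- function(s) {
  if (s < 0 || s != floor(s)) stop("`s` must be a non-negative integer")
  side <- 2L * as.integer(s) + 1L
  list(s = as.integer(s), side = side, n = side * side)
}

# row-major window offsets for radius s: a (2s+1)^2 x 2 matrix of
# (drow, dcol), v-th row = offset of patch index v
window_offsets <- function(s) {
  side <- 2L * s + 1L
  d <- seq.int(-s, s)
  cbind(drow = rep(d, each = side), dcol = rep(d, times = side))
}

#' Extract a patch from an image
#'
#' Returns the `n = (2s+1)^2` pixels of the square window of radius `s`
#' centered at `center`, ordered row-major so that index `v = (n+1)/2` is
#' the center pixel.  The image must already be padded (or the window must
#' fit) — no border logic is applied here.
#'
#' @param image numeric `H x W x 3` array.
#' @param center integer `c(row, col)` (1-based).
#' @param s patch radius.
#' @return `n x 3` numeric matrix; row `v` holds the RGB of patch pixel `v`.
#' @export
extract_patch <- function(image, center, s) {
  image <- as_image(image)
  off <- window_offsets(as.integer(s))
  rows <- center[1] + off[, 1]; cols <- center[2] + off[, 2]
  if (any(rows < 1 | rows > dim(image)[1] | cols < 1 | cols > dim(image)[2]))
    stop("patch window exceeds image bounds; pad the image first")
  n <- nrow(off)
  out <- matrix(0, n, 3L)
  for (q in 1:3) out[, q] <- image[cbind(rows, cols, q)]
  out
}

#' Coordinates of a processing block
#'
#' The `(2r+1)^2` pixel coordinates of the block centered at `center`,
#' row-major, including the center itself.
#'
#' @param center integer `c(row, col)`.
#' @param r block radius.
#' @return `(2r+1)^2 x 2` integer matrix of (row, col) coordinates.
#' @export
block_centers <- function(center, r) {
  if (r < 0 || r != floor(r)) stop("`r` must be a non-negative integer")
  off <- window_offsets(as.integer(r))
  cbind(row = center[1] + off[, 1], col = center[2] + off[, 2])
}
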