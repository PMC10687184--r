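#' Sum-of-squared-distances patch dissimilarity
#'
#' The classic NLM patch distance: the sum over patch positions of the
#' squared Euclidean RGB distance between corresponding pixels,
#' `D = sum_v ||x_jv - x_iv||^2`.  A single impulsive pixel in either patch
#' can dominate this sum, which is why NLM preserves impulses.
#'
#' @param wj,wi `n x 3` patch matrices (see [extract_patch()]).
#' @return non-negative scalar in squared-intensity units.
#' @export
ssd_patch_distance <- function(wj, wi) {
  if (!is.matrix(wj) || !is.matrix(wi) || any(dim(wj) != dim(wi)))
    stop("patches must be matrices of identical dimension")
  sum((wj - wi)^2)
}

#' Trimmed pixel-to-patch distance
#'
#' The mean of the `alpha` smallest squared Euclidean RGB distances from a
#' single pixel `x` to the `n` pixels of the reference patch `wi` (all of
#' them, including the patch center).  With `alpha = n` it is the average
#' squared distance to the whole patch; with `alpha = 1` it is the distance
#' to the nearest pixel.  Intermediate values trim the influence of
#' outliers present in `wi`.  Squared distances are sorted directly:
#' squaring is monotone on non-negatives, so the order is the same as for
#' distances.
#'
#' @param x length-3 RGB pixel.
#' @param wi `n x 3` reference patch.
#' @param alpha trim count, `1 <= alpha <= n`.
#' @return non-negative scalar.
#' @export
trimmed_pixel_distance <- function(x, wi, alpha) {
  n <- nrow(wi)
  if (alpha < 1 || alpha > n || alpha != floor(alpha))
    stop("`alpha` must be an integer in 1..n")
  d2 <- (wi[, 1] - x[1])^2 + (wi[, 2] - x[2])^2 + (wi[, 3] - x[3])^2
  mean(sort(d2)[seq_len(alpha)])
}

#' Robust trimmed patch dissimilarity
#'
#' The two-level trimmed dissimilarity at the heart of the MINOR filter.
#' For every pixel `u` of the candidate patch `wj`, the trimmed
#' pixel-to-patch distance `R(x_ju, wi)` is computed
#' ([trimmed_pixel_distance()]); the `beta` pixels of `wj` with the
#' smallest `R` form the trimmed window `W*`, and the dissimilarity is
#' `Delta = mean of the beta smallest R values`.  The measure is
#' directional (`Delta(wj, wi) != Delta(wi, wj)` in general) and, unlike
#' the SSD distance, a patch is not at zero dissimilarity from itself
#' unless it is constant — which is precisely what lets the filter weight
#' the central pixel without trusting it.
#'
#' Ties in both sort stages are broken by ascending patch index (stable
#' sort), so the membership of the trimmed window is deterministic.
#'
#' @param wj candidate patch (`n x 3`).
#' @param wi reference (central) patch (`n x 3`).
#' @param alpha inner trim count, `1 <= alpha <= n`.
#' @param beta outer trim count, `1 <= beta <= n`.
#' @return object of class `trimmed_match`: list with `delta` (the
#'   dissimilarity), `selected` (the `beta` patch indices of `wj` forming
#'   the trimmed window, ordered by ascending `R`), and `r_values` (all
#'   `n` per-pixel trimmed distances).
#' @export
robust_patch_dissimilarity <- function(wj, wi, alpha, beta) {
  if (!is.matrix(wj) || !is.matrix(wi) || any(dim(wj) != dim(wi)))
    stop("patches must be matrices of identical dimension")
  n <- nrow(wj)
  if (beta < 1 || beta > n || beta != floor(beta))
    stop("`beta` must be an integer in 1..n")
  r_values <- vapply(seq_len(n), function(u)
    trimmed_pixel_distance(wj[u, ], wi, alpha), numeric(1))
  ord <- order(r_values)              # stable: ties broken by ascending index
  selected <- ord[seq_len(beta)]
  structure(
    list(delta = mean(r_values[selected]),
         selected = selected,
         r_values = r_values),
    class = "trimmed_match")
}

#' @export
print.trimmed_match <- function(x, ...) {
  cat("Trimmed patch match\n")
  cat("  delta:   ", format(x$delta), "\n")
  cat("  trimmed window (beta =", length(x$selected), "): ",
      paste(x$selected, collapse = " "), "\n")
  invisible(x)
}
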