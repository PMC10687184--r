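new_denoise_result <- function(core, method, params, iterations_done = 1L) {
  structure(
    list(image = clip255(core$image),
         z = core$z,
         fallback = core$fallback,
         method = method,
         params = params,
         iterations = iterations_done),
    class = "denoise_result")
}

#' @export
print.denoise_result <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<denoise_result> %s, %d x %d\n", x$method, d[1], d[2]))
  p <- x$params
  cat("  params: ", paste(names(p), unlist(p), sep = "=", collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  fallback pixels: %d; iterations: %d\n",
              x$fallback, x$iterations))
  invisible(x)
}

#' @export
summary.denoise_result <- function(object, ...) {
  cat(sprintf("%s restoration of a %d x %d image\n",
              object$method, dim(object$image)[1], dim(object$image)[2]))
  cat("  intensity range: [",
      format(min(object$image)), ", ", format(max(object$image)), "]\n",
      sep = "")
  cat("  normalizer Z: median ", format(median(object$z)),
      ", min ", format(min(object$z)), "\n", sep = "")
  cat("  pixels with empty contribution set: ", object$fallback, "\n",
      sep = "")
  invisible(object)
}

#' @export
plot.denoise_result <- function(x, ...) {
  plot(as.raster(clip255(x$image) / 255), ...)
}

#' MINOR filter: robust NLM for mixed Gaussian and impulsive noise
#'
#' Denoises an RGB image using the trimmed patch dissimilarity
#' ([robust_patch_dissimilarity()]) inside a blockwise NLM scheme.  For
#' every pixel and every patch offset `v`, candidate patches from the block
#' centered at the offset-`v` neighbour are compared to that block's central
#' patch; a candidate contributes its symmetric-index pixel, weighted by
#' `exp(-Delta / sigma^2)`, and only if that pixel belongs to the
#' candidate's trimmed window (its `beta` most patch-consistent pixels).
#' Impulses are thereby excluded from the averages even when they sit at a
#' block center, because a patch is never at zero dissimilarity from itself.
#'
#' `mode = "global"` (MINOR_G) pools every contribution into one weighted
#' average per pixel; `mode = "standard"` (MINOR_S) normalizes the n
#' per-offset estimates separately and averages the non-empty ones.
#'
#' @param image numeric `H x W x 3` array in [0, 255].
#' @param s patch radius (default 1: 3 x 3 patches).
#' @param r block radius.
#' @param alpha inner trim count, in `1..(2s+1)^2`.
#' @param beta outer trim count (trimmed-window size), in `1..(2s+1)^2`.
#' @param sigma weight bandwidth in intensity units.
#' @param mode `"global"` (MINOR_G, default) or `"standard"` (MINOR_S).
#' @param iterations number of filtering passes (a second pass helps for
#'   contamination levels around p = 50).
#' @param weight_threshold drop contributions with weight below this value
#'   before normalization; 0 disables.
#' @param pad_mode border policy passed to [pad_image()].
#' @return object of class `denoise_result`: list with the restored `image`,
#'   the per-pixel normalizer `z`, the `fallback` count (pixels whose
#'   contribution set was empty and which were passed through unchanged),
#'   and the resolved parameters.
#' @examples
#' img <- make_phantom("step-edge", size = c(32, 32))
#' noisy <- add_mgin(img, p = 30, seed = 7)
#' out <- minor_filter(noisy$image, r = 3, alpha = 4, beta = 5, sigma = 40)
#' psnr(img, out$image) > psnr(img, noisy$image)
#' @export
minor_filter <- function(image, s = 1, r = 6, alpha = 4, beta = 5,
                         sigma = 40, mode = c("global", "standard"),
                         iterations = 1, weight_threshold = 0,
                         pad_mode = "reflect") {
  mode <- match.arg(mode)
  image <- as_image(image)
  n <- (2 * s + 1)^2
  check_count <- function(x, nm, lo, hi) {
    if (!is.numeric(x) || length(x) != 1L || x != floor(x) || x < lo || x > hi)
      stop(sprintf("`%s` must be an integer in %d..%d", nm, lo, hi))
  }
  check_count(s, "s", 0, 1e6); check_count(r, "r", 0, 1e6)
  check_count(alpha, "alpha", 1, n); check_count(beta, "beta", 1, n)
  check_count(iterations, "iterations", 1, 100)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (weight_threshold < 0) stop("`weight_threshold` must be >= 0")
  h <- dim(image)[1]; w <- dim(image)[2]
  cur <- image
  fallback <- 0L
  for (it in seq_len(iterations)) {
    padded <- pad_image(cur, r + 2 * s, mode = pad_mode)
    core <- minor_core(padded, h, w, as.integer(s), as.integer(r),
                       as.integer(alpha), as.integer(beta), sigma,
                       mode == "global", weight_threshold)
    cur <- core$image
    fallback <- fallback + core$fallback
  }
  core$fallback <- fallback
  new_denoise_result(core,
    method = if (mode == "global") "MINOR_G" else "MINOR_S",
    params = list(s = s, r = r, alpha = alpha, beta = beta, sigma = sigma,
                  iterations = iterations, weight_threshold = weight_threshold),
    iterations_done = iterations)
}

#' Classic non-local means filter
#'
#' The NLM baseline with the sum-of-squared-distances patch dissimilarity
#' and weights `exp(-D / sigma^2)`.  Three aggregation modes: `"pixelwise"`
#' (each pixel is the weighted average of block-member pixels),
#' `"patchwise"` (mean of the n per-offset estimates built with the
#' symmetric patch index), and `"global"` (all contributions pooled into a
#' single weighted average).
#'
#' Because the SSD similarity of the central patch to itself is always
#' zero, the raw self-weight is 1 and pixelwise NLM preserves impulses at
#' the window center; `central_weight = "max"` (the default) substitutes
#' the largest weight among the other block members, the usual remedy.
#'
#' @inheritParams minor_filter
#' @param mode aggregation scheme, see above.
#' @param central_weight `"max"` (substitute the self-weight, default) or
#'   `"raw"` (keep the self-weight of 1).
#' @return `denoise_result`, as for [minor_filter()].
#' @export
nlm_filter <- function(image, s = 1, r = 10, sigma = 55,
                       mode = c("pixelwise", "patchwise", "global"),
                       central_weight = c("max", "raw"),
                       iterations = 1, weight_threshold = 0,
                       pad_mode = "reflect") {
  mode <- match.arg(mode)
  central_weight <- match.arg(central_weight)
  image <- as_image(image)
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (s < 0 || s != floor(s)) stop("`s` must be a non-negative integer")
  if (r < 0 || r != floor(r)) stop("`r` must be a non-negative integer")
  h <- dim(image)[1]; w <- dim(image)[2]
  mcode <- match(mode, c("pixelwise", "patchwise", "global")) - 1L
  margin <- if (mode == "pixelwise") r + s else r + 2 * s
  cur <- image
  fallback <- 0L
  for (it in seq_len(iterations)) {
    padded <- pad_image(cur, margin, mode = pad_mode)
    core <- nlm_core(padded, h, w, as.integer(s), as.integer(r), sigma,
                     mcode, if (central_weight == "max") 1L else 0L,
                     weight_threshold)
    cur <- core$image
    fallback <- fallback + core$fallback
  }
  core$fallback <- fallback
  new_denoise_result(core,
    method = paste0("NLM_", mode),
    params = list(s = s, r = r, sigma = sigma,
                  central_weight = central_weight, iterations = iterations,
                  weight_threshold = weight_threshold),
    iterations_done = iterations)
}

#' Bilateral filter
#'
#' Weighted block average with weights combining spatial closeness
#' (`exp(-rho^2 / sigma_s^2)`, `rho` the Euclidean distance between pixel
#' coordinates) and radiometric similarity
#' (`exp(-||x_j - x_i||^2 / sigma_r^2)` in RGB).  As `sigma_r` grows the
#' filter tends to plain Gaussian convolutional smoothing; as `sigma_s`
#' grows it tends to a Yaroslavsky-type range filter.
#'
#' @inheritParams minor_filter
#' @param sigma_s spatial bandwidth (pixels), > 0.
#' @param sigma_r radiometric bandwidth (intensity units), > 0.
#' @return `denoise_result`.
#' @export
bilateral_filter <- function(image, r = 3, sigma_s = 2, sigma_r = 30,
                             pad_mode = "reflect") {
  image <- as_image(image)
  if (!is.numeric(sigma_s) || sigma_s <= 0) stop("`sigma_s` must be > 0")
  if (!is.numeric(sigma_r) || sigma_r <= 0) stop("`sigma_r` must be > 0")
  if (r < 0 || r != floor(r)) stop("`r` must be a non-negative integer")
  h <- dim(image)[1]; w <- dim(image)[2]
  padded <- pad_image(image, r, mode = pad_mode)
  core <- bilateral_core(padded, h, w, as.integer(r), sigma_s, sigma_r)
  new_denoise_result(core, method = "BF",
                     params = list(r = r, sigma_s = sigma_s,
                                   sigma_r = sigma_r))
}
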