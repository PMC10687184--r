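#' Add white Gaussian noise to a color image
#'
#' Every channel of every pixel receives an independent zero-mean Gaussian
#' increment with standard deviation `sigma_n` (intensity units); the result
#' is clipped to [0, 255].  Deterministic given `seed`.
#'
#' @param image numeric `H x W x 3` array, values in [0, 255].
#' @param sigma_n Gaussian standard deviation, >= 0.
#' @param seed integer RNG seed.
#' @param clip clip the result to [0, 255] (default `TRUE`).
#' @return noisy image array.
#' @export
add_gaussian <- function(image, sigma_n, seed, clip = TRUE) {
  image <- as_image(image)
  if (!is.numeric(sigma_n) || length(sigma_n) != 1L || sigma_n < 0)
    stop("`sigma_n` must be a single non-negative number")
  if (sigma_n == 0) return(image)
  noisy <- image + withr::with_seed(seed,
    array(rnorm(length(image), 0, sigma_n), dim = dim(image)))
  if (clip) clip255(noisy) else noisy
}

#' Add random-valued impulsive noise (RVIN)
#'
#' A uniformly random subset of `round(fraction * H * W)` distinct pixel
#' sites is selected (without replacement); at each selected site all three
#' channels are replaced by independent uniform integers in [0, 255].
#' The returned mask marks exactly the replaced sites, which makes the
#' impulse-removal metrics testable against ground truth.
#'
#' @param image numeric `H x W x 3` array.
#' @param fraction proportion of corrupted pixels, in [0, 1].
#' @param seed integer RNG seed.
#' @return list with components `image` (noisy array) and `mask`
#'   (H x W logical matrix, `TRUE` at impulse sites).
#' @export
add_impulsive <- function(image, fraction, seed) {
  image <- as_image(image)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 1)
    stop("`fraction` must be a single number in [0, 1]")
  h <- dim(image)[1]; w <- dim(image)[2]
  npix <- h * w
  k <- round(fraction * npix)
  mask <- matrix(FALSE, h, w)
  if (k > 0) {
    withr::with_seed(seed, {
      sites <- sample.int(npix, k, replace = FALSE)
      vals <- matrix(sample(0:255, 3L * k, replace = TRUE), ncol = 3L)
    })
    mask[sites] <- TRUE
    for (q in 1:3) {
      ch <- image[, , q]
      ch[sites] <- vals[, q]
      image[, , q] <- ch
    }
  }
  list(image = image, mask = mask)
}

#' Add mixed Gaussian and impulsive noise (MGIN)
#'
#' The contamination model used throughout: the image is first corrupted by
#' zero-mean Gaussian noise with standard deviation `p`, then `p` percent of
#' its pixels are replaced by random-valued impulses.  The order (Gaussian
#' first, impulses second) is part of the model.  Sub-seeds for the two
#' stages are derived deterministically from `seed`.
#'
#' @param image numeric `H x W x 3` array.
#' @param p contamination level in [0, 100]: Gaussian std in intensity units
#'   and impulse percentage simultaneously.
#' @param seed integer RNG seed.
#' @param clip clip after the Gaussian stage (default `TRUE`).
#' @return list with components `image` and `mask` as in [add_impulsive()].
#' @export
add_mgin <- function(image, p, seed, clip = TRUE) {
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 100)
    stop("`p` must be a single number in [0, 100]")
  g <- add_gaussian(image, p, seed = seed, clip = clip)
  add_impulsive(g, p / 100, seed = seed + 1L)
}
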