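#' Recommended filter parameters for a given contamination level
#'
#' Parameter presets tuned for the mixed-noise model of [add_mgin()] at the
#' three study levels p = 10, 30, 50.  For MINOR the patch radius is always
#' `s = 1` (3 x 3 patches suffice at every level); the block radius grows
#' with the contamination (`r` = 1, 6, 12), the inner trim is `alpha = 2`
#' at low contamination and 4 otherwise, the trimmed-window size is
#' `beta = 5` throughout, and the bandwidth is `sigma = 20` at p = 10 and
#' 40 at the higher levels.  For the classic NLM baseline the established
#' presets are much larger windows: `(s, r)` = (1, 10), (2, 17), (3, 17).
#'
#' The NLM bandwidth is not part of the published `(s, r)` preset; it is
#' set from the established color-NLM recommendation of a per-sample
#' bandwidth `h` of 0.55, 0.40 and 0.35 times the noise standard deviation
#' for the three patch sizes, rescaled to the unnormalized SSD distance
#' used here: `sigma = h * sqrt(3 n)`.
#'
#' An off-grid `p` is mapped to the nearest supported level with a warning.
#'
#' @param p contamination level; supported levels are 10, 30, 50.
#' @param method `"minor"` or `"nlm"`.
#' @return named list of parameters, directly usable as arguments to
#'   [minor_filter()] or [nlm_filter()].
#' @examples
#' recommended_params(30, "minor")
#' @export
recommended_params <- function(p, method = c("minor", "nlm")) {
  method <- match.arg(method)
  levels <- c(10, 30, 50)
  if (!p %in% levels) {
    p_near <- levels[which.min(abs(levels - p))]
    warning(sprintf(
      "no preset for p = %s; using the nearest supported level p = %d",
      format(p), p_near))
    p <- p_near
  }
  if (method == "minor") {
    switch(as.character(p),
      "10" = list(s = 1L, r = 1L,  alpha = 2L, beta = 5L, sigma = 20),
      "30" = list(s = 1L, r = 6L,  alpha = 4L, beta = 5L, sigma = 40),
      "50" = list(s = 1L, r = 12L, alpha = 4L, beta = 5L, sigma = 40))
  } else {
    sr <- switch(as.character(p),
      "10" = list(s = 1L, r = 10L, h = 0.55 * p),
      "30" = list(s = 2L, r = 17L, h = 0.40 * p),
      "50" = list(s = 3L, r = 17L, h = 0.35 * p))
    n <- (2L * sr$s + 1L)^2
    list(s = sr$s, r = sr$r, sigma = sr$h * sqrt(3 * n))
  }
}
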