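check_pair <- function(clean, restored) {
  clean <- as_image(clean, "clean")
  restored <- as_image(restored, "restored")
  if (!all(dim(clean) == dim(restored)))
    stop("`clean` and `restored` must have identical dimensions")
  list(clean = clean, restored = restored)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` with
#' `MSE = (1/3N) sum_i ||o_i - y_i||^2`, the squared RGB Euclidean norm
#' summed over the N pixels and divided by the 3N channel values.
#' Identical images give `Inf`.
#'
#' @param clean,restored numeric `H x W x 3` arrays of equal dimension.
#' @return PSNR in dB.
#' @export
psnr <- function(clean, restored) {
  p <- check_pair(clean, restored)
  mse <- mean((p$clean - p$restored)^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}

#' Mean absolute error
#'
#' Mean absolute channel difference over the 3N channel values; the usual
#' indicator of detail preservation (lower is better).
#'
#' @inheritParams psnr
#' @return MAE in intensity units.
#' @export
mae <- function(clean, restored) {
  p <- check_pair(clean, restored)
  mean(abs(p$clean - p$restored))
}

#' Impulse removal index
#'
#' A "relaxed" PSNR that measures the capacity of a filter to remove
#' impulses.  The per-pixel error is the minimum squared RGB distance from
#' the restored pixel `y_i` to any clean pixel within the window of radius
#' `window_radius` centered at `i` in the clean image (reflect-padded):
#' `MSE_R = (1/3N) sum_i min_{o_j in W_i} ||y_i - o_j||^2`, and
#' `IRI = 10 log10(255^2 / MSE_R)`.  A restored pixel that matches any
#' clean pixel of its neighbourhood (an edge-consistent substitution)
#' contributes nothing; a retained impulse is far from every clean
#' neighbour and is punished.  Since the window contains `o_i` itself,
#' `IRI >= PSNR` always, and at `window_radius = 0` the two coincide.
#' The measure is directional: the window lives on the clean image.
#'
#' @inheritParams psnr
#' @param window_radius radius of the clean-image search window (default 1,
#'   a 3 x 3 window matching the s = 1 patches used by the filters).
#' @return IRI in dB.
#' @export
iri <- function(clean, restored, window_radius = 1) {
  p <- check_pair(clean, restored)
  if (window_radius < 0 || window_radius != floor(window_radius))
    stop("`window_radius` must be a non-negative integer")
  wr <- as.integer(window_radius)
  h <- dim(p$clean)[1]; w <- dim(p$clean)[2]
  pc <- pad_image(p$clean, wr)
  best <- NULL
  for (dr in -wr:wr) for (dc in -wr:wr) {
    shifted <- pc[wr + dr + seq_len(h), wr + dc + seq_len(w), , drop = FALSE]
    d2 <- (shifted[, , 1] - p$restored[, , 1])^2 +
          (shifted[, , 2] - p$restored[, , 2])^2 +
          (shifted[, , 3] - p$restored[, , 3])^2
    best <- if (is.null(best)) d2 else pmin(best, d2)
  }
  mse_r <- sum(best) / (3 * h * w)
  if (mse_r == 0) return(Inf)
  10 * log10(255^2 / mse_r)
}

#' Full evaluation report
#'
#' Computes all four restoration metrics for a clean/restored pair and
#' returns them with the parameters they were computed under (the IRI
#' window radius in particular, without which IRI values are not
#' comparable).
#'
#' @inheritParams iri
#' @param msssim compute [msssim_l()] too (needs sides >= 176; skipped with
#'   `NA` otherwise unless forced).
#' @return object of class `metric_report`: list with `psnr`, `mae`,
#'   `iri`, `mssim_l` and `params`.
#' @export
evaluate_restoration <- function(clean, restored, window_radius = 1,
                                 msssim = TRUE) {
  p <- check_pair(clean, restored)
  ml <- NA_real_
  if (msssim && min(dim(p$clean)[1:2]) >= 176)
    ml <- msssim_l(p$clean, p$restored)
  structure(
    list(psnr = psnr(p$clean, p$restored),
         mae = mae(p$clean, p$restored),
         iri = iri(p$clean, p$restored, window_radius),
         mssim_l = ml,
         params = list(iri_window_radius = window_radius)),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "  NA  " else
    if (is.infinite(v)) "  inf " else sprintf("%6.2f", v)
  cat("Restoration quality\n")
  cat("  PSNR:    ", fmt(x$psnr), " dB\n", sep = "")
  cat("  MSSIM_L: ", fmt(x$mssim_l), "\n", sep = "")
  cat("  IRI:     ", fmt(x$iri), " dB (window radius ",
      x$params$iri_window_radius, ")\n", sep = "")
  cat("  MAE:     ", fmt(x$mae), "\n", sep = "")
  invisible(x)
}
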