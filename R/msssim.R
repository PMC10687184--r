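# Multi-scale structural similarity (MS-SSIM), canonical settings:
# 5 scales with relative weights (0.0448, 0.2856, 0.3001, 0.2363, 0.1333),
# an 11 x 11 Gaussian window with std 1.5 ("valid" convolution), stability
# constants C1 = (0.01 L)^2, C2 = (0.03 L)^2 with L = 255, and dyadic
# downsampling by 2 x 2 averaging between scales.

gaussian_window <- function(size = 11L, sigma = 1.5) {
  d <- seq_len(size) - (size + 1) / 2
  g <- exp(-d^2 / (2 * sigma^2))
  g / sum(g)
}

# separable "valid" convolution of a matrix with a 1D kernel (rows then cols)
conv_valid <- function(m, k) {
  kl <- length(k)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h - kl + 1L, w)
  for (t in seq_len(kl)) out <- out + k[t] * m[t:(h - kl + t), , drop = FALSE]
  out2 <- matrix(0, nrow(out), w - kl + 1L)
  for (t in seq_len(kl)) out2 <- out2 + k[t] * out[, t:(w - kl + t), drop = FALSE]
  out2
}

downsample2 <- function(m) {
  h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  (m[seq(1L, h, 2L), seq(1L, w, 2L)] + m[seq(2L, h, 2L), seq(1L, w, 2L)] +
   m[seq(1L, h, 2L), seq(2L, w, 2L)] + m[seq(2L, h, 2L), seq(2L, w, 2L)]) / 4
}

# mean SSIM and mean contrast-structure term of one grayscale scale
ssim_scale <- function(a, b, k) {
  C1 <- (0.01 * 255)^2
  C2 <- (0.03 * 255)^2
  mu_a <- conv_valid(a, k); mu_b <- conv_valid(b, k)
  saa <- conv_valid(a * a, k) - mu_a^2
  sbb <- conv_valid(b * b, k) - mu_b^2
  sab <- conv_valid(a * b, k) - mu_a * mu_b
  cs <- (2 * sab + C2) / (saa + sbb + C2)
  l <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  c(ssim = mean(l * cs), cs = mean(cs))
}

#' Multi-scale SSIM
#'
#' MS-SSIM between two images with the canonical 5-scale settings (see
#' above), computed per channel and averaged over the three channels, or on
#' the luma channel alone with `luma = TRUE`.  Contrast-structure terms are
#' floored at zero before the weighted geometric pooling so that the
#' fractional exponents are defined.
#'
#' @inheritParams psnr
#' @param luma convert to luma (Rec. 601) and compute a single-channel
#'   score instead of the per-channel average.
#' @return MS-SSIM in [0, 1] (1 = identical).
#' @export
msssim <- function(clean, restored, luma = FALSE) {
  p <- check_pair(clean, restored)
  weights <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)
  nscales <- length(weights)
  if (min(dim(p$clean)[1:2]) < 11 * 2^(nscales - 1))
    stop("image too small for the 5-scale MS-SSIM pyramid (need >= 176 px per side)")
  k <- gaussian_window()
  one_channel <- function(a, b) {
    mcs <- numeric(nscales)
    for (l in seq_len(nscales)) {
      st <- ssim_scale(a, b, k)
      mcs[l] <- if (l < nscales) st["cs"] else st["ssim"]
      if (l < nscales) { a <- downsample2(a); b <- downsample2(b) }
    }
    prod(pmax(mcs, 0)^weights)
  }
  if (luma) {
    lw <- c(0.299, 0.587, 0.114)
    a <- lw[1] * p$clean[, , 1] + lw[2] * p$clean[, , 2] + lw[3] * p$clean[, , 3]
    b <- lw[1] * p$restored[, , 1] + lw[2] * p$restored[, , 2] +
         lw[3] * p$restored[, , 3]
    return(one_channel(a, b))
  }
  mean(vapply(1:3, function(q)
    one_channel(p$clean[, , q], p$restored[, , q]), numeric(1)))
}

#' Log-scaled multi-scale SSIM
#'
#' `MSSIM_L = -10 log10(1 - MS-SSIM)`, which spreads the compressed upper
#' range of MS-SSIM onto a dB-like scale; identical images give `Inf`.
#'
#' @inheritParams msssim
#' @return log-scaled score (higher is better).
#' @export
msssim_l <- function(clean, restored, luma = FALSE) {
  m <- msssim(clean, restored, luma = luma)
  if (m >= 1) return(Inf)
  -10 * log10(1 - m)
}
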