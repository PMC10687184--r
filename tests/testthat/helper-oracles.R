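# Fixtures are generated in code; oracles are deliberately naive
# (full matrices, explicit loops) and independent of the package internals.

random_image <- function(h, w, seed) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}

random_patch <- function(s = 1, seed = 1) {
  n <- (2 * s + 1)^2
  withr::with_seed(seed, matrix(runif(3 * n, 0, 255), n, 3))
}

constant_image <- function(h, w, rgb = c(60, 60, 60)) {
  array(rep(rgb, each = h * w), dim = c(h, w, 3))
}

# 128 x 128 phantom combining a step edge with disks, used for the
# end-to-end efficacy fixture
step_disks_phantom <- function(size = c(128, 128), seed = 3) {
  st <- make_phantom("step-edge", size = size)
  dk <- make_phantom("disks", size = size, seed = seed, k = 4)
  bg <- dk[1, 1, ] # disk phantom background color
  on_disk <- !(dk[, , 1] == bg[1] & dk[, , 2] == bg[2] & dk[, , 3] == bg[3])
  for (q in 1:3) st[, , q] <- ifelse(on_disk, dk[, , q], st[, , q])
  st
}

# brute-force trimmed dissimilarity: full n x n squared-distance matrix,
# full sorts at both levels
brute_delta <- function(wj, wi, alpha, beta) {
  n <- nrow(wj)
  dm <- matrix(0, n, n)
  for (u in seq_len(n)) for (k in seq_len(n))
    dm[u, k] <- sum((wj[u, ] - wi[k, ])^2)
  rv <- numeric(n)
  for (u in seq_len(n)) rv[u] <- mean(sort(dm[u, ])[seq_len(alpha)])
  ord <- order(rv)
  list(delta = mean(rv[ord[seq_len(beta)]]), selected = ord[seq_len(beta)],
       r_values = rv)
}

# naive per-window minimum oracle for the impulse removal index
iri_oracle <- function(clean, restored, wr) {
  h <- dim(clean)[1]; w <- dim(clean)[2]
  pc <- pad_image(clean, wr)
  tot <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    best <- Inf
    for (dr in -wr:wr) for (dc in -wr:wr) {
      o <- pc[wr + i + dr, wr + j + dc, ]
      best <- min(best, sum((restored[i, j, ] - o)^2))
    }
    tot <- tot + best
  }
  mse_r <- tot / (3 * h * w)
  if (mse_r == 0) Inf else 10 * log10(255^2 / mse_r)
}

# independent R implementation of the MINOR recursion (any alpha, beta),
# driven by the R-level dissimilarity functions; only usable on tiny images
minor_oracle <- function(image, s, r, alpha, beta, sigma,
                         mode = c("global", "standard")) {
  mode <- match.arg(mode)
  h <- dim(image)[1]; w <- dim(image)[2]
  n <- (2 * s + 1)^2
  m <- r + 2 * s
  pad <- pad_image(image, m)
  off <- cbind(rep(-s:s, each = 2 * s + 1), rep(-s:s, times = 2 * s + 1))
  out <- array(0, dim = dim(image))
  for (i0 in seq_len(h)) for (j0 in seq_len(w)) {
    ip <- c(i0 + m, j0 + m)
    num <- matrix(0, n, 3); den <- numeric(n)
    for (v in seq_len(n)) {
      cc <- ip + off[v, ]
      wc <- extract_patch(pad, cc, s)
      vh <- n + 1 - v
      for (jb in seq_len((2 * r + 1)^2)) {
        joff <- cbind(rep(-r:r, each = 2 * r + 1),
                      rep(-r:r, times = 2 * r + 1))[jb, ]
        jc <- cc + joff
        wj <- extract_patch(pad, jc, s)
        tm <- robust_patch_dissimilarity(wj, wc, alpha, beta)
        if (!(vh %in% tm$selected)) next
        wgt <- exp(-tm$delta / sigma^2)
        num[v, ] <- num[v, ] + wgt * pad[jc[1] + off[vh, 1],
                                         jc[2] + off[vh, 2], ]
        den[v] <- den[v] + wgt
      }
    }
    est <- if (mode == "global") {
      if (sum(den) > 0) colSums(num) / sum(den) else image[i0, j0, ]
    } else {
      ok <- den > 0
      if (any(ok)) colMeans(num[ok, , drop = FALSE] / den[ok]) else
        image[i0, j0, ]
    }
    out[i0, j0, ] <- est
  }
  out
}

rotate90 <- function(img) {
  # counter-clockwise rotation of an H x W x 3 array
  h <- dim(img)[1]; w <- dim(img)[2]
  out <- array(0, dim = c(w, h, 3))
  for (q in 1:3) out[, , q] <- t(img[, , q])[w:1, , drop = FALSE]
  out
}
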