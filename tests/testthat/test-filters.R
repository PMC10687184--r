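test_that("every filter is the identity on constant images", {
  flat <- constant_image(12, 12, c(37, 120, 201))
  runs <- list(
    minor_filter(flat, s = 1, r = 2, alpha = 4, beta = 5, sigma = 40),
    minor_filter(flat, s = 1, r = 2, alpha = 2, beta = 9, sigma = 20,
                 mode = "standard"),
    nlm_filter(flat, s = 1, r = 2, sigma = 50, mode = "pixelwise"),
    nlm_filter(flat, s = 1, r = 2, sigma = 50, mode = "patchwise"),
    nlm_filter(flat, s = 1, r = 2, sigma = 50, mode = "global"),
    bilateral_filter(flat, r = 2, sigma_s = 2, sigma_r = 30))
  for (res in runs)
    expect_lt(max(abs(res$image - flat)), 1e-9)
})

test_that("filter outputs are convex combinations within [0, 255]", {
  noisy <- add_mgin(random_image(16, 16, seed = 1), 50, seed = 2)$image
  for (res in list(
    minor_filter(noisy, r = 2),
    nlm_filter(noisy, r = 2, mode = "patchwise"),
    bilateral_filter(noisy, r = 2))) {
    expect_true(all(res$image >= 0 & res$image <= 255))
    expect_gte(min(res$image), min(noisy) - 1e-9)
    expect_lte(max(res$image), max(noisy) + 1e-9)
  }
})

test_that("filters commute with quarter-turn rotation", {
  noisy <- add_mgin(make_phantom("checker", size = c(16, 16)), 30,
                    seed = 5)$image
  apply_all <- function(img) list(
    nlm_filter(img, r = 2, sigma = 60, mode = "pixelwise")$image,
    nlm_filter(img, r = 2, sigma = 60, mode = "global")$image,
    bilateral_filter(img, r = 2)$image)
  direct <- apply_all(noisy)
  rotated <- apply_all(rotate90(noisy))
  for (k in seq_along(direct))
    expect_lt(max(abs(rotate90(direct[[k]]) - rotated[[k]])), 1e-9)
})

test_that("MINOR commutes with rotation away from the padded border", {
  # reflect padding duplicates border pixels, which ties the trimmed R
  # values there; the deterministic index tie-break is not rotation
  # covariant, so exact equivariance holds on the interior only
  noisy <- add_mgin(make_phantom("checker", size = c(16, 16)), 30,
                    seed = 5)$image
  keep <- 5:12 # exclude the r + 2s = 4 border band
  for (mode in c("global", "standard")) {
    f <- function(im) minor_filter(im, r = 2, alpha = 4, beta = 5,
                                   sigma = 40, mode = mode)$image
    d <- rotate90(f(noisy)) - f(rotate90(noisy))
    expect_lt(max(abs(d[keep, keep, ])), 1e-9, label = mode)
  }
})

test_that("bilateral limits: Gaussian convolution and range filter", {
  img <- random_image(14, 14, seed = 3)
  r <- 3; ss <- 2; sr <- 25
  off <- expand.grid(dr = -r:r, dc = -r:r)
  pad <- pad_image(img, r)
  shift <- function(d) pad[r + d[1] + seq_len(14), r + d[2] + seq_len(14), ,
                           drop = FALSE]
  # sigma_r -> infinity: plain Gaussian convolution over the block
  conv <- array(0, dim = dim(img)); z <- 0
  for (k in seq_len(nrow(off))) {
    w <- exp(-(off$dr[k]^2 + off$dc[k]^2) / ss^2)
    conv <- conv + w * shift(c(off$dr[k], off$dc[k])); z <- z + w
  }
  got <- bilateral_filter(img, r = r, sigma_s = ss, sigma_r = 1e12)$image
  expect_lt(max(abs(got - conv / z)), 1e-6)

  # sigma_s -> infinity: Yaroslavsky-type range filter
  num <- array(0, dim = dim(img)); den <- array(0, dim = dim(img)[1:2])
  for (k in seq_len(nrow(off))) {
    sh <- shift(c(off$dr[k], off$dc[k]))
    d2 <- (sh[, , 1] - img[, , 1])^2 + (sh[, , 2] - img[, , 2])^2 +
          (sh[, , 3] - img[, , 3])^2
    w <- exp(-d2 / sr^2)
    for (q in 1:3) num[, , q] <- num[, , q] + w * sh[, , q]
    den <- den + w
  }
  got2 <- bilateral_filter(img, r = r, sigma_s = 1e12, sigma_r = sr)$image
  expect_lt(max(abs(got2 - num / rep(den, 3))), 1e-6)

  expect_error(bilateral_filter(img, sigma_s = 0), "sigma_s")
  expect_error(bilateral_filter(img, sigma_r = -2), "sigma_r")
})

test_that("single-pixel patches reduce pixelwise NLM to range filtering", {
  img <- random_image(10, 10, seed = 4)
  r <- 2; sg <- 40
  got <- nlm_filter(img, s = 0, r = r, sigma = sg, mode = "pixelwise",
                    central_weight = "raw")$image
  pad <- pad_image(img, r)
  num <- array(0, dim = dim(img)); den <- array(0, dim = dim(img)[1:2])
  for (dr in -r:r) for (dc in -r:r) {
    sh <- pad[r + dr + seq_len(10), r + dc + seq_len(10), , drop = FALSE]
    d2 <- (sh[, , 1] - img[, , 1])^2 + (sh[, , 2] - img[, , 2])^2 +
          (sh[, , 3] - img[, , 3])^2
    w <- exp(-d2 / sg^2)
    for (q in 1:3) num[, , q] <- num[, , q] + w * sh[, , q]
    den <- den + w
  }
  expect_lt(max(abs(got - num / rep(den, 3))), 1e-9)
})

test_that("patchwise and global NLM differ on noise, agree on constants", {
  noisy <- add_mgin(make_phantom("step-edge", size = c(12, 12)), 30,
                    seed = 9)$image
  pw <- nlm_filter(noisy, r = 2, sigma = 60, mode = "patchwise")$image
  gl <- nlm_filter(noisy, r = 2, sigma = 60, mode = "global")$image
  expect_gt(max(abs(pw - gl)), 0.01)
  flat <- constant_image(12, 12)
  expect_lt(max(abs(nlm_filter(flat, r = 2, mode = "patchwise")$image -
                    nlm_filter(flat, r = 2, mode = "global")$image)), 1e-9)
})

test_that("MINOR core matches an independent R implementation", {
  noisy <- add_mgin(make_phantom("step-edge", size = c(8, 8)), 40,
                    seed = 13)$image
  for (mode in c("global", "standard")) {
    got <- minor_filter(noisy, s = 1, r = 1, alpha = 4, beta = 5, sigma = 40,
                        mode = mode)$image
    ref <- minor_oracle(noisy, s = 1, r = 1, alpha = 4, beta = 5, sigma = 40,
                        mode = mode)
    expect_lt(max(abs(got - ref)), 1e-9, label = mode)
  }
})

test_that("alpha = beta = n collapses MINOR to mean-distance NLM weighting", {
  # with full trim counts the selection gate passes everything and the
  # weight uses the grand mean of pairwise distances; checked against the
  # same independent oracle in that limit
  noisy <- add_mgin(make_phantom("gradient", size = c(8, 8)), 30,
                    seed = 17)$image
  got <- minor_filter(noisy, s = 1, r = 1, alpha = 9, beta = 9,
                      sigma = 60)$image
  ref <- minor_oracle(noisy, s = 1, r = 1, alpha = 9, beta = 9, sigma = 60)
  expect_lt(max(abs(got - ref)), 1e-9)
})

test_that("MINOR removes an isolated impulse that pixelwise NLM retains", {
  flat <- constant_image(32, 32, c(60, 60, 60))
  imp <- flat; imp[16, 16, ] <- c(250, 250, 250)
  pars <- recommended_params(30, "minor")
  got <- minor_filter(imp, s = pars$s, r = pars$r, alpha = pars$alpha,
                      beta = pars$beta, sigma = pars$sigma)$image
  expect_lt(max(abs(got[16, 16, ] - 60)), 1)
  raw <- nlm_filter(imp, s = 1, r = 6, sigma = 40, mode = "pixelwise",
                    central_weight = "raw")$image
  expect_gt(raw[16, 16, 1], 60 + 0.5 * 190)
  # the usual remedy: substituting the self-weight removes it again
  fixed <- nlm_filter(imp, s = 1, r = 6, sigma = 40, mode = "pixelwise",
                      central_weight = "max")$image
  expect_lt(max(abs(fixed[16, 16, ] - 60)), 5)
})

test_that("weight thresholding and the empty-set fallback are accounted", {
  noisy <- add_mgin(random_image(8, 8, seed = 21), 50, seed = 22)$image
  res <- minor_filter(noisy, r = 1, weight_threshold = 2) # w <= 1 always
  expect_equal(res$fallback, 64L)
  expect_equal(res$image, noisy) # untouched pass-through
  res2 <- minor_filter(noisy, r = 1)
  expect_equal(res2$fallback, 0L)
  expect_true(all(res2$z > 0))
})

test_that("iterated filtering re-applies the filter to its own output", {
  noisy <- add_mgin(make_phantom("step-edge", size = c(10, 10)), 50,
                    seed = 23)$image
  once <- minor_filter(noisy, r = 2)
  twice <- minor_filter(noisy, r = 2, iterations = 2)
  manual <- minor_filter(once$image, r = 2)
  expect_equal(twice$image, manual$image, tolerance = 1e-12)
})

test_that("recommended parameter presets match the published table", {
  expect_equal(recommended_params(30, "minor"),
               list(s = 1L, r = 6L, alpha = 4L, beta = 5L, sigma = 40))
  expect_equal(recommended_params(10, "minor"),
               list(s = 1L, r = 1L, alpha = 2L, beta = 5L, sigma = 20))
  expect_equal(recommended_params(50, "minor"),
               list(s = 1L, r = 12L, alpha = 4L, beta = 5L, sigma = 40))
  n50 <- recommended_params(50, "nlm")
  expect_equal(n50$s, 3L); expect_equal(n50$r, 17L)
  expect_equal(recommended_params(10, "nlm")[c("s", "r")],
               list(s = 1L, r = 10L))
  expect_warning(p <- recommended_params(25, "minor"), "nearest")
  expect_equal(p$r, 6L)
})

test_that("denoise_result exposes its diagnostics", {
  res <- minor_filter(constant_image(8, 8), r = 1)
  expect_s3_class(res, "denoise_result")
  expect_output(print(res), "MINOR_G")
  expect_output(summary(res), "empty contribution")
  expect_equal(dim(res$z), c(8L, 8L))
})
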