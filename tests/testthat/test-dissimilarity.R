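test_that("SSD patch distance matches direct arithmetic and a loop oracle", {
  w1 <- random_patch(seed = 1)
  expect_equal(ssd_patch_distance(w1, w1), 0)
  expect_equal(ssd_patch_distance(w1 + 1, w1), 27) # 9 pixels x 3 channels x 1^2
  w2 <- random_patch(seed = 2)
  loop <- 0
  for (v in 1:9) loop <- loop + sum((w1[v, ] - w2[v, ])^2)
  expect_equal(ssd_patch_distance(w1, w2), loop)
  expect_error(ssd_patch_distance(w1, random_patch(s = 2)), "identical")
})

test_that("trimmed pixel-to-patch distance averages the alpha nearest", {
  wi <- random_patch(seed = 3)
  # a pixel duplicated inside the patch is at distance zero for alpha = 1
  expect_equal(trimmed_pixel_distance(wi[4, ], wi, alpha = 1), 0)
  x <- c(10, 200, 30)
  d2 <- apply(wi, 1, function(p) sum((p - x)^2))
  for (a in c(1, 3, 9))
    expect_equal(trimmed_pixel_distance(x, wi, a), mean(sort(d2)[1:a]))
  # alpha = n is the mean squared distance to the whole patch
  expect_equal(trimmed_pixel_distance(x, wi, 9), mean(d2))
  # non-decreasing in alpha
  rs <- vapply(1:9, function(a) trimmed_pixel_distance(x, wi, a), numeric(1))
  expect_true(all(diff(rs) >= 0))
  expect_error(trimmed_pixel_distance(x, wi, 0), "alpha")
  expect_error(trimmed_pixel_distance(x, wi, 10), "alpha")
})

test_that("robust dissimilarity keeps its trimmed-window bookkeeping", {
  wj <- random_patch(seed = 4); wi <- random_patch(seed = 5)
  tm <- robust_patch_dissimilarity(wj, wi, alpha = 4, beta = 5)
  expect_s3_class(tm, "trimmed_match")
  expect_length(tm$selected, 5)
  expect_length(tm$r_values, 9)
  expect_true(all(tm$r_values >= 0))
  expect_equal(tm$delta, mean(sort(tm$r_values)[1:5]))
  # selected indices are those of the smallest R values, ascending R
  expect_equal(tm$selected, order(tm$r_values)[1:5])
})

test_that("constant identical patches are at zero dissimilarity", {
  flat <- matrix(100, 9, 3)
  for (a in c(1, 4, 9)) for (b in c(1, 5, 9))
    expect_equal(robust_patch_dissimilarity(flat, flat, a, b)$delta, 0)
})

test_that("alpha = beta = n recovers the grand mean of all pairwise distances", {
  wj <- random_patch(seed = 6); wi <- random_patch(seed = 7)
  dm <- outer(1:9, 1:9, Vectorize(function(u, k) sum((wj[u, ] - wi[k, ])^2)))
  expect_equal(robust_patch_dissimilarity(wj, wi, 9, 9)$delta, mean(dm))
})

test_that("robust dissimilarity agrees with the brute-force oracle", {
  for (seed in 1:50) {
    wj <- random_patch(seed = 2 * seed)
    wi <- random_patch(seed = 2 * seed + 1)
    ab <- withr::with_seed(seed, c(sample(9, 1), sample(9, 1)))
    got <- robust_patch_dissimilarity(wj, wi, ab[1], ab[2])
    ref <- brute_delta(wj, wi, ab[1], ab[2])
    expect_equal(got$delta, ref$delta, tolerance = 1e-12)
    expect_identical(got$selected, ref$selected)
  }
})

test_that("dissimilarity grows with beta and is directional", {
  wj <- random_patch(seed = 8); wi <- random_patch(seed = 9)
  deltas <- vapply(1:9, function(b)
    robust_patch_dissimilarity(wj, wi, 4, b)$delta, numeric(1))
  expect_true(all(diff(deltas) >= 0))
  # directional: no symmetry claimed (or present, generically)
  d_ji <- robust_patch_dissimilarity(wj, wi, 4, 5)$delta
  d_ij <- robust_patch_dissimilarity(wi, wj, 4, 5)$delta
  expect_false(isTRUE(all.equal(d_ji, d_ij)))
})

test_that("trimming suppresses a single extreme outlier", {
  base <- random_patch(seed = 10)
  wj <- base; wi <- base
  wj[3, ] <- c(255, 255, 255); wi[7, ] <- c(0, 255, 0) # impulses
  trimmed <- robust_patch_dissimilarity(wj, wi, 8, 8)$delta
  full <- robust_patch_dissimilarity(wj, wi, 9, 9)$delta
  expect_lt(trimmed, full)
})

test_that("a non-constant patch is not at zero dissimilarity from itself", {
  wi <- random_patch(seed = 11)
  expect_gt(robust_patch_dissimilarity(wi, wi, 2, 5)$delta, 0)
  expect_gt(robust_patch_dissimilarity(wi, wi, 9, 9)$delta, 0)
  # with alpha = 1 every pixel finds itself: delta collapses to zero
  expect_equal(robust_patch_dissimilarity(wi, wi, 1, 5)$delta, 0)
})
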