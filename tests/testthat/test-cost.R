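test_that("grayscale conversion uses the BT.601 luminance weights", {
  white <- array(1, c(2, 2, 3))
  expect_equal(to_grayscale(white), matrix(1, 2, 2))
  red <- array(0, c(2, 2, 3)); red[, , 1] <- 1
  expect_equal(to_grayscale(red), matrix(0.299, 2, 2))
  img <- rand_rgb(6, 5, seed = 10)
  manual <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  expect_equal(to_grayscale(img), manual)
})

test_that("sobel_x responds to ramps with the slope and to constants with zero", {
  expect_equal(sobel_x(matrix(0.4, 5, 8)), matrix(0, 5, 8))
  w <- 10
  ramp <- matrix(rep((0:(w - 1)) / w, each = 4), 4, w)
  g <- sobel_x(ramp)
  expect_equal(g[, 2:(w - 1)], matrix(1 / w, 4, w - 2))
})

test_that("sobel_x equals explicit 3x3 convolution at interior pixels", {
  m <- rand_mat(5, 5, seed = 11)
  g <- sobel_x(m)
  k <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # columns: x-1, x, x+1
  for (i in 2:4) for (j in 2:4)
    expect_equal(g[i, j], sum(m[(i - 1):(i + 1), (j - 1):(j + 1)] * k) / 8)
  expect_error(sobel_x(matrix(0, 2, 5)), "3 x 3")
})

test_that("colour cost is the channel-summed absolute difference at offset d", {
  left <- rand_rgb(6, 12, seed = 12)
  pair0 <- stereo_pair(left, left)
  expect_equal(color_cost(pair0, 0), matrix(0, 6, 12))

  right <- rand_rgb(6, 12, seed = 13)
  pair <- stereo_pair(left, right)
  for (d in 0:3) {
    got <- color_cost(pair, d, TM = 0.5)
    for (i in 1:6) for (j in 1:12) {
      expected <- if (j - d < 1) 0.5 else sum(abs(left[i, j, ] - right[i, j - d, ]))
      expect_equal(got[i, j], expected)
    }
  }
})

test_that("a single-pixel colour difference matches the hand-computed sum", {
  left <- array(0.5, c(3, 3, 3)); right <- array(0.5, c(3, 3, 3))
  left[2, 2, ] <- c(0.1, 0.2, 0.3)
  right[2, 2, ] <- c(0.12, 0.18, 0.33)
  pair <- stereo_pair(left, right)
  expect_equal(color_cost(pair, 0)[2, 2], 0.02 + 0.02 + 0.03)
})

test_that("gradient cost vanishes on self-matches and equals its re-computation", {
  flat <- array(0.3, c(5, 10, 3))
  # the d leftmost columns have no counterpart and take the ceiling TG
  exp_flat <- matrix(0, 5, 10); exp_flat[, 1:2] <- 0.0078
  expect_equal(gradient_cost(stereo_pair(flat, flat), 2), exp_flat)
  left <- rand_rgb(6, 12, seed = 14)
  expect_equal(gradient_cost(stereo_pair(left, left), 0), matrix(0, 6, 12))

  right <- rand_rgb(6, 12, seed = 15)
  pair <- stereo_pair(left, right)
  gl <- sobel_x(to_grayscale(left)); gr <- sobel_x(to_grayscale(right))
  for (d in c(0, 2)) {
    got <- gradient_cost(pair, d, TG = 0.05)
    for (i in 1:6) for (j in 1:12) {
      expected <- if (j - d < 1) 0.05 else abs(gl[i, j] - gr[i, j - d])
      expect_equal(got[i, j], expected)
    }
  }
})

test_that("combined cost blends the truncated terms with weight alpha", {
  # direct evaluation: alpha 0.1, M = 0.50 truncated at TM = 0.30,
  # G = 0.005 below TG = 0.010
  expect_equal(0.1 * min(0.30, 0.50) + 0.9 * min(0.010, 0.005), 0.0345)

  left <- rand_rgb(8, 14, seed = 16)
  right <- rand_rgb(8, 14, seed = 17)
  pair <- stereo_pair(left, right)
  p <- aswi_params(d_min_global = 0L, d_max_global = 5L)
  vol <- combined_cost(pair, c(0, 5), p)
  for (k in 1:6) {
    d <- k - 1
    m <- color_cost(pair, d, TM = p$TM)
    g <- gradient_cost(pair, d, TG = p$TG)
    expect_equal(vol$costs[, , k],
                 p$alpha * pmin(m, p$TM) + (1 - p$alpha) * pmin(g, p$TG))
  }
  # identical pair at d = 0 gives the zero plane
  vol0 <- combined_cost(stereo_pair(left, left), c(0, 3),
                        aswi_params(d_max_global = 3L))
  expect_equal(vol0$costs[, , 1], matrix(0, 8, 14))
})

test_that("all computed costs respect the truncation ceiling and positivity", {
  pair <- stereo_pair(rand_rgb(8, 14, seed = 18), rand_rgb(8, 14, seed = 19))
  p <- aswi_params(d_max_global = 6L)
  vol <- combined_cost(pair, c(0, 6), p)
  expect_gte(min(vol$costs), 0)
  expect_lte(max(vol$costs), p$alpha * p$TM + (1 - p$alpha) * p$TG + 1e-15)
})

test_that("raising the truncation thresholds never decreases a cost", {
  pair <- stereo_pair(rand_rgb(8, 14, seed = 20), rand_rgb(8, 14, seed = 21))
  lo <- combined_cost(pair, c(0, 4),
                      aswi_params(TM = 0.05, TG = 0.004, d_max_global = 4L))
  hi <- combined_cost(pair, c(0, 4),
                      aswi_params(TM = 0.10, TG = 0.008, d_max_global = 4L))
  expect_true(all(hi$costs >= lo$costs - 1e-15))
})

test_that("a masked volume equals the full volume wherever the mask covers", {
  pair <- stereo_pair(rand_rgb(10, 16, seed = 22), rand_rgb(10, 16, seed = 23))
  p <- aswi_params(d_max_global = 8L)
  full <- combined_cost(pair, c(0, 8), p)
  set.seed(24)
  lo <- matrix(sample(0:4, 160, replace = TRUE), 10, 16)
  hi <- lo + matrix(sample(0:4, 160, replace = TRUE), 10, 16)
  mask <- range_mask(lo, pmin(hi, 8L))
  masked <- combined_cost(pair, c(0, 8), p, mask = mask)
  for (k in 1:9) {
    d <- k - 1
    covered <- mask$lo <= d & d <= mask$hi
    expect_equal(masked$valid[, , k], covered)
    expect_equal(masked$costs[, , k][covered], full$costs[, , k][covered])
  }
  # the all-pixels full-range mask reproduces the unmasked volume entrywise
  fullmask <- range_mask(matrix(0L, 10, 16), matrix(8L, 10, 16))
  expect_identical(combined_cost(pair, c(0, 8), p, mask = fullmask)$costs,
                   full$costs)
})
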