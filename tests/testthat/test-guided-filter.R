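test_that("box filter preserves constants and has the exact impulse response", {
  expect_equal(box_filter(matrix(0.7, 9, 13), 2), matrix(0.7, 9, 13))
  imp <- matrix(0, 7, 7); imp[4, 4] <- 1
  got <- box_filter(imp, 1)
  expected <- matrix(0, 7, 7); expected[3:5, 3:5] <- 1 / 9
  expect_equal(got, expected)
})

test_that("box filter equals the naive windowed mean on random images", {
  for (case in list(c(16, 16, 3), c(11, 7, 2), c(5, 20, 4))) {
    m <- rand_mat(case[1], case[2], seed = sum(case))
    expect_equal(box_filter(m, case[3]), naive_box_mean(m, case[3]),
                 tolerance = 1e-12)
  }
  expect_error(box_filter(matrix(0, 4, 4), 9), "radius")
})

test_that("scalar guided filter preserves constants and hits the large-eps limit", {
  const <- matrix(0.42, 10, 10)
  expect_equal(guided_filter_gray(const, const, 2, 1e-4), const,
               tolerance = 1e-12)
  guide <- rand_mat(12, 12, seed = 30)
  input <- rand_mat(12, 12, seed = 31)
  # eps -> infinity: a -> 0, b -> window mean, output -> double box filter
  expect_equal(guided_filter_gray(guide, input, 2, 1e6),
               box_filter(box_filter(input, 2), 2), tolerance = 1e-6)
})

test_that("scalar guided filter matches the explicit per-window kernel oracle", {
  for (seed in c(32, 33)) {
    guide <- rand_mat(12, 12, seed = seed)
    input <- rand_mat(12, 12, seed = seed + 100)
    expect_equal(guided_filter_gray(guide, input, 2, 1e-3),
                 naive_guided_gray(guide, input, 2, 1e-3), tolerance = 1e-8)
  }
  expect_error(guided_filter_gray(matrix(0, 3, 3), matrix(0, 4, 4), 1, 1e-3),
               "dimensions")
})

test_that("colour guided filter with identical channels reduces to the scalar one", {
  g <- rand_mat(12, 12, seed = 34)
  guide <- array(rep(g, 3), c(12, 12, 3))
  input <- rand_mat(12, 12, seed = 35)
  # with three identical channels the rank-1 covariance plus eps*I gives a
  # total coefficient cov/(v + eps/3): the scalar filter at eps/3
  eps <- 3e-3
  expect_equal(guided_filter_color(guide, input, 2, eps),
               guided_filter_gray(g, input, 2, eps / 3), tolerance = 1e-10)
})

test_that("colour guided filter preserves constants and the guide's edges", {
  guide <- rand_rgb(10, 10, seed = 36)
  expect_equal(guided_filter_color(guide, matrix(0.3, 10, 10), 2, 1e-4),
               matrix(0.3, 10, 10), tolerance = 1e-9)
  # step guide, smooth (linear) input: output jumps only at the guide's step
  h <- 12; w <- 20
  step <- array(0.2, c(h, w, 3)); step[, 11:w, ] <- 0.8
  input <- matrix(rep(seq(0, 1, length.out = w), each = h), h, w)
  out <- guided_filter_color(step, input, 3, 1e-4)
  jumps <- abs(out[, -1] - out[, -w])
  at_step <- jumps[, 10]
  away <- jumps[, c(3:7, 14:18)]
  expect_gt(min(at_step), 5 * max(away))
  expect_error(guided_filter_color(step, input, 3, 0), "eps")
})

test_that("cost-volume smoothing filters each slice independently with the guide", {
  pair <- stereo_pair(rand_rgb(10, 14, seed = 37), rand_rgb(10, 14, seed = 38))
  p <- aswi_params(er = 2L, br = 2L, d_max_global = 3L)
  vol <- combined_cost(pair, c(0, 3), p)
  sm <- smooth_cost_volume(vol, pair$left, p)
  for (k in 1:4)
    expect_equal(sm$costs[, , k],
                 guided_filter_color(pair$left, vol$costs[, , k], p$br, p$eps))
  # identical slices smooth to identical slices
  vol2 <- vol
  for (k in 2:4) vol2$costs[, , k] <- vol2$costs[, , 1]
  sm2 <- smooth_cost_volume(vol2, pair$left, p)
  for (k in 2:4) expect_equal(sm2$costs[, , k], sm2$costs[, , 1])
})

test_that("full-range stage masks leave the smoothed volume untouched", {
  pair <- stereo_pair(rand_rgb(10, 14, seed = 39), rand_rgb(10, 14, seed = 40))
  p <- aswi_params(er = 2L, br = 2L, d_max_global = 3L)
  full <- range_mask(matrix(0L, 10, 14), matrix(3L, 10, 14), "y2")
  vol <- combined_cost(pair, c(0, 3), p)
  expect_identical(smooth_cost_volume(vol, pair$left, p)$costs,
                   smooth_cost_volume(vol, pair$left, p, stage_mask = full)$costs)
  expect_identical(smooth_cost_volume(vol, pair$left, p, stage_mask = full)$valid,
                   vol$valid)
})
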