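test_that("stage radii follow the separable-convolution reach rules", {
  expect_equal(stage_radii(7, 7, "x1"), c(14, 21))
  expect_equal(stage_radii(7, 7, "y1"), c(14, 14))
  expect_equal(stage_radii(7, 7, "x2"), c(7, 14))
  expect_equal(stage_radii(7, 7, "y2"), c(7, 7))
  expect_error(stage_radii(7, 7, "z9"), "stage")
  # earlier stages always reach at least as far as later ones
  set.seed(60)
  for (i in 1:20) {
    er <- sample(1:9, 1); br <- sample(1:9, 1)
    expect_true(all(stage_radii(er, br, "x1") >= stage_radii(er, br, "y1")))
    expect_true(all(stage_radii(er, br, "y1") >= stage_radii(er, br, "x2")))
    expect_true(all(stage_radii(er, br, "x2") >= stage_radii(er, br, "y2")))
  }
})

test_that("range masks bracket the previous map's window extremes plus the offset", {
  p <- aswi_params(er = 2L, br = 2L, d_offset = 2L, d_max_global = 20L)
  const <- disparity_map(matrix(10, 8, 8))
  m <- build_range_mask(const, "y2", p)
  expect_equal(m$lo, matrix(8, 8, 8))
  expect_equal(m$hi, matrix(12, 8, 8))

  step <- matrix(5, 8, 12); step[, 7:12] <- 20
  ms <- build_range_mask(disparity_map(step), "y2",
                         aswi_params(er = 2L, br = 2L, d_offset = 2L,
                                     d_max_global = 25L))
  expect_equal(ms$lo[4, 6], 5 - 2)   # window straddles the step
  expect_equal(ms$hi[4, 6], 20 + 2)

  holey <- matrix(3, 4, 4); holey[2, 2] <- NA
  expect_error(build_range_mask(disparity_map(holey), "y2", p), "valid")
})

test_that("range masks agree with the exhaustive window min/max scan", {
  p <- aswi_params(er = 2L, br = 3L, d_offset = 1L, d_max_global = 30L)
  set.seed(61)
  prev <- disparity_map(matrix(runif(14 * 18, 0, 25), 14, 18))
  for (stage in c("x1", "y1", "x2", "y2")) {
    m <- build_range_mask(prev, stage, p)
    r <- stage_radii(p$er, p$br, stage)
    lo <- pmax(naive_window_extreme(round(prev$d), r[1], r[2], min) - 1, 0)
    hi <- pmin(naive_window_extreme(round(prev$d), r[1], r[2], max) + 1, 30)
    expect_equal(m$lo, lo)
    expect_equal(m$hi, hi)
    # containment of the previous disparity is guaranteed by construction
    expect_true(all(prev$d >= m$lo & prev$d <= m$hi))
  }
})

test_that("the merged mask is the per-pixel envelope of its inputs", {
  set.seed(62)
  masks <- lapply(1:4, function(i) {
    lo <- matrix(sample(0:6, 30, replace = TRUE), 5, 6)
    range_mask(lo, lo + matrix(sample(0:6, 30, replace = TRUE), 5, 6))
  })
  m <- merge_range_masks(masks)
  for (k in 1:4) {
    expect_true(all(m$lo <= masks[[k]]$lo))
    expect_true(all(m$hi >= masks[[k]]$hi))
  }
  expect_equal(m$lo, Reduce(pmin, lapply(masks, `[[`, "lo")))
  expect_equal(m$hi, Reduce(pmax, lapply(masks, `[[`, "hi")))
  # idempotence on identical inputs
  same <- merge_range_masks(list(masks[[1]], masks[[1]], masks[[1]], masks[[1]]))
  expect_equal(same$lo, masks[[1]]$lo)
  expect_equal(same$hi, masks[[1]]$hi)
})

test_that("a static scene reaches a bitwise fixed point after warm-up", {
  spec <- scene_spec(height = 28, width = 40, surface = "plane", d_base = 6,
                     d_amplitude = 0, texture = "noise", seed = 63,
                     n_frames = 4, d_max_global = 12)
  frames <- lapply(generate_scene(spec), `[[`, "pair")
  p <- test_params(warmup_frames = 1L)
  out <- aswi_sequence(frames, p)
  expect_false(attr(out[[1]], "masked"))
  expect_true(attr(out[[2]], "masked"))
  expect_identical(out[[3]]$d, out[[4]]$d)
})

test_that("drifting scenes stay inside the masks when drift <= d_offset", {
  spec <- scene_spec(height = 28, width = 40, surface = "plane", d_base = 4,
                     d_amplitude = 0, drift_per_frame = 1, n_frames = 4,
                     texture = "noise", seed = 64, d_max_global = 16)
  frames <- generate_scene(spec)
  p <- test_params(warmup_frames = 1L)
  out <- aswi_sequence(lapply(frames, `[[`, "pair"), p)
  stages <- c("x1", "y1", "x2", "y2")
  for (t in 2:4) {
    prev <- disparity_map(out[[t - 1]]$d, out[[t - 1]]$valid)
    masks <- lapply(stages, build_range_mask, prev = prev, params = p)
    m <- merge_range_masks(masks)
    gt <- frames[[t]]$gt_disparity
    expect_true(all(gt >= m$lo & gt <= m$hi))
    ok <- out[[t]]$valid & !frames[[t]]$occluded
    expect_lt(disparity_mae(out[[t]]$d, gt, ok), 0.5)
  }
})

test_that("masked runs compute no more cost entries than the full range", {
  fr <- plane_fixture(d = 6, h = 24, w = 36)
  p <- test_params()
  first <- aswi_match(fr$pair, p)
  prev <- disparity_map(first$d, first$valid)
  stages <- c("x1", "y1", "x2", "y2")
  masks <- setNames(lapply(stages, build_range_mask, prev = prev, params = p),
                    stages)
  merged <- merge_range_masks(masks)
  vol <- combined_cost(fr$pair, c(0, 12), p, mask = merged)
  expect_lt(sum(vol$valid), prod(dim(vol$costs)))
})

test_that("iterating a single pair once equals matching with its own masks", {
  fr <- plane_fixture(d = 7, h = 24, w = 36)
  p <- test_params(warmup_frames = 1L)
  out <- aswi_sequence(list(fr$pair, fr$pair), p)
  first <- aswi_match(fr$pair, p)
  prev <- disparity_map(first$d, first$valid)
  stages <- c("x1", "y1", "x2", "y2")
  masks <- setNames(lapply(stages, build_range_mask, prev = prev, params = p),
                    stages)
  second <- aswi_match(fr$pair, p, masks = masks)
  expect_identical(out[[2]]$d, second$d)
})
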