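# Running mean along rows (window of half-width r over columns), with
# shrinking windows at the borders normalised by the true in-bounds count.
row_mean <- function(m, r) {
  w <- ncol(m)
  cs <- cbind(0, t(apply(m, 1L, cumsum)))       # H x (W+1) prefix sums
  hi <- pmin(w, seq_len(w) + r)
  lo <- pmax(1L, seq_len(w) - r)
  sums <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
  sweep(sums, 2L, hi - lo + 1L, "/")
}

#' Box (mean) filter with shrinking borders
#'
#' Mean over the (2r+1)^2 window, computed as two separable running-mean
#' passes (rows then columns) for O(n) cost independent of r. Border
#' windows shrink to the in-bounds part and are normalised by the true
#' pixel count, so constants are preserved exactly.
#'
#' @param img numeric H x W matrix.
#' @param r window half-width (radius), >= 1.
#' @return filtered H x W matrix.
#' @export
box_filter <- function(img, r) {
  img <- as.matrix(img)
  r <- as.integer(r)
  if (r < 1) stop("box filter radius must be >= 1", call. = FALSE)
  if (r > nrow(img) || r > ncol(img))
    stop("box filter radius exceeds an image dimension", call. = FALSE)
  t(row_mean(t(row_mean(img, r)), r))
}

#' Guided filter, scalar guide
#'
#' Edge-preserving smoothing of \code{input} steered by \code{guide}: in
#' every window the output is the affine function a*guide + b whose
#' coefficients minimise the regularised fit to the input, then per-pixel
#' coefficients are averaged over all windows containing the pixel. All
#' window means use \code{box_filter}, so the filter runs in O(n).
#'
#' @param guide H x W matrix (typically an intensity image in [0,1]).
#' @param input H x W matrix to be filtered.
#' @param r window radius in pixels.
#' @param eps regularisation added to the guide variance; larger eps
#'   pushes the filter toward a plain double box filter.
#' @return filtered H x W matrix.
#' @export
guided_filter_gray <- function(guide, input, r, eps) {
  guide <- as.matrix(guide); input <- as.matrix(input)
  if (!identical(dim(guide), dim(input)))
    stop("guide and input must have identical dimensions", call. = FALSE)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  mean_i <- box_filter(guide, r)
  corr_i <- box_filter(guide * guide, r)
  var_i <- corr_i - mean_i * mean_i
  mean_p <- box_filter(input, r)
  corr_ip <- box_filter(guide * input, r)
  cov_ip <- corr_ip - mean_i * mean_p
  a <- cov_ip / (var_i + eps)
  b <- mean_p - a * mean_i
  box_filter(a, r) * guide + box_filter(b, r)
}

#' Guided filter, RGB guide
#'
#' Colour generalisation of the guided filter: the per-window linear
#' model uses a 3-vector coefficient against the RGB guide, obtained from
#' the window's 3x3 guide covariance regularised by eps on the diagonal.
#' The closed-form 3x3 inverse is evaluated vectorised over all pixels.
#'
#' @param guide H x W x 3 RGB array.
#' @param input H x W matrix to be filtered.
#' @param r window radius in pixels.
#' @param eps diagonal covariance regularisation, > 0.
#' @return filtered H x W matrix.
#' @export
guided_filter_color <- function(guide, input, r, eps) {
  guide <- as_rgb(guide); input <- as.matrix(input)
  if (!identical(dim(guide)[1:2], dim(input)))
    stop("guide and input must have identical dimensions", call. = FALSE)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (!all(is.finite(guide)) || !all(is.finite(input)))
    stop("non-finite values in guide or input", call. = FALSE)
  I1 <- guide[, , 1]; I2 <- guide[, , 2]; I3 <- guide[, , 3]
  m1 <- box_filter(I1, r); m2 <- box_filter(I2, r); m3 <- box_filter(I3, r)
  mp <- box_filter(input, r)
  # covariance entries of the guide, and guide-input covariances
  v11 <- box_filter(I1 * I1, r) - m1 * m1 + eps
  v22 <- box_filter(I2 * I2, r) - m2 * m2 + eps
  v33 <- box_filter(I3 * I3, r) - m3 * m3 + eps
  v12 <- box_filter(I1 * I2, r) - m1 * m2
  v13 <- box_filter(I1 * I3, r) - m1 * m3
  v23 <- box_filter(I2 * I3, r) - m2 * m3
  c1 <- box_filter(I1 * input, r) - m1 * mp
  c2 <- box_filter(I2 * input, r) - m2 * mp
  c3 <- box_filter(I3 * input, r) - m3 * mp
  # closed-form inverse of the symmetric 3x3 (v + eps I), per pixel
  co11 <- v22 * v33 - v23 * v23
  co12 <- v13 * v23 - v12 * v33
  co13 <- v12 * v23 - v13 * v22
  co22 <- v11 * v33 - v13 * v13
  co23 <- v12 * v13 - v11 * v23
  co33 <- v11 * v22 - v12 * v12
  det <- v11 * co11 + v12 * co12 + v13 * co13
  a1 <- (co11 * c1 + co12 * c2 + co13 * c3) / det
  a2 <- (co12 * c1 + co22 * c2 + co23 * c3) / det
  a3 <- (co13 * c1 + co23 * c2 + co33 * c3) / det
  b <- mp - a1 * m1 - a2 * m2 - a3 * m3
  box_filter(a1, r) * I1 + box_filter(a2, r) * I2 +
    box_filter(a3, r) * I3 + box_filter(b, r)
}

#' Smooth a cost volume with the guided filter
#'
#' Each disparity slice is filtered independently with the reference RGB
#' image as guide (adaptive-support-weight aggregation). In mask-aware
#' runs the output validity of entry (p, d) requires the stage mask to
#' cover d at p; cost values outside the cost volume's own merged mask
#' were held at the truncation ceiling when the volume was built.
#'
#' @param vol a \code{cost_volume}.
#' @param guide H x W x 3 RGB reference image.
#' @param params an \code{aswi_params} object (uses \code{br}, \code{eps}).
#' @param stage_mask optional \code{disparity_range_mask} restricting
#'   which output entries are valid (typically the final "y2" stage mask).
#' @return a smoothed \code{cost_volume}.
#' @export
smooth_cost_volume <- function(vol, guide, params = aswi_params(),
                               stage_mask = NULL) {
  guide <- as_rgb(guide)
  dm <- dim(vol$costs)
  if (!identical(dim(guide)[1:2], dm[1:2]))
    stop("guide does not match the cost volume dimensions", call. = FALSE)
  out <- vol
  for (k in seq_len(dm[3])) {
    out$costs[, , k] <- guided_filter_color(guide, vol$costs[, , k],
                                            params$br, params$eps)
  }
  if (!is.null(stage_mask)) {
    for (k in seq_len(dm[3])) {
      d <- vol$d_min + k - 1L
      out$valid[, , k] <- vol$valid[, , k] &
        stage_mask$lo <= d & d <= stage_mask$hi
    }
  }
  out
}
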