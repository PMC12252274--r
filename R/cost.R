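#' Convert an RGB image to grayscale luminance
#'
#' ITU-R BT.601 weights (0.299, 0.587, 0.114).
#'
#' @param rgb H x W x 3 array, values in [0,1].
#' @return H x W matrix in [0,1].
#' @export
to_grayscale <- function(rgb) {
  rgb <- as_rgb(rgb)
  0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]
}

#' Horizontal Sobel gradient
#'
#' 3x3 Sobel-x kernel with replicate border padding, scaled by 1/8 so the
#' response to a unit-slope intensity ramp equals the slope. Keeping the
#' gradient on the [0,1] intensity scale makes the truncation threshold
#' TG resolution-independent.
#'
#' @param gray H x W matrix, H and W >= 3.
#' @return H x W matrix of signed x-gradients.
#' @export
sobel_x <- function(gray) {
  gray <- as.matrix(gray)
  h <- nrow(gray); w <- ncol(gray)
  if (h < 3 || w < 3) stop("image must be at least 3 x 3 for Sobel",
                           call. = FALSE)
  # replicate-pad by one pixel on each side
  p <- gray[c(1, 1:h, h), c(1, 1:w, w)]
  ri <- 2:(h + 1); ci <- 2:(w + 1)
  right <- p[ri - 1, ci + 1] + 2 * p[ri, ci + 1] + p[ri + 1, ci + 1]
  left  <- p[ri - 1, ci - 1] + 2 * p[ri, ci - 1] + p[ri + 1, ci - 1]
  (right - left) / 8
}

# Shift image columns so that out[, x] = img[, x - d] (view = "left":
# sampling the right image at the match position of left pixel x) or
# out[, x] = img[, x + d] (view = "right"). Vacated columns are NA.
shift_cols <- function(m, d, view = "left") {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  if (view == "left") {
    if (d < w) out[, (d + 1):w] <- m[, 1:(w - d), drop = FALSE]
  } else {
    if (d < w) out[, 1:(w - d)] <- m[, (d + 1):w, drop = FALSE]
  }
  out
}

#' Per-disparity colour matching cost
#'
#' Sum over the three channels of absolute intensity differences between
#' the reference pixel and its candidate match d columns away. Candidates
#' falling outside the other frame receive the truncation bound TM rather
#' than a fabricated clamped match; such pixels are later resolved by the
#' left-right consistency fill.
#'
#' @param pair a \code{stereo_pair}.
#' @param d integer disparity level.
#' @param TM colour truncation bound assigned to out-of-frame candidates.
#' @param view reference view, "left" or "right".
#' @return H x W matrix of non-negative costs.
#' @export
color_cost <- function(pair, d, TM = aswi_params()$TM,
                       view = c("left", "right")) {
  view <- match.arg(view)
  ref <- if (view == "left") pair$left else pair$right
  oth <- if (view == "left") pair$right else pair$left
  cost <- matrix(0, dim(ref)[1], dim(ref)[2])
  for (c in 1:3) {
    s <- shift_cols(oth[, , c], d, view)
    cost <- cost + abs(ref[, , c] - s)
  }
  cost[is.na(cost)] <- TM
  cost
}

#' Per-disparity gradient matching cost
#'
#' Absolute difference between the horizontal Sobel gradients of the two
#' grayscale frames at disparity offset d; out-of-frame candidates get TG.
#'
#' @inheritParams color_cost
#' @param TG gradient truncation bound assigned to out-of-frame candidates.
#' @return H x W matrix of non-negative costs.
#' @export
gradient_cost <- function(pair, d, TG = aswi_params()$TG,
                          view = c("left", "right")) {
  view <- match.arg(view)
  gl <- sobel_x(to_grayscale(pair$left))
  gr <- sobel_x(to_grayscale(pair$right))
  ref <- if (view == "left") gl else gr
  oth <- if (view == "left") gr else gl
  s <- shift_cols(oth, d, view)
  cost <- abs(ref - s)
  cost[is.na(cost)] <- TG
  cost
}

#' Truncated colour + gradient cost volume
#'
#' Builds C(p,d) = alpha * min(TM, M(p,d)) + (1 - alpha) * min(TG, G(p,d))
#' for every pixel and every disparity level in \code{d_range}. When a
#' range mask is given, entries outside the per-pixel interval are marked
#' invalid and held at the truncation ceiling alpha*TM + (1-alpha)*TG, so
#' downstream smoothing treats unexplored disparities as maximally
#' dissimilar and winner-takes-all never selects them.
#'
#' @param pair a \code{stereo_pair}.
#' @param d_range integer vector \code{c(d_min, d_max)}.
#' @param params an \code{aswi_params} object.
#' @param mask optional \code{disparity_range_mask} (typically the merged
#'   stage envelope).
#' @param view reference view.
#' @return an object of class \code{cost_volume}: list with \code{costs}
#'   (H x W x n_d array), \code{valid} (same shape, logical), and
#'   \code{d_min}, \code{d_max}.
#' @export
combined_cost <- function(pair, d_range, params = aswi_params(),
                          mask = NULL, view = c("left", "right")) {
  view <- match.arg(view)
  d_min <- as.integer(d_range[1]); d_max <- as.integer(d_range[2])
  if (d_min > d_max) stop("empty disparity range", call. = FALSE)
  if (d_min < params$d_min_global || d_max > params$d_max_global)
    stop("disparity range outside global bounds", call. = FALSE)
  h <- dim(pair$left)[1]; w <- dim(pair$left)[2]
  nd <- d_max - d_min + 1L
  costs <- array(NA_real_, c(h, w, nd))
  valid <- array(TRUE, c(h, w, nd))
  ceiling_cost <- params$alpha * params$TM + (1 - params$alpha) * params$TG

  gl <- sobel_x(to_grayscale(pair$left))
  gr <- sobel_x(to_grayscale(pair$right))
  ref_img <- if (view == "left") pair$left else pair$right
  oth_img <- if (view == "left") pair$right else pair$left
  ref_g <- if (view == "left") gl else gr
  oth_g <- if (view == "left") gr else gl

  if (!is.null(mask)) {
    if (!identical(dim(mask$lo), c(h, w)))
      stop("mask shape does not match the image", call. = FALSE)
    if (any(mask$lo > mask$hi))
      stop("range mask invariant violated: lo > hi", call. = FALSE)
  }

  for (k in seq_len(nd)) {
    d <- d_min + k - 1L
    m <- matrix(0, h, w)
    for (c in 1:3) {
      s <- shift_cols(oth_img[, , c], d, view)
      m <- m + abs(ref_img[, , c] - s)
    }
    g <- abs(ref_g - shift_cols(oth_g, d, view))
    oob <- is.na(m)
    m[oob] <- params$TM
    g[is.na(g)] <- params$TG
    plane <- params$alpha * pmin(params$TM, m) +
      (1 - params$alpha) * pmin(params$TG, g)
    if (!is.null(mask)) {
      covered <- mask$lo <= d & d <= mask$hi
      plane[!covered] <- ceiling_cost
      valid[, , k] <- covered
    }
    costs[, , k] <- plane
  }
  structure(list(costs = costs, valid = valid,
                 d_min = d_min, d_max = d_max, view = view),
            class = "cost_volume")
}

#' @export
print.cost_volume <- function(x, ...) {
  dm <- dim(x$costs)
  cat(sprintf("%s-view cost volume %d x %d, disparities %d..%d (%.1f%% valid)\n",
              x$view, dm[1], dm[2], x$d_min, x$d_max, 100 * mean(x$valid)))
  invisible(x)
}
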