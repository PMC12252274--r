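#' Rectified stereo pair
#'
#' Bundles a left and right RGB frame. Images are H x W x 3 arrays with
#' values in [0,1] and are assumed rectified: a scene point seen at left
#' column x appears at right column x - d on the same row, d >= 0.
#' Pixel coordinates are 0-based (x = column - 1, y = row - 1) in all
#' user-facing geometry.
#'
#' @param left,right RGB arrays, identical dimensions, values in [0,1].
#' @param frame_index integer frame number (>= 0) within a sequence.
#' @return an object of class \code{stereo_pair}.
#' @export
stereo_pair <- function(left, right, frame_index = 0L) {
  left <- as_rgb(left)
  right <- as_rgb(right)
  if (!identical(dim(left), dim(right)))
    stop("left and right images must have identical dimensions", call. = FALSE)
  rng <- range(left, right)
  if (rng[1] < 0 || rng[2] > 1)
    stop("image values must lie in [0,1]", call. = FALSE)
  if (frame_index < 0) stop("frame_index must be >= 0", call. = FALSE)
  structure(list(left = left, right = right,
                 frame_index = as.integer(frame_index)),
            class = "stereo_pair")
}

# Promote a grayscale matrix / single-channel array to H x W x 3.
as_rgb <- function(img) {
  if (is.matrix(img)) img <- array(img, c(dim(img), 1L))
  if (length(dim(img)) != 3L) stop("image must be H x W x channels", call. = FALSE)
  if (dim(img)[3] == 1L) img <- array(rep(img, 3L), c(dim(img)[1:2], 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L) stop("image must have 1, 3 or 4 channels", call. = FALSE)
  img
}

#' Disparity map
#'
#' A dense float disparity field with an explicit validity mask. Invalid
#' pixels hold \code{NA}; consumers must branch on \code{valid}, never on
#' the stored value.
#'
#' @param d numeric H x W matrix; \code{NA} at invalid pixels.
#' @param valid logical H x W matrix; \code{valid[i,j]} iff \code{d[i,j]}
#'   is a usable disparity. Defaults to \code{!is.na(d)}.
#' @param view which camera the map is expressed in, "left" or "right".
#' @return an object of class \code{disparity_map}.
#' @export
disparity_map <- function(d, valid = !is.na(d), view = c("left", "right")) {
  view <- match.arg(view)
  d <- as.matrix(d)
  valid <- as.matrix(valid)
  if (!identical(dim(d), dim(valid)))
    stop("d and valid must have identical dimensions", call. = FALSE)
  if (any(is.na(d) & valid))
    stop("NA disparity marked valid", call. = FALSE)
  d[!valid] <- NA_real_
  structure(list(d = d, valid = valid, view = view), class = "disparity_map")
}

#' Per-pixel disparity search-range mask
#'
#' Integer bounds \code{[lo, hi]} per pixel restricting which disparity
#' levels are evaluated, one mask per separable-convolution stage of the
#' guided filter.
#'
#' @param lo,hi integer H x W matrices with \code{lo <= hi} elementwise.
#' @param stage stage label, one of "x1", "y1", "x2", "y2" (or "merged").
#' @return an object of class \code{disparity_range_mask}.
#' @export
range_mask <- function(lo, hi, stage = "merged") {
  lo <- as.matrix(lo); hi <- as.matrix(hi)
  if (!identical(dim(lo), dim(hi)))
    stop("lo and hi must have identical dimensions", call. = FALSE)
  if (any(lo > hi))
    stop("range mask invariant violated: lo > hi at some pixel", call. = FALSE)
  if (!stage %in% c("x1", "y1", "x2", "y2", "merged"))
    stop("unknown mask stage: ", stage, call. = FALSE)
  structure(list(lo = lo, hi = hi, stage = stage),
            class = "disparity_range_mask")
}

#' @export
print.disparity_map <- function(x, ...) {
  cat(sprintf("%s-view disparity map %d x %d, %.1f%% valid, range [%.3f, %.3f]\n",
              x$view, nrow(x$d), ncol(x$d), 100 * mean(x$valid),
              suppressWarnings(min(x$d, na.rm = TRUE)),
              suppressWarnings(max(x$d, na.rm = TRUE))))
  invisible(x)
}

#' @export
print.stereo_pair <- function(x, ...) {
  d <- dim(x$left)
  cat(sprintf("rectified stereo pair, %d x %d px, frame %d\n",
              d[1], d[2], x$frame_index))
  invisible(x)
}
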