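#' Mean absolute error over valid pixels
#'
#' @param est,gt numeric H x W matrices (disparity in levels or depth in
#'   mm; choose one space explicitly and use it for both).
#' @param valid logical H x W matrix of pixels to evaluate; defaults to
#'   pixels finite in both maps.
#' @return scalar MAE.
#' @export
disparity_mae <- function(est, gt, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(est) & is.finite(gt)
  valid <- valid & is.finite(est) & is.finite(gt)
  if (!any(valid)) stop("no valid pixels to evaluate", call. = FALSE)
  mean(abs(est[valid] - gt[valid]))
}

#' Root-mean-square error over valid pixels
#'
#' @inheritParams disparity_mae
#' @return scalar RMSE (always >= the MAE of the same pixels).
#' @export
disparity_rmse <- function(est, gt, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(est) & is.finite(gt)
  valid <- valid & is.finite(est) & is.finite(gt)
  if (!any(valid)) stop("no valid pixels to evaluate", call. = FALSE)
  sqrt(mean((est[valid] - gt[valid])^2))
}

#' Equal-weight per-keyframe averaging
#'
#' The benchmark protocol for keyframe-organised sequences: first the
#' mean error within each keyframe, then the unweighted mean of those
#' keyframe means. Unlike the pooled mean, this weights every keyframe
#' equally regardless of how many frames it holds, which biases the
#' result toward keyframes with few frames.
#'
#' @param per_frame numeric vector of per-frame errors.
#' @param keyframe vector (same length) assigning each frame to a
#'   keyframe.
#' @return scalar protocol average.
#' @export
keyframe_average <- function(per_frame, keyframe) {
  if (length(per_frame) != length(keyframe))
    stop("per_frame and keyframe must have equal length", call. = FALSE)
  if (length(per_frame) == 0) stop("no frames", call. = FALSE)
  if (any(!is.finite(per_frame))) stop("non-finite per-frame error",
                                       call. = FALSE)
  mean(tapply(per_frame, keyframe, mean))
}

#' Published per-keyframe benchmark errors
#'
#' Per-keyframe depth MAE (mm) of the iterative matcher on the two
#' keyframe-organised benchmark sequences, as shipped with the package
#' for protocol arithmetic (columns \code{dataset}, \code{keyframe},
#' \code{mae_mm}).
#'
#' @return a data.frame.
#' @export
scared_keyframe_table <- function() {
  path <- system.file("extdata", "scared_aswi_keyframe_mae.csv",
                      package = "aswi")
  utils::read.csv(path)
}

#' Render a disparity error map to a PNG
#'
#' Absolute error, linearly mapped to the viridis colormap; invalid
#' pixels are black.
#'
#' @param est,gt numeric H x W matrices.
#' @param path output PNG path.
#' @param max_err error mapped to the top colour; defaults to the 99th
#'   percentile of the finite errors.
#' @return the path, invisibly.
#' @export
write_error_map <- function(est, gt, path, max_err = NULL) {
  err <- abs(est - gt)
  ok <- is.finite(err)
  if (is.null(max_err))
    max_err <- stats::quantile(err[ok], 0.99, names = FALSE)
  pal <- grDevices::hcl.colors(256, "viridis")
  idx <- pmin(pmax(round(err / max(max_err, 1e-12) * 255) + 1, 1), 256)
  rgbv <- grDevices::col2rgb(pal[idx]) / 255
  img <- array(0, c(nrow(err), ncol(err), 3))
  for (c in 1:3) {
    ch <- matrix(rgbv[c, ], nrow(err), ncol(err))
    ch[!ok] <- 0
    img[, , c] <- ch
  }
  write_image(img, path)
  invisible(path)
}
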