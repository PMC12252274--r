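#' Winner-takes-all disparity selection
#'
#' Per pixel, the disparity level with the minimal smoothed cost among
#' the valid entries; ties break toward the smaller disparity.
#'
#' @param vol a (smoothed) \code{cost_volume}.
#' @return a \code{disparity_map} in the volume's view, valid everywhere.
#' @export
wta <- function(vol) {
  dm <- dim(vol$costs)
  best <- matrix(Inf, dm[1], dm[2])
  bestd <- matrix(NA_real_, dm[1], dm[2])
  for (k in seq_len(dm[3])) {
    ck <- vol$costs[, , k]
    ck[!vol$valid[, , k]] <- Inf
    upd <- ck < best            # strict: ties keep the earlier (smaller) d
    best[upd] <- ck[upd]
    bestd[upd] <- vol$d_min + k - 1L
  }
  if (any(is.na(bestd)))
    stop("pixel with no valid cost entry; range mask construction bug upstream",
         call. = FALSE)
  disparity_map(bestd, view = vol$view)
}

#' Sub-pixel disparity refinement
#'
#' Fits a parabola through the smoothed costs at d-1, d, d+1 and moves
#' the disparity to its vertex: d* = d + (C(d-1) - C(d+1)) /
#' (2 * (C(d-1) - 2 C(d) + C(d+1))). Applied only where both neighbours
#' are valid and the parabola is convex; the shift never exceeds 0.5.
#'
#' @param vol the \code{cost_volume} the map was selected from.
#' @param disp the integer \code{disparity_map} from \code{wta}.
#' @return a refined \code{disparity_map}.
#' @export
subpixel_refine <- function(vol, disp) {
  dm <- dim(vol$costs)
  h <- dm[1]; w <- dm[2]; nd <- dm[3]
  k <- round(disp$d) - vol$d_min + 1      # slice index per pixel
  i <- row(k); j <- col(k)
  inner <- disp$valid & k > 1 & k < nd
  ii <- i[inner]; jj <- j[inner]; kk <- k[inner]
  lin <- function(kidx) cbind(ii, jj, kidx)
  ok <- vol$valid[lin(kk - 1)] & vol$valid[lin(kk)] & vol$valid[lin(kk + 1)]
  cm <- vol$costs[lin(kk - 1)]; c0 <- vol$costs[lin(kk)]
  cp <- vol$costs[lin(kk + 1)]
  denom <- cm - 2 * c0 + cp
  ok <- ok & denom > 0
  delta <- ifelse(ok, (cm - cp) / (2 * denom), 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  d <- disp$d
  d[cbind(ii, jj)] <- d[cbind(ii, jj)] + delta
  disparity_map(d, disp$valid, view = disp$view)
}

#' Weighted median filter with bilateral weights
#'
#' Per pixel, the weighted median of the valid disparities in the
#' (2 radius + 1)^2 window, weighted by spatial proximity
#' exp(-||p - j||^2 / sigma_G^2) and colour similarity
#' exp(-||I_p - I_j||^2 / sigma_M^2) in the guide image. The weighted
#' median is the smallest value whose cumulative weight reaches half the
#' total. Pixels whose window holds no valid disparity stay invalid.
#'
#' @param disp a \code{disparity_map}.
#' @param guide H x W x 3 RGB image of the same view.
#' @param radius window radius, pixels.
#' @param sigma_G spatial scale, pixels.
#' @param sigma_M colour scale, normalised intensity.
#' @return a filtered \code{disparity_map}.
#' @export
weighted_median <- function(disp, guide, radius, sigma_G, sigma_M) {
  guide <- as_rgb(guide)
  h <- nrow(disp$d); w <- ncol(disp$d)
  radius <- as.integer(radius)
  if (radius < 1) stop("radius must be >= 1", call. = FALSE)
  off <- -radius:radius
  sp_w <- exp(-outer(off^2, off^2, "+") / sigma_G^2)  # (2r+1)^2 spatial term
  g1 <- matrix(guide[, , 1], h, w)  # keep matrix shape for 1-row images
  g2 <- matrix(guide[, , 2], h, w)
  g3 <- matrix(guide[, , 3], h, w)
  dvals <- disp$d
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    ri <- max(1L, i - radius):min(h, i + radius)
    for (j in seq_len(w)) {
      rj <- max(1L, j - radius):min(w, j + radius)
      v <- dvals[ri, rj]
      keep <- !is.na(v)
      if (!any(keep)) next
      dc <- (g1[ri, rj] - g1[i, j])^2 + (g2[ri, rj] - g2[i, j])^2 +
        (g3[ri, rj] - g3[i, j])^2
      wgt <- sp_w[ri - i + radius + 1L, rj - j + radius + 1L] *
        exp(-dc / sigma_M^2)
      v <- v[keep]; wgt <- wgt[keep]
      o <- order(v)
      cw <- cumsum(wgt[o])
      out[i, j] <- v[o][which(cw >= cw[length(cw)] / 2)[1]]
    }
  }
  disparity_map(out, view = disp$view)
}

#' Left-right consistency check
#'
#' Pixel p = (x, y) in the left map is consistent iff the right map at
#' (x - round(d_left(p)), y) exists, is valid, and differs from
#' d_left(p) by at most \code{tol} levels.
#'
#' @param d_left left-view \code{disparity_map}.
#' @param d_right right-view \code{disparity_map}.
#' @param tol tolerance in disparity levels.
#' @return logical H x W validity matrix.
#' @export
lr_check <- function(d_left, d_right, tol = 1.0) {
  if (!identical(dim(d_left$d), dim(d_right$d)))
    stop("left and right maps must have identical dimensions", call. = FALSE)
  h <- nrow(d_left$d); w <- ncol(d_left$d)
  jr <- col(d_left$d) - round(d_left$d)   # matched right column (1-based)
  ok <- d_left$valid & !is.na(jr) & jr >= 1 & jr <= w
  idx <- which(ok)
  ir <- ((idx - 1) %% h) + 1
  ridx <- cbind(ir, jr[idx])
  ok[idx] <- d_right$valid[ridx] &
    abs(d_left$d[idx] - d_right$d[ridx]) <= tol
  ok[is.na(ok)] <- FALSE
  ok
}

#' Fill invalid disparities from consistent neighbours
#'
#' Per scanline, each invalid pixel takes the smaller of the nearest
#' valid disparities to its left and right (background wins at occlusion
#' borders); a one-sided neighbourhood uses that side. Rows with no
#' valid pixel fall back to the nearest valid pixel along the column.
#'
#' @param disp a \code{disparity_map} with at least one valid pixel.
#' @return list with \code{map} (fully valid \code{disparity_map}) and
#'   \code{n_filled} (number of pixels that were invalid).
#' @export
fill_invalid <- function(disp) {
  d <- disp$d
  h <- nrow(d); w <- ncol(d)
  if (!any(disp$valid)) stop("cannot fill a fully invalid map", call. = FALSE)
  n_filled <- sum(!disp$valid)
  for (i in seq_len(h)) {
    v <- which(disp$valid[i, ])
    if (length(v) == 0) next
    miss <- which(!disp$valid[i, ])
    if (length(miss) == 0) next
    li <- findInterval(miss, v)                 # index of nearest valid left
    left_val <- ifelse(li >= 1, d[i, v[pmax(li, 1)]], NA_real_)
    ri <- li + 1                                # nearest valid right
    right_val <- ifelse(ri <= length(v), d[i, v[pmin(ri, length(v))]], NA_real_)
    d[i, miss] <- pmin(left_val, right_val, na.rm = TRUE)
  }
  # rows that were fully invalid: nearest valid row per column
  bad_rows <- which(!apply(disp$valid, 1, any))
  if (length(bad_rows) > 0) {
    good_rows <- setdiff(seq_len(h), bad_rows)
    for (i in bad_rows) {
      src <- good_rows[which.min(abs(good_rows - i))]
      d[i, ] <- d[src, ]
    }
  }
  list(map = disparity_map(d, matrix(TRUE, h, w), view = disp$view),
       n_filled = n_filled)
}

#' Specular-glare mask
#'
#' Marks pixels saturated in every channel (specular highlights from the
#' endoscope LED), which carry no usable matching signal.
#'
#' @param img H x W x 3 RGB array in [0,1].
#' @param threshold saturation threshold in (0,1].
#' @return logical H x W matrix, TRUE at glare pixels.
#' @export
glare_mask <- function(img, threshold = 250 / 255) {
  img <- as_rgb(img)
  if (threshold <= 0 || threshold > 1)
    stop("glare threshold must be in (0,1]", call. = FALSE)
  pmin(img[, , 1], img[, , 2], img[, , 3]) >= threshold
}

#' Dense disparity estimation for one rectified stereo pair
#'
#' The full single-pair matcher: truncated colour+gradient cost volumes
#' for both views, guided-filter aggregation, winner-takes-all with
#' sub-pixel refinement, then the postprocessing chain -- weighted median
#' on the right map, left-right consistency check, glare rejection,
#' occlusion filling, and a final whole-map weighted median. When
#' per-stage disparity-range masks are supplied (video mode), the cost
#' volume is computed only inside their merged envelope.
#'
#' @param pair a \code{stereo_pair}.
#' @param params an \code{aswi_params} object.
#' @param masks optional named list of \code{disparity_range_mask}s with
#'   elements x1, y1, x2, y2 (see \code{\link{build_range_mask}}).
#' @return an object of class \code{aswi_disparity}: the final left-view
#'   \code{disparity_map} plus a consistency report (counts of
#'   left-right-inconsistent, glare, and filled pixels) and the
#'   parameters used.
#' @export
aswi_match <- function(pair, params = aswi_params(), masks = NULL) {
  stopifnot(inherits(pair, "stereo_pair"))
  d_range <- c(params$d_min_global, params$d_max_global)
  merged <- if (!is.null(masks)) merge_range_masks(masks) else NULL
  final_mask <- if (!is.null(masks)) masks$y2 else NULL

  vol_l <- combined_cost(pair, d_range, params, mask = merged, view = "left")
  vol_r <- combined_cost(pair, d_range, params, mask = merged, view = "right")
  vol_l <- smooth_cost_volume(vol_l, pair$left, params, stage_mask = final_mask)
  vol_r <- smooth_cost_volume(vol_r, pair$right, params, stage_mask = final_mask)

  d_l <- subpixel_refine(vol_l, wta(vol_l))
  d_r <- subpixel_refine(vol_r, wta(vol_r))
  d_r <- weighted_median(d_r, pair$right, params$median_radius,
                         params$sigma_G, params$sigma_M)

  consistent <- lr_check(d_l, d_r, params$lr_tolerance)
  glare <- glare_mask(pair$left, params$glare_threshold)
  n_inconsistent <- sum(!consistent)
  n_glare <- sum(glare & consistent)
  keep <- consistent & !glare
  d <- d_l$d
  d[!keep] <- NA_real_
  filled <- fill_invalid(disparity_map(d, keep, view = "left"))
  final <- weighted_median(filled$map, pair$left, params$median_radius,
                           params$sigma_G, params$sigma_M)
  report <- list(n_inconsistent = n_inconsistent, n_glare = n_glare,
                 n_filled = filled$n_filled)
  structure(list(d = final$d, valid = final$valid, view = "left",
                 report = report, params = params,
                 frame_index = pair$frame_index),
            class = c("aswi_disparity", "disparity_map"))
}

#' @export
print.aswi_disparity <- function(x, ...) {
  cat(sprintf("ASWI disparity map %d x %d (frame %d)\n",
              nrow(x$d), ncol(x$d), x$frame_index))
  cat(sprintf("  disparity range [%.3f, %.3f], %.1f%% valid\n",
              min(x$d, na.rm = TRUE), max(x$d, na.rm = TRUE),
              100 * mean(x$valid)))
  cat(sprintf("  postprocessing: %d LR-inconsistent, %d glare, %d filled\n",
              x$report$n_inconsistent, x$report$n_glare, x$report$n_filled))
  invisible(x)
}

#' @export
summary.aswi_disparity <- function(object, ...) {
  s <- list(dim = dim(object$d),
            disparity = summary(as.vector(object$d)),
            valid_fraction = mean(object$valid),
            report = object$report)
  class(s) <- "summary.aswi_disparity"
  s
}

#' @export
print.summary.aswi_disparity <- function(x, ...) {
  cat(sprintf("ASWI disparity %d x %d, %.1f%% valid\n",
              x$dim[1], x$dim[2], 100 * x$valid_fraction))
  print(x$disparity)
  cat(sprintf("LR-inconsistent %d, glare %d, filled %d\n",
              x$report$n_inconsistent, x$report$n_glare, x$report$n_filled))
  invisible(x)
}

#' Plot a disparity map as an image
#'
#' @param x a \code{disparity_map} or \code{aswi_disparity}.
#' @param main plot title.
#' @param ... passed to \code{image}.
#' @export
plot.disparity_map <- function(x, main = "disparity", ...) {
  d <- x$d
  # image() draws x right / y up; transpose and flip rows for raster order
  graphics::image(t(d[nrow(d):1, , drop = FALSE]), asp = nrow(d) / ncol(d),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main, ...)
  invisible(x)
}
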