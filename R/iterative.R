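#' Stage-dependent mask window radii
#'
#' The guided filter is realised as two box-filter stages, each applied
#' as a horizontal (x) then vertical (y) separable pass. A pixel's value
#' at a given stage depends on previous-frame disparities within a
#' rectangular neighbourhood whose half-widths shrink as the pipeline
#' advances: the earliest pass (x1) must look furthest ahead.
#'
#' @param er edge radius (guided-filter window), pixels.
#' @param br box-filter radius, pixels.
#' @param stage one of "x1", "y1", "x2", "y2".
#' @return integer vector \code{c(rx, ry)}.
#' @export
stage_radii <- function(er, br, stage) {
  if (er < 1 || br < 1) stop("er and br must be >= 1", call. = FALSE)
  er <- as.integer(er); br <- as.integer(br)
  switch(stage,
         x1 = c(er + br, er + 2L * br),
         y1 = c(er + br, er + br),
         x2 = c(er, er + br),
         y2 = c(er, er),
         stop("unknown mask stage: ", stage, call. = FALSE))
}

#' Build a per-pixel disparity-range mask from the previous frame
#'
#' For each pixel, the min and max disparity over the stage's rectangular
#' window in the previous frame's (fully filled) map, rounded to the
#' nearest integer level (the underlying matching candidate; sub-pixel
#' shifts never exceed half a level), widened by \code{d_offset}, and
#' clamped to the global bounds. Windows clip at the image border.
#' Rounding rather than flooring/ceiling keeps the masks stable when an
#' estimate hovers just below or above an integer, so static scenes
#' settle to a fixed point instead of flipping a bound every frame.
#'
#' @param prev a fully valid \code{disparity_map} (the postprocessed
#'   previous-frame output).
#' @param stage one of "x1", "y1", "x2", "y2".
#' @param params an \code{aswi_params} object.
#' @return a \code{disparity_range_mask} for that stage.
#' @export
build_range_mask <- function(prev, stage, params = aswi_params()) {
  if (!all(prev$valid))
    stop("range masks require a fully valid (filled) previous map",
         call. = FALSE)
  r <- stage_radii(params$er, params$br, stage)
  pd <- round(prev$d)
  lo <- window_extreme(pd, r[1], r[2], min) - params$d_offset
  hi <- window_extreme(pd, r[1], r[2], max) + params$d_offset
  lo <- pmax(lo, params$d_min_global)
  hi <- pmin(hi, params$d_max_global)
  range_mask(lo, hi, stage)
}

# Separable running min/max over a rectangle with x half-width rx
# (columns) and y half-width ry (rows). Border windows clip: the index
# clamp re-reads in-bounds values, which is idempotent under min/max.
window_extreme <- function(m, rx, ry, fun) {
  fun2 <- if (identical(fun, min)) pmin else pmax
  pass <- function(mm, r, along_cols) {
    if (along_cols) mm <- t(mm)
    n <- ncol(mm)
    out <- mm
    for (o in seq_len(r)) {
      out <- fun2(out, mm[, pmax(seq_len(n) - o, 1), drop = FALSE],
                  mm[, pmin(seq_len(n) + o, n), drop = FALSE])
    }
    if (along_cols) t(out) else out
  }
  pass(pass(m, rx, FALSE), ry, TRUE)
}

#' Merge per-stage masks into their envelope
#'
#' The per-pixel union interval (min of the lower bounds, max of the
#' upper bounds) of the four stage masks; the cost volume is computed on
#' this envelope so that every filtering stage finds the entries it needs.
#'
#' @param masks list of \code{disparity_range_mask}s.
#' @return a \code{disparity_range_mask} with stage "merged".
#' @export
merge_range_masks <- function(masks) {
  masks <- unname(masks)
  dims <- lapply(masks, function(m) dim(m$lo))
  if (length(unique(dims)) != 1)
    stop("masks have mismatching shapes", call. = FALSE)
  lo <- Reduce(pmin, lapply(masks, `[[`, "lo"))
  hi <- Reduce(pmax, lapply(masks, `[[`, "hi"))
  range_mask(lo, hi, "merged")
}

#' Run the iterative matcher over a stereo sequence
#'
#' Frames with index below \code{warmup_frames} (and frame 0 always) are
#' matched over the full global disparity range; every later frame builds
#' the four stage masks from the previous frame's filled map and matches
#' only inside them, exploiting temporal coherence. If a frame's
#' left-right inconsistency rate exceeds \code{cut_fraction} (a scene
#' cut / tracking loss), the next frame falls back to the full range.
#'
#' @param frames list of \code{stereo_pair}s, in temporal order.
#' @param params an \code{aswi_params} object.
#' @return list of \code{aswi_disparity} results, one per frame. Each
#'   carries an attribute \code{masked} saying whether range masks were
#'   in force for that frame.
#' @export
aswi_sequence <- function(frames, params = aswi_params()) {
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  out <- vector("list", length(frames))
  prev <- NULL
  prev_bad_rate <- 0
  for (t in seq_along(frames)) {
    use_masks <- (t - 1) >= params$warmup_frames && !is.null(prev) &&
      prev_bad_rate <= params$cut_fraction
    masks <- if (use_masks) {
      stages <- c("x1", "y1", "x2", "y2")
      stats::setNames(lapply(stages, build_range_mask, prev = prev,
                             params = params), stages)
    } else NULL
    res <- aswi_match(frames[[t]], params, masks)
    attr(res, "masked") <- use_masks
    out[[t]] <- res
    prev <- disparity_map(res$d, res$valid, view = "left")
    prev_bad_rate <- res$report$n_inconsistent / length(res$d)
  }
  out
}
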