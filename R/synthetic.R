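#' Synthetic scene specification
#'
#' Describes a procedurally generated rectified stereo scene: a disparity
#' surface, a texture painted on the left image, optional saturated glare
#' discs, and an optional per-frame disparity drift for sequences. The
#' generated pairs have horizontal-only disparity, occlusion bands at
#' depth steps, and exact ground truth -- the structural properties the
#' matcher assumes, without any external data.
#'
#' @param height,width image size in pixels.
#' @param surface disparity surface: "plane" (fronto-parallel),
#'   "slanted_plane" (linear ramp across x), "height_profile" (smooth
#'   sinusoidal height field), or "step_pyramid" (nested rectangular
#'   steps with sharp edges).
#' @param d_base base disparity in levels.
#' @param d_amplitude surface disparity amplitude in levels.
#' @param n_steps number of nested steps for "step_pyramid".
#' @param texture "noise" (band-limited noise; the default emulates a
#'   texture that respects the sampling limit), "sinusoid", or
#'   "low_contrast".
#' @param texture_contrast peak-to-peak texture contrast in [0,1].
#' @param glare_spots number of saturated specular discs to paint.
#' @param drift_per_frame disparity added to the whole surface each frame
#'   (levels/frame), emulating slow camera approach.
#' @param n_frames number of frames to generate.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param d_min_global,d_max_global bounds the surface must respect over
#'   all frames.
#' @return an object of class \code{scene_spec}.
#' @export
scene_spec <- function(height = 48L, width = 64L,
                       surface = c("plane", "slanted_plane",
                                   "height_profile", "step_pyramid"),
                       d_base = 8, d_amplitude = 4, n_steps = 2L,
                       texture = c("noise", "sinusoid", "low_contrast"),
                       texture_contrast = 0.8, glare_spots = 0L,
                       drift_per_frame = 0, n_frames = 1L, seed = 1L,
                       d_min_global = 0L, d_max_global = 24L) {
  surface <- match.arg(surface)
  texture <- match.arg(texture)
  spec <- list(height = as.integer(height), width = as.integer(width),
               surface = surface, d_base = d_base,
               d_amplitude = d_amplitude, n_steps = as.integer(n_steps),
               texture = texture, texture_contrast = texture_contrast,
               glare_spots = as.integer(glare_spots),
               drift_per_frame = drift_per_frame,
               n_frames = as.integer(n_frames), seed = as.integer(seed),
               d_min_global = as.integer(d_min_global),
               d_max_global = as.integer(d_max_global))
  # surface span: plane is flat, step_pyramid only rises, the others swing
  # symmetrically around d_base
  amp_lo <- switch(surface, plane = 0, step_pyramid = 0,
                   abs(spec$d_amplitude))
  amp_hi <- switch(surface, plane = 0, abs(spec$d_amplitude))
  lo <- spec$d_base - amp_lo +
    min(0, spec$drift_per_frame * (spec$n_frames - 1))
  hi <- spec$d_base + amp_hi +
    max(0, spec$drift_per_frame * (spec$n_frames - 1))
  if (lo < spec$d_min_global || hi > spec$d_max_global)
    stop("scene disparities would leave the global bounds over the sequence",
         call. = FALSE)
  if (spec$texture_contrast < 0 || spec$texture_contrast > 1)
    stop("texture_contrast must be in [0,1]", call. = FALSE)
  if (spec$n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  structure(spec, class = "scene_spec")
}

# Disparity field of the surface at a given frame index (0-based).
surface_disparity <- function(spec, frame = 0L) {
  h <- spec$height; w <- spec$width
  base <- spec$d_base + spec$drift_per_frame * frame
  x01 <- matrix(rep((seq_len(w) - 1) / max(w - 1, 1), each = h), h, w)
  y01 <- matrix(rep((seq_len(h) - 1) / max(h - 1, 1), times = w), h, w)
  switch(spec$surface,
         plane = matrix(base, h, w),
         slanted_plane = base + spec$d_amplitude * (2 * x01 - 1),
         height_profile = base + spec$d_amplitude *
           sin(2 * pi * x01) * cos(pi * y01),
         step_pyramid = {
           d <- matrix(base, h, w)
           for (l in seq_len(spec$n_steps)) {
             ix <- round(l * w / (2 * (spec$n_steps + 1)))
             iy <- round(l * h / (2 * (spec$n_steps + 1)))
             rows <- (iy + 1):(h - iy)
             cols <- (ix + 1):(w - ix)
             d[rows, cols] <- base +
               round(spec$d_amplitude * l / spec$n_steps)
           }
           d
         })
}

# Left-image texture, H x W x 3, deterministic given the current RNG state.
paint_texture <- function(spec) {
  h <- spec$height; w <- spec$width
  c2 <- spec$texture_contrast / 2
  img <- array(0.5, c(h, w, 3))
  if (spec$texture == "sinusoid") {
    x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
    phase <- stats::runif(3, 0, 2 * pi)
    for (c in 1:3)
      img[, , c] <- 0.5 + c2 * sin(2 * pi * x / 16 + phase[c]) *
        cos(2 * pi * y / 11 + phase[c] / 2)
  } else {
    contrast <- if (spec$texture == "low_contrast") c2 * 0.2 else c2
    for (c in 1:3) {
      n <- matrix(stats::runif(h * w), h, w)
      n <- box_filter(n, 1L)      # band-limit: no energy near Nyquist
      n <- (n - min(n)) / max(max(n) - min(n), 1e-12)
      img[, , c] <- 0.5 + contrast * (2 * n - 1) / 2
    }
  }
  img
}

# Synthesize the right image and left-view occlusion mask from the left
# image and its (left-view) disparity field. Disoccluded right-image
# pixels (content hidden from the left camera) show the scene's hidden
# background texture: a disocclusion band never shows a copy of the
# occluder, and giving it unmatched content is what keeps phantom
# correspondences out of the right-view map. The hidden texture is drawn
# once per scene (not per frame) so a static scene produces identical
# images every frame.
warp_right <- function(left, d, hidden = NULL) {
  h <- nrow(d); w <- ncol(d)
  right <- array(NA_real_, dim(left))
  occluded <- matrix(FALSE, h, w)
  band_fill <- if (is.null(hidden)) {
    array(stats::runif(h * w * 3, min(left), max(left)), dim(left))
  } else hidden
  integer_d <- all(abs(d - round(d)) < 1e-9)
  if (integer_d) {
    d <- round(d)
    for (i in seq_len(h)) {
      xr <- seq_len(w) - d[i, ]                  # 1-based target column
      claimed_d <- rep(-Inf, w)
      winner <- rep(NA_integer_, w)
      for (x in seq_len(w)) {
        t <- xr[x]
        if (t < 1) { occluded[i, x] <- TRUE; next }
        if (d[i, x] > claimed_d[t]) {
          if (!is.na(winner[t])) occluded[i, winner[t]] <- TRUE
          claimed_d[t] <- d[i, x]
          winner[t] <- x
        } else {
          occluded[i, x] <- TRUE
        }
      }
      for (t in which(!is.na(winner)))
        right[i, t, ] <- left[i, winner[t], ]
      # right-only (disoccluded) columns: unseen content
      miss <- which(is.na(winner))
      for (t in miss) right[i, t, ] <- band_fill[i, t, ]
    }
  } else {
    # smooth sub-pixel surfaces: fixed-point inverse warp with linear
    # interpolation (injective for |dd/dx| < 1, so no self-occlusion)
    for (i in seq_len(h)) {
      drow <- d[i, ]
      dfun <- stats::approxfun(seq_len(w), drow, rule = 2)
      for (t in seq_len(w)) {
        x <- t + drow[min(t, w)]
        for (it in 1:12) x <- t + dfun(x)
        if (x < 1 || x > w) next
        x0 <- floor(x); fr <- x - x0
        x1 <- min(x0 + 1, w)
        right[i, t, ] <- (1 - fr) * left[i, x0, ] + fr * left[i, x1, ]
      }
      occluded[i, ] <- (seq_len(w) - drow) < 1
      miss <- which(is.na(right[i, , 1]))
      for (t in miss) right[i, t, ] <- band_fill[i, t, ]
    }
  }
  list(right = right, occluded = occluded)
}

#' Generate a synthetic stereo scene
#'
#' Builds the disparity surface, paints the texture on the left image,
#' synthesizes the right image by visibility-aware warping (when several
#' left pixels land on the same right pixel the largest disparity --
#' the nearest surface -- wins and the losers are occluded), paints
#' optional saturated glare discs consistently in both views, and drifts
#' the surface by \code{drift_per_frame} each frame. Fully reproducible
#' from \code{spec$seed}.
#'
#' @param spec a \code{scene_spec}.
#' @return list of frames; each frame is a list with \code{pair}
#'   (\code{stereo_pair}), \code{gt_disparity} (H x W matrix, left view),
#'   \code{occluded} and \code{glare} (logical H x W masks, left view).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  left0 <- paint_texture(spec)
  h <- spec$height; w <- spec$width
  # scene-level hidden background revealed in disocclusion bands
  hidden <- array(stats::runif(h * w * 3, min(left0), max(left0)), dim(left0))
  glare_centers <- if (spec$glare_spots > 0) {
    cbind(row = sample(seq(4, h - 3), spec$glare_spots, replace = TRUE),
          col = sample(seq(max(4, spec$d_max_global + 2), w - 3),
                       spec$glare_spots, replace = TRUE))
  } else NULL

  frames <- vector("list", spec$n_frames)
  for (t in seq_len(spec$n_frames)) {
    d <- surface_disparity(spec, t - 1L)
    wr <- warp_right(left0, d, hidden)
    left <- left0
    glare <- matrix(FALSE, h, w)
    if (!is.null(glare_centers)) {
      for (g in seq_len(nrow(glare_centers))) {
        gi <- glare_centers[g, 1]; gj <- glare_centers[g, 2]
        rows <- pmax(1, gi - 2):pmin(h, gi + 2)
        for (ii in rows) {
          cols <- pmax(1, gj - 2):pmin(w, gj + 2)
          cols <- cols[(ii - gi)^2 + (cols - gj)^2 <= 4]
          glare[ii, cols] <- TRUE
          left[ii, cols, ] <- 1
          cr <- cols - round(d[ii, cols])
          cr <- cr[cr >= 1 & cr <= w]
          if (length(cr) > 0) wr$right[ii, cr, ] <- 1
        }
      }
    }
    frames[[t]] <- list(pair = stereo_pair(left, wr$right, frame_index = t - 1L),
                        gt_disparity = d, occluded = wr$occluded,
                        glare = glare)
  }
  frames
}

#' The package's worked regression fixture
#'
#' A fixed 32 x 24 two-level step scene (disparities 4 and 9, sinusoid
#' texture, seed 0) used throughout the documentation and as a frozen
#' regression anchor: the expected final disparity map produced by
#' \code{aswi_match} at the fixture parameters is shipped in
#' \code{inst/extdata/worked_fixture_expected.csv}.
#'
#' @return a single synthetic frame (see \code{\link{generate_scene}}),
#'   with the matching parameters attached as attribute \code{params}.
#' @export
worked_fixture <- function() {
  spec <- scene_spec(height = 24L, width = 32L, surface = "step_pyramid",
                     d_base = 4, d_amplitude = 5, n_steps = 1L,
                     texture = "sinusoid", texture_contrast = 0.8,
                     seed = 0L, d_min_global = 0L, d_max_global = 12L)
  frame <- generate_scene(spec)[[1]]
  # filter radii scaled to the miniature frame (~W/10): the full-frame
  # defaults (er = br = 7) would span half this 32-px-wide image
  attr(frame, "params") <- aswi_params(er = 3L, br = 3L, median_radius = 3L,
                                       d_min_global = 0L, d_max_global = 12L)
  frame
}
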