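#' Algorithm parameters
#'
#' Constructs the validated parameter set for the iterative
#' adaptive-support-weight matcher. All intensity-scale thresholds
#' (\code{TM}, \code{TG}, \code{sigma_M}, \code{glare_threshold}) are
#' expressed on the internal \code{[0,1]} image scale, so they are
#' independent of input bit depth.
#'
#' @param alpha balance between colour and gradient cost, in \code{[0,1]}.
#'   The default 0.1 favours the gradient term.
#' @param TM truncation threshold for the summed 3-channel colour cost.
#' @param TG truncation threshold for the x-gradient cost.
#' @param er edge radius of the guided filter window, pixels.
#' @param br box-filter radius used by every mean pass of the guided
#'   filter, pixels; defaults to \code{er}.
#' @param eps guided-filter regularisation on the \code{[0,1]} scale.
#' @param d_offset disparity margin added around the previous frame's
#'   local min/max when building range masks, in disparity levels.
#' @param sigma_G spatial scale of the weighted-median bilateral weights,
#'   pixels.
#' @param sigma_M colour scale of the weighted-median bilateral weights,
#'   normalised intensity.
#' @param median_radius window radius of the weighted median, pixels.
#' @param glare_threshold intensity above which a pixel counts as
#'   saturated in every channel, in \code{(0,1]}.
#' @param lr_tolerance maximum left/right disparity disagreement, levels.
#' @param warmup_frames number of initial frames run at the full global
#'   disparity range before range masks take over.
#' @param d_min_global,d_max_global global disparity search bounds, levels.
#' @param cut_fraction if the left-right inconsistency rate of a frame
#'   exceeds this fraction, the next frame falls back to the full range
#'   (scene-cut recovery).
#' @return an object of class \code{aswi_params} (a named list).
#' @export
aswi_params <- function(alpha = 0.1, TM = 0.0824, TG = 0.0078,
                        er = 7L, br = er, eps = 1e-4,
                        d_offset = 2L, sigma_G = 9, sigma_M = 0.1,
                        median_radius = 9L, glare_threshold = 250 / 255,
                        lr_tolerance = 1.0, warmup_frames = 5L,
                        d_min_global = 0L, d_max_global = 63L,
                        cut_fraction = 0.5) {
  p <- list(alpha = alpha, TM = TM, TG = TG,
            er = as.integer(er), br = as.integer(br), eps = eps,
            d_offset = as.integer(d_offset),
            sigma_G = sigma_G, sigma_M = sigma_M,
            median_radius = as.integer(median_radius),
            glare_threshold = glare_threshold,
            lr_tolerance = lr_tolerance,
            warmup_frames = as.integer(warmup_frames),
            d_min_global = as.integer(d_min_global),
            d_max_global = as.integer(d_max_global),
            cut_fraction = cut_fraction)
  validate_params(p)
  structure(p, class = "aswi_params")
}

validate_params <- function(p) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop(sprintf("invalid parameter '%s': %s", field, why),
                          call. = FALSE)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(p$alpha) && p$alpha >= 0 && p$alpha <= 1, "alpha", "must be in [0,1]")
  chk(num1(p$TM) && p$TM > 0, "TM", "must be > 0")
  chk(num1(p$TG) && p$TG > 0, "TG", "must be > 0")
  chk(num1(p$eps) && p$eps > 0, "eps", "must be > 0")
  chk(num1(p$sigma_G) && p$sigma_G > 0, "sigma_G", "must be > 0")
  chk(num1(p$sigma_M) && p$sigma_M > 0, "sigma_M", "must be > 0")
  chk(num1(p$er) && p$er >= 1, "er", "must be >= 1")
  chk(num1(p$br) && p$br >= 1, "br", "must be >= 1")
  chk(num1(p$median_radius) && p$median_radius >= 1, "median_radius",
      "must be >= 1")
  chk(num1(p$d_offset) && p$d_offset >= 0, "d_offset", "must be >= 0")
  chk(num1(p$glare_threshold) && p$glare_threshold > 0 &&
        p$glare_threshold <= 1, "glare_threshold", "must be in (0,1]")
  chk(num1(p$lr_tolerance) && p$lr_tolerance >= 0, "lr_tolerance",
      "must be >= 0")
  chk(num1(p$warmup_frames) && p$warmup_frames >= 0, "warmup_frames",
      "must be >= 0")
  chk(num1(p$d_min_global) && num1(p$d_max_global) &&
        p$d_min_global <= p$d_max_global, "d_min_global",
      "must satisfy d_min_global <= d_max_global")
  chk(num1(p$cut_fraction) && p$cut_fraction > 0 && p$cut_fraction <= 1,
      "cut_fraction", "must be in (0,1]")
  invisible(p)
}

#' Rectified stereo camera model
#'
#' Intrinsics and baseline of a rectified stereo rig, used to convert
#' disparity (pixels) to metric depth Z = fx * baseline / d.
#'
#' @param fx,fy focal lengths in pixels.
#' @param cx,cy principal point in pixels (0-based image coordinates).
#' @param baseline interocular distance in mm.
#' @param width,height image size in pixels.
#' @return an object of class \code{camera_model}.
#' @export
camera_model <- function(fx = 1024.09, fy = 1023.89,
                         cx = 601.81, cy = 508.13,
                         baseline = 4.35,
                         width = 1280L, height = 1024L) {
  chk <- function(ok, field, why) {
    if (!isTRUE(ok)) stop(sprintf("invalid camera field '%s': %s", field, why),
                          call. = FALSE)
  }
  chk(is.numeric(fx) && fx > 0, "fx", "must be > 0")
  chk(is.numeric(fy) && fy > 0, "fy", "must be > 0")
  chk(is.numeric(baseline) && baseline > 0, "baseline", "must be > 0")
  chk(is.numeric(width) && width >= 1, "width", "must be >= 1")
  chk(is.numeric(height) && height >= 1, "height", "must be >= 1")
  chk(is.numeric(cx) && cx >= 0 && cx < width, "cx", "must be in [0, width)")
  chk(is.numeric(cy) && cy >= 0 && cy < height, "cy", "must be in [0, height)")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, baseline = baseline,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_model")
}

.param_keys <- c("alpha", "TM", "TG", "er", "br", "eps", "d_offset",
                 "sigma_G", "sigma_M", "median_radius", "glare_threshold",
                 "lr_tolerance", "warmup_frames", "d_min_global",
                 "d_max_global", "cut_fraction")
.camera_keys <- c("fx", "fy", "cx", "cy", "baseline", "width", "height")

#' Load parameters and camera model from a config file
#'
#' Reads a YAML or JSON config with two optional top-level sections,
#' \code{params} and \code{camera}. Omitted keys take their documented
#' defaults; unknown keys are an error (typo safety). An empty file
#' yields the full default parameter set.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a list with elements \code{params} (\code{aswi_params}) and
#'   \code{camera} (\code{camera_model}).
#' @export
load_params <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), c("params", "camera"))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  pc <- if (is.null(cfg$params)) list() else as.list(cfg$params)
  cc <- if (is.null(cfg$camera)) list() else as.list(cfg$camera)
  bad <- setdiff(names(pc), .param_keys)
  if (length(bad) > 0)
    stop("unknown params key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(names(cc), .camera_keys)
  if (length(bad) > 0)
    stop("unknown camera key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  list(params = do.call(aswi_params, pc),
       camera = do.call(camera_model, cc))
}

#' @export
print.aswi_params <- function(x, ...) {
  cat("ASWI parameters\n")
  cat(sprintf("  cost: alpha=%g TM=%g TG=%g, disparity range [%d, %d]\n",
              x$alpha, x$TM, x$TG, x$d_min_global, x$d_max_global))
  cat(sprintf("  guided filter: er=%d br=%d eps=%g\n", x$er, x$br, x$eps))
  cat(sprintf("  postprocess: median_radius=%d sigma_G=%g sigma_M=%g lr_tol=%g glare>=%.3f\n",
              x$median_radius, x$sigma_G, x$sigma_M, x$lr_tolerance,
              x$glare_threshold))
  cat(sprintf("  iteration: d_offset=%d warmup_frames=%d cut_fraction=%g\n",
              x$d_offset, x$warmup_frames, x$cut_fraction))
  invisible(x)
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera: fx=%g fy=%g cx=%g cy=%g baseline=%g mm, %dx%d px\n",
              x$fx, x$fy, x$cx, x$cy, x$baseline, x$width, x$height))
  invisible(x)
}
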