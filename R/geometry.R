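#' Convert disparity to metric depth
#'
#' Rectified-stereo relation Z = fx * baseline / d. Disparity is
#' horizontal, so the horizontal focal length applies. Invalid or zero
#' disparities yield invalid (NA) depth.
#'
#' @param disp a \code{disparity_map} (levels = pixels).
#' @param cam a \code{camera_model} (baseline in mm).
#' @return H x W depth matrix in mm, NA where undefined.
#' @export
disparity_to_depth <- function(disp, cam) {
  z <- cam$fx * cam$baseline / disp$d
  z[!disp$valid | disp$d <= 0] <- NA_real_
  z
}

#' Convert depth to disparity
#'
#' Inverse of \code{\link{disparity_to_depth}}: d = fx * baseline / Z.
#'
#' @param depth H x W depth matrix in mm (NA = invalid).
#' @param cam a \code{camera_model}.
#' @return a left-view \code{disparity_map}.
#' @export
depth_to_disparity <- function(depth, cam) {
  d <- cam$fx * cam$baseline / depth
  d[!is.finite(d) | depth <= 0] <- NA_real_
  disparity_map(d, view = "left")
}

#' Reproject a disparity map to a 3-D point cloud
#'
#' Pinhole reprojection X = (x - cx) Z / fx, Y = (y - cy) Z / fy,
#' Z = fx b / d, with 0-based pixel coordinates. Invalid pixels are
#' skipped.
#'
#' @param disp a \code{disparity_map}.
#' @param img optional H x W x 3 RGB image supplying per-point colours.
#' @param cam a \code{camera_model}.
#' @return list with \code{points} (N x 3 matrix, mm) and \code{colors}
#'   (N x 3 in [0,1]).
#' @export
disparity_to_pointcloud <- function(disp, img = NULL, cam) {
  z <- disparity_to_depth(disp, cam)
  keep <- which(!is.na(z))
  h <- nrow(z)
  y0 <- ((keep - 1) %% h)            # 0-based row
  x0 <- ((keep - 1) %/% h)           # 0-based column
  zz <- z[keep]
  pts <- cbind(x = (x0 - cam$cx) * zz / cam$fx,
               y = (y0 - cam$cy) * zz / cam$fy,
               z = zz)
  cols <- if (is.null(img)) {
    matrix(1, length(keep), 3)
  } else {
    img <- as_rgb(img)
    cbind(img[, , 1][keep], img[, , 2][keep], img[, , 3][keep])
  }
  list(points = pts, colors = cols)
}

#' Diffraction-limited spatial resolution (Rayleigh criterion)
#'
#' Smallest resolvable object-space separation at working distance Z for
#' an aperture of diameter D at wavelength lambda:
#' d_RC = Z * tan(asin(1.22 lambda / D)), which in the small-angle regime
#' of endoscope optics reduces to Z * 1.22 * lambda / D.
#'
#' @param wavelength light wavelength in metres.
#' @param aperture aperture diameter in metres.
#' @param depth working distance Z in metres.
#' @param exact use the exact tan(asin(.)) form instead of the
#'   small-angle approximation.
#' @return spatial resolution in metres.
#' @export
rayleigh_resolution <- function(wavelength, aperture, depth, exact = FALSE) {
  if (wavelength <= 0 || aperture <= 0 || depth <= 0)
    stop("all inputs must be > 0", call. = FALSE)
  s <- 1.22 * wavelength / aperture
  if (s >= 1) stop("1.22 * lambda / D >= 1: diffraction angle undefined",
                   call. = FALSE)
  if (exact) depth * tan(asin(s)) else depth * s
}

#' Object-space footprint of one sensor pixel
#'
#' Similar-triangles projection t = t' * Z / f: the smallest structure a
#' single pixel of pitch t' can resolve at working distance Z with focal
#' length f.
#'
#' @param pixel_size sensor pixel pitch t' in metres.
#' @param depth working distance Z in metres.
#' @param focal_length focal length f in metres.
#' @return object-space size in metres.
#' @export
pixel_footprint <- function(pixel_size, depth, focal_length) {
  if (pixel_size <= 0 || depth <= 0 || focal_length <= 0)
    stop("all inputs must be > 0", call. = FALSE)
  pixel_size * depth / focal_length
}

#' Pixel pitch from sensor diagonal and aspect ratio
#'
#' Sensor width = diagonal * aw / sqrt(aw^2 + ah^2); pitch = width /
#' horizontal pixel count (square pixels assumed).
#'
#' @param diagonal sensor diagonal in metres.
#' @param aspect_w,aspect_h aspect ratio terms (e.g. 16 and 9).
#' @param horizontal_pixels pixels across the sensor width.
#' @return pixel pitch in metres.
#' @export
sensor_pixel_size <- function(diagonal, aspect_w, aspect_h, horizontal_pixels) {
  if (diagonal <= 0 || aspect_w <= 0 || aspect_h <= 0 || horizontal_pixels <= 0)
    stop("all inputs must be > 0", call. = FALSE)
  width <- diagonal * aspect_w / sqrt(aspect_w^2 + aspect_h^2)
  width / horizontal_pixels
}
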