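#' Read an image as an RGB array in [0,1]
#'
#' Supports 8/16-bit PNG and binary or ASCII PPM/PGM. Grayscale inputs
#' are replicated to three channels; an alpha channel is dropped.
#'
#' @param path image file path.
#' @return H x W x 3 numeric array with values in [0,1].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("cannot read image, file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    tryCatch(png::readPNG(path),
             error = function(e) stop("unreadable PNG '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  } else if (ext %in% c("ppm", "pgm", "pnm")) {
    read_pnm(path)
  } else {
    stop("unsupported image format '", ext, "' for ", path, call. = FALSE)
  }
  as_rgb(img)
}

#' Write an RGB array in [0,1] as a PNG file
#'
#' @param img H x W (x3) numeric array, values in [0,1].
#' @param path output path ending in .png.
#' @export
write_image <- function(img, path) {
  png::writePNG(as_rgb(img), path)
  invisible(path)
}

# Minimal PPM/PGM reader (P2/P3 ASCII, P5/P6 binary, maxval <= 65535),
# returning values scaled to [0,1].
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || ch == "")
        stop("malformed PNM header in ", path, call. = FALSE)
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0 || ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path, call. = FALSE)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (any(is.na(c(w, h, maxval))) || w < 1 || h < 1 || maxval < 1)
    stop("malformed PNM header in ", path, call. = FALSE)
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- as.numeric(w) * h * nch
  vals <- if (magic %in% c("P2", "P3")) {
    scan(con, what = integer(), n = n, quiet = TRUE)
  } else if (maxval < 256) {
    as.integer(readBin(con, "raw", n = n))
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = "big")
  }
  if (length(vals) != n) stop("truncated PNM data in ", path, call. = FALSE)
  # stored row-major, top row first, channels interleaved
  arr <- array(NA_real_, c(h, w, nch))
  for (c in seq_len(nch))
    arr[, , c] <- matrix(vals[seq(c, n, by = nch)], nrow = h, byrow = TRUE)
  arr / maxval
}

#' Read a PFM float map
#'
#' Portable float map: header "Pf" (grayscale) or "PF" (colour), width,
#' height, then a scale whose sign encodes endianness (negative =
#' little-endian), followed by float32 rows stored bottom-up. Non-finite
#' values (the +Inf invalid-pixel sentinel) are returned as \code{NA}.
#'
#' @param path PFM file path.
#' @param na_nonfinite replace non-finite values with NA (default TRUE).
#' @return numeric H x W matrix (grayscale PFM only).
#' @export
read_pfm <- function(path, na_nonfinite = TRUE) {
  if (!file.exists(path)) stop("PFM file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  read_line_raw <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0) stop("malformed PFM header in ", path, call. = FALSE)
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  magic <- read_line_raw()
  if (!magic %in% c("Pf", "PF"))
    stop("malformed PFM header (magic '", magic, "') in ", path, call. = FALSE)
  if (magic == "PF")
    stop("colour PFM not supported: ", path, call. = FALSE)
  dims <- strsplit(trimws(read_line_raw()), "[[:space:]]+")[[1]]
  w <- as.integer(dims[1]); h <- as.integer(dims[2])
  scale <- as.numeric(read_line_raw())
  if (any(is.na(c(w, h, scale))) || w < 1 || h < 1 || scale == 0)
    stop("malformed PFM header in ", path, call. = FALSE)
  endian <- if (scale < 0) "little" else "big"
  vals <- readBin(con, "numeric", n = w * h, size = 4L, endian = endian)
  if (length(vals) != w * h) stop("truncated PFM data in ", path, call. = FALSE)
  # bottom row stored first
  m <- matrix(vals, nrow = h, byrow = TRUE)[h:1, , drop = FALSE]
  if (na_nonfinite) m[!is.finite(m)] <- NA_real_
  m
}

#' Write a PFM float map
#'
#' Writes grayscale little-endian PFM (scale -1). \code{NA} values (the
#' invalid-pixel sentinel) are encoded as +Inf.
#'
#' @param m numeric H x W matrix.
#' @param path output path.
#' @export
write_pfm <- function(m, path) {
  m <- as.matrix(m)
  m[is.na(m)] <- Inf
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("Pf\n%d %d\n-1.0\n", ncol(m), nrow(m)), con,
            eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(m[nrow(m):1, , drop = FALSE])), con,
           size = 4L, endian = "little")
  invisible(path)
}

#' Write a PLY point cloud
#'
#' @param points N x 3 numeric matrix of x, y, z coordinates in mm; all
#'   coordinates must be finite.
#' @param colors N x 3 matrix of RGB colours in [0,1] (or 0..255 integers).
#' @param path output path.
#' @param binary write binary_little_endian (default) or ASCII.
#' @export
write_ply <- function(points, colors = NULL, path, binary = TRUE) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be N x 3", call. = FALSE)
  n <- nrow(points)
  if (n > 0 && !all(is.finite(points)))
    stop("non-finite point coordinates are not allowed", call. = FALSE)
  if (n == 0) warning("writing empty PLY (0 vertices): ", path)
  if (is.null(colors)) colors <- matrix(1, n, 3)
  colors <- as.matrix(colors)
  if (max(colors, 0) <= 1) colors <- colors * 255
  colors <- pmin(pmax(round(colors), 0), 255)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  hdr <- c("ply", paste("format", fmt, "1.0"),
           paste("element vertex", n),
           "property float x", "property float y", "property float z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL,
            useBytes = TRUE)
  if (n == 0) return(invisible(path))
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(points[i, ]), con, size = 4L, endian = "little")
      writeBin(as.raw(colors[i, ]), con)
    }
  } else {
    lines <- sprintf("%.9g %.9g %.9g %d %d %d",
                     points[, 1], points[, 2], points[, 3],
                     colors[, 1], colors[, 2], colors[, 3])
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL,
              useBytes = TRUE)
  }
  invisible(path)
}

#' Read a PLY point cloud written by \code{write_ply}
#'
#' @param path PLY file path.
#' @return list with \code{points} (N x 3) and \code{colors} (N x 3 in [0,1]).
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_line_raw <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1L)
      if (length(b) == 0) stop("malformed PLY header in ", path, call. = FALSE)
      if (b == as.raw(10L)) break
      out <- c(out, b)
    }
    rawToChar(out)
  }
  if (read_line_raw() != "ply") stop("not a PLY file: ", path, call. = FALSE)
  fmt <- NULL; n <- NULL
  repeat {
    ln <- read_line_raw()
    if (ln == "end_header") break
    if (grepl("^format ", ln)) fmt <- strsplit(ln, " ")[[1]][2]
    if (grepl("^element vertex ", ln)) n <- as.integer(strsplit(ln, " ")[[1]][3])
  }
  if (is.null(fmt) || is.null(n)) stop("malformed PLY header in ", path,
                                       call. = FALSE)
  pts <- matrix(0, n, 3); cols <- matrix(0, n, 3)
  if (n == 0) return(list(points = pts, colors = cols))
  if (fmt == "binary_little_endian") {
    for (i in seq_len(n)) {
      pts[i, ] <- readBin(con, "numeric", 3L, size = 4L, endian = "little")
      cols[i, ] <- as.integer(readBin(con, "raw", 3L))
    }
  } else if (fmt == "ascii") {
    txt <- readLines(con, n = n)
    parts <- do.call(rbind, lapply(strsplit(trimws(txt), "[[:space:]]+"),
                                   as.numeric))
    pts <- parts[, 1:3, drop = FALSE]
    cols <- parts[, 4:6, drop = FALSE]
  } else {
    stop("unsupported PLY format '", fmt, "' in ", path, call. = FALSE)
  }
  list(points = pts, colors = cols / 255)
}
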