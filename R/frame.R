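#' Retina frame: an image on the retinal coordinate domain
#'
#' A `retina_frame` holds an H x W x 3 pixel array with channel values in
#' \[0, 1\] together with the viewing-geometry scale `pixels_per_degree`,
#' which converts degrees of visual angle into pixels. All angular
#' parameters elsewhere in the package (inhibition-of-return width, the
#' winner-take-all inhibition radius, the saliency accumulation width used
#' for tuning) are converted through this single scale.
#'
#' Coordinate convention: continuous `(x, y)` with `x` rightward and `y`
#' downward, 0-based, pixel centers at integer coordinates. Pixel
#' `pixels[i, j, ]` sits at `(x = j - 1, y = i - 1)`.
#'
#' @param pixels numeric array, either H x W (grayscale, replicated to 3
#'   channels) or H x W x 3, values in \[0, 1\].
#' @param pixels_per_degree positive scale in pixels per degree of visual
#'   angle. The default 12.8 treats a 224-px frame as roughly 17.5 degrees
#'   of visual field, typical of desktop eye-tracking geometry.
#' @return an object of class `retina_frame`.
#' @export
retina_frame <- function(pixels, pixels_per_degree = 12.8) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3L || dim(pixels)[3L] != 3L) {
    stop("`pixels` must be an H x W or H x W x 3 numeric array", call. = FALSE)
  }
  if (dim(pixels)[1L] < 8L || dim(pixels)[2L] < 8L) {
    stop("frame must be at least 8 x 8 pixels", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("frame contains non-finite pixel values", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(pixels_per_degree) || length(pixels_per_degree) != 1L ||
      pixels_per_degree <= 0) {
    stop("`pixels_per_degree` must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      height_px = dim(pixels)[1L],
      width_px = dim(pixels)[2L],
      pixels_per_degree = pixels_per_degree
    ),
    class = "retina_frame"
  )
}

#' @export
print.retina_frame <- function(x, ...) {
  cat(sprintf(
    "<retina_frame> %d x %d px, %.2f px/degree, value range [%.3f, %.3f]\n",
    x$height_px, x$width_px, x$pixels_per_degree,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.retina_frame <- function(x) c(x$height_px, x$width_px)

deg2px <- function(deg, ppd) deg * ppd

#' Load an image file as a retina frame
#'
#' Reads an 8- or 16-bit PNG, JPEG or TIFF raster, scales values to
#' \[0, 1\], and replicates grayscale inputs to three channels. Alpha
#' channels are dropped.
#'
#' @param path path to the image file.
#' @param pixels_per_degree viewing-geometry scale, see [retina_frame()].
#' @return a [retina_frame()].
#' @export
load_image <- function(path, pixels_per_degree = 12.8) {
  if (!file.exists(path)) {
    stop(sprintf("image file does not exist: '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(
    switch(ext,
      png = png::readPNG(path),
      jpg = ,
      jpeg = jpeg::readJPEG(path),
      tif = ,
      tiff = as.array(EBImage::readImage(path)),
      # fall back to EBImage's format sniffing
      as.array(EBImage::readImage(path))
    ),
    error = function(e) {
      stop(sprintf("cannot read image '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  if (ext %in% c("tif", "tiff") || !(ext %in% c("png", "jpg", "jpeg"))) {
    # EBImage stores images x-major (width first); transpose to row-major
    px <- if (length(dim(px)) == 2L) t(px) else aperm(px, c(2L, 1L, 3L))
  }
  if (length(dim(px)) == 3L && dim(px)[3L] > 3L) {
    px <- px[, , 1:3, drop = FALSE]  # drop alpha
  }
  if (length(dim(px)) == 3L && dim(px)[3L] == 2L) {
    px <- px[, , 1L]  # gray + alpha
  }
  px[px < 0] <- 0
  px[px > 1] <- 1
  retina_frame(if (length(dim(px)) == 2L) as.matrix(px) else px,
               pixels_per_degree = pixels_per_degree)
}

#' Save a retina frame as a PNG image
#'
#' @param frame a [retina_frame()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_frame_png <- function(frame, path) {
  stopifnot(inherits(frame, "retina_frame"))
  png::writePNG(frame$pixels, target = path)
  invisible(path)
}

# Bilinear sampling of a single channel at fractional (row, col), 0-based
# pixel-center coordinates; out-of-range coordinates are clamped (replicate
# border).
.bilinear_channel <- function(m, rows, cols) {
  h <- nrow(m); w <- ncol(m)
  rows <- pmin(pmax(rows, 0), h - 1)
  cols <- pmin(pmax(cols, 0), w - 1)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, h - 1); c1 <- pmin(c0 + 1, w - 1)
  fr <- rows - r0; fc <- cols - c0
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c1 + 1)
  i10 <- cbind(r1 + 1, c0 + 1); i11 <- cbind(r1 + 1, c1 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i01] * (1 - fr) * fc +
    m[i10] * fr * (1 - fc) + m[i11] * fr * fc
}

#' Resize a retina frame by bilinear resampling
#'
#' Resamples to the working resolution (default 224 x 224). Each output
#' pixel center is mapped into the source grid with the area-alignment
#' convention `src = (dst + 0.5) * size_in / size_out - 0.5` and the source
#' is sampled bilinearly with replicated borders, so values stay in
#' \[0, 1\] and constant frames map to constant frames.
#'
#' @param frame a [retina_frame()].
#' @param size target `(height, width)` in pixels, each at least 8.
#' @return a resized [retina_frame()] with the same `pixels_per_degree`.
#' @export
resize_frame <- function(frame, size = c(224L, 224L)) {
  stopifnot(inherits(frame, "retina_frame"))
  size <- as.integer(size)
  if (length(size) != 2L || any(!is.finite(size)) || any(size < 8L)) {
    stop("`size` must be two integers >= 8", call. = FALSE)
  }
  h_in <- frame$height_px; w_in <- frame$width_px
  h_out <- size[1L]; w_out <- size[2L]
  if (h_in == h_out && w_in == w_out) {
    return(frame)
  }
  rows <- (seq_len(h_out) - 0.5) * h_in / h_out - 0.5
  cols <- (seq_len(w_out) - 0.5) * w_in / w_out - 0.5
  rc <- expand.grid(row = rows, col = cols)  # column-major like R matrices
  out <- array(0, dim = c(h_out, w_out, 3L))
  for (ch in 1:3) {
    out[, , ch] <- matrix(
      .bilinear_channel(frame$pixels[, , ch], rc$row, rc$col),
      nrow = h_out, ncol = w_out
    )
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  retina_frame(out, pixels_per_degree = frame$pixels_per_degree)
}
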