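#' @title Pre-attentive feature maps and attracting masses
#'
#' @description
#' The model drives attention with N = 8 low-level feature gradients:
#' the spatial gradient of intensity (f1), of the three colour channels
#' (f2..f4) and of four orientation-energy maps at 0/45/90/135 degrees
#' (f5..f8). Each gradient is a per-pixel 2-vector (d/dx, d/dy). The mass
#' attracting attention at a pixel is `mu_i = alpha_i * ||f_i||`
#' (Euclidean norm), and the total mass is `mu = sum_i mu_i`.
#'
#' @name features
NULL

#' Intensity map of a frame
#'
#' Per-pixel mean of the three colour channels, in \[0, 1\].
#'
#' @param frame a [retina_frame()].
#' @return an H x W numeric matrix.
#' @export
intensity_map <- function(frame) {
  stopifnot(inherits(frame, "retina_frame"))
  (frame$pixels[, , 1L] + frame$pixels[, , 2L] + frame$pixels[, , 3L]) / 3
}

# Even-symmetric (cosine) Gabor kernel, zero-DC. theta is the edge
# orientation the filter responds to: theta = 0 means vertical edges
# (intensity modulated along x).
.gabor_kernel <- function(theta_deg, wavelength, sigma) {
  half <- ceiling(3 * sigma)
  g <- seq(-half, half)
  xx <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)   # x (columns)
  yy <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = FALSE)  # y (rows)
  th <- theta_deg * pi / 180
  # carrier axis perpendicular to the edge orientation
  xr <- xx * cos(th) + yy * sin(th)
  k <- exp(-(xx^2 + yy^2) / (2 * sigma^2)) * cos(2 * pi * xr / wavelength)
  k - mean(k)
}

# 2-D convolution with replicate borders via EBImage's FFT filtering.
.filter_replicate <- function(m, kernel) {
  EBImage::filter2(m, kernel, boundary = "replicate")
}

#' Orientation-energy maps
#'
#' Rectified responses of an even-symmetric Gabor bank at 0, 45, 90 and
#' 135 degrees, revealing the presence of edges at those orientations
#' (0 degrees = vertical edges, 90 = horizontal). The kernels are zero-DC,
#' so constant images yield (numerically) zero response everywhere.
#'
#' @param intensity an H x W intensity matrix, e.g. from [intensity_map()].
#' @param wavelength Gabor carrier wavelength in pixels.
#' @param sigma Gaussian envelope width in pixels (kernel support is
#'   `2 * ceiling(3 sigma) + 1` pixels per side).
#' @return a list of four non-negative H x W matrices, named
#'   `orient0`, `orient45`, `orient90`, `orient135`.
#' @export
orientation_maps <- function(intensity, wavelength = 8, sigma = 4) {
  stopifnot(is.matrix(intensity), all(is.finite(intensity)))
  support <- 2L * ceiling(3 * sigma) + 1L
  if (nrow(intensity) < support || ncol(intensity) < support) {
    stop(sprintf(
      "grid (%d x %d) smaller than the %d-px Gabor support",
      nrow(intensity), ncol(intensity), support), call. = FALSE)
  }
  angles <- c(0, 45, 90, 135)
  out <- lapply(angles, function(a) {
    abs(.filter_replicate(intensity, .gabor_kernel(a, wavelength, sigma)))
  })
  names(out) <- paste0("orient", angles)
  out
}

# Central-difference spatial gradient with replicated borders; returns
# list(gx, gy) in units of value change per pixel.
.central_gradient <- function(m) {
  h <- nrow(m); w <- ncol(m)
  # replicate-pad by one pixel, then central differences everywhere
  left <- m[, c(1L, seq_len(w - 1L)), drop = FALSE]
  right <- m[, c(seq_len(w)[-1L], w), drop = FALSE]
  up <- m[c(1L, seq_len(h - 1L)), , drop = FALSE]
  down <- m[c(seq_len(h)[-1L], h), , drop = FALSE]
  list(gx = (right - left) / 2, gy = (down - up) / 2)
}

#' Extract the 8-feature gradient stack of a frame
#'
#' Computes the spatial gradients (central differences, replicated
#' borders) of the intensity map, the three colour channels and the four
#' orientation-energy maps.
#'
#' @param frame a [retina_frame()].
#' @param color_space `"rgb"` uses the raw channels as the three colour
#'   features; `"opponent"` uses the colour-opponent transform
#'   (R - G, B - (R + G)/2, (R + G + B)/3).
#' @param wavelength,sigma Gabor parameters, see [orientation_maps()].
#' @return a `feature_stack`: a list with `maps` (8 elements, each
#'   `list(gx, gy)`), `names`, and the frame geometry.
#' @export
extract_features <- function(frame, color_space = c("rgb", "opponent"),
                             wavelength = 8, sigma = 4) {
  stopifnot(inherits(frame, "retina_frame"))
  color_space <- match.arg(color_space)
  intens <- intensity_map(frame)
  r <- frame$pixels[, , 1L]; g <- frame$pixels[, , 2L]
  b <- frame$pixels[, , 3L]
  chans <- if (color_space == "rgb") {
    list(r, g, b)
  } else {
    list(r - g, b - (r + g) / 2, (r + g + b) / 3)
  }
  omaps <- orientation_maps(intens, wavelength = wavelength, sigma = sigma)
  sources <- c(list(intensity = intens),
               stats::setNames(chans, paste0("color", 1:3)), omaps)
  structure(
    list(
      maps = lapply(sources, .central_gradient),
      names = names(sources),
      height_px = frame$height_px,
      width_px = frame$width_px,
      pixels_per_degree = frame$pixels_per_degree
    ),
    class = "feature_stack"
  )
}

#' @export
print.feature_stack <- function(x, ...) {
  cat(sprintf("<feature_stack> %d maps (%s) on %d x %d px\n",
              length(x$maps), paste(x$names, collapse = ", "),
              x$height_px, x$width_px))
  invisible(x)
}

#' Per-feature scalar magnitude maps
#'
#' Euclidean norms `||f_i||` of the gradient 2-vectors, one non-negative
#' H x W matrix per feature. These are the scalar maps combined by the
#' winner-take-all baseline.
#'
#' @param stack a `feature_stack` from [extract_features()].
#' @return a named list of 8 non-negative matrices.
#' @export
feature_magnitudes <- function(stack) {
  stopifnot(inherits(stack, "feature_stack"))
  stats::setNames(
    lapply(stack$maps, function(f) sqrt(f$gx^2 + f$gy^2)),
    stack$names
  )
}

#' Mass distribution attracting the focus of attention
#'
#' Builds the per-feature masses `mu_i = alpha_i * ||f_i||` and their sum
#' `mu`, which acts as the gravitational source density.
#'
#' @param stack a `feature_stack` from [extract_features()].
#' @param alphas positive per-feature scaling factors; the default weights
#'   all features equally.
#' @return a `mass_distribution`: list with `mu` (H x W total mass),
#'   `mu_i` (list of per-feature masses), `alphas` and frame geometry.
#' @export
compute_masses <- function(stack, alphas = rep(1, length(stack$maps))) {
  stopifnot(inherits(stack, "feature_stack"))
  if (length(alphas) != length(stack$maps)) {
    stop("`alphas` must have one entry per feature map", call. = FALSE)
  }
  if (any(!is.finite(alphas)) || any(alphas <= 0)) {
    stop("all `alphas` must be positive and finite", call. = FALSE)
  }
  mags <- feature_magnitudes(stack)
  mu_i <- Map(function(m, a) a * m, mags, as.list(alphas))
  mu <- Reduce(`+`, mu_i)
  .mass_distribution(mu, mu_i, alphas, stack$pixels_per_degree)
}

.mass_distribution <- function(mu, mu_i, alphas, ppd) {
  structure(
    list(mu = mu, mu_i = mu_i, alphas = alphas,
         height_px = nrow(mu), width_px = ncol(mu),
         pixels_per_degree = ppd),
    class = "mass_distribution"
  )
}

#' @export
print.mass_distribution <- function(x, ...) {
  cat(sprintf(
    "<mass_distribution> %d x %d px, %d component(s), total mass %.4g\n",
    x$height_px, x$width_px, length(x$mu_i), sum(x$mu)))
  invisible(x)
}

#' Use a precomputed saliency map as the mass distribution
#'
#' Supports running the model on an externally supplied saliency map
#' (e.g. a classical bottom-up saliency model's output) instead of the
#' basic features: the map, shifted so its minimum is zero, becomes the
#' single mass component.
#'
#' @param saliency an H x W numeric matrix (or grayscale image values).
#' @param pixels_per_degree viewing-geometry scale for the map.
#' @return a single-component `mass_distribution`.
#' @export
saliency_as_mass <- function(saliency, pixels_per_degree = 12.8) {
  saliency <- as.matrix(saliency)
  stopifnot(all(is.finite(saliency)))
  mu <- saliency - min(saliency)
  if (max(mu) == 0) {
    warning("constant saliency map: total mass is zero", call. = FALSE)
  }
  .mass_distribution(mu, list(saliency = mu), alphas = 1,
                     ppd = pixels_per_degree)
}
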