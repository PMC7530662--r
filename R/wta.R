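#' Combine feature maps into a master map with equal weights
#'
#' Arithmetic (equal-weight linear) combination of scalar maps — for
#' gradient features, their magnitude maps (see [feature_magnitudes()]).
#'
#' @param maps a list of H x W numeric matrices of equal shape (or a
#'   single matrix).
#' @param inhibition_radius_px radius of the winner-take-all inhibition
#'   disk, in pixels (default: 2 degrees at 12.8 px/degree).
#' @return an object of class `master_map`.
#' @export
combine_equal <- function(maps, inhibition_radius_px = 25.6) {
  if (is.matrix(maps)) maps <- list(maps)
  if (length(maps) < 1L) {
    stop("at least one map is required", call. = FALSE)
  }
  dims <- lapply(maps, dim)
  if (!all(vapply(dims, identical, logical(1L), dims[[1L]]))) {
    stop("all maps must have the same shape", call. = FALSE)
  }
  if (!is.numeric(inhibition_radius_px) || inhibition_radius_px <= 0) {
    stop("`inhibition_radius_px` must be positive", call. = FALSE)
  }
  values <- Reduce(`+`, maps) / length(maps)
  stopifnot(all(is.finite(values)))
  structure(
    list(values = values, inhibition_radius_px = inhibition_radius_px),
    class = "master_map"
  )
}

#' Winner-take-all scanpath
#'
#' The classical discrete baseline: the first fixation is the location of
#' the maximum of the master map; the selected location is then inhibited
#' within the inhibition radius (values set to `-Inf`) and the next
#' maximum is selected, and so on. Ties at the maximum are broken in
#' row-major order. The output is discrete — there is no continuous
#' dynamics and no timing model, so fixations get a uniform duration.
#'
#' @param master a `master_map` from [combine_equal()].
#' @param n_fixations number of fixations to generate; the default
#'   assumes 3 fixations per viewing second.
#' @param exposure viewing time in seconds, used for the default
#'   `n_fixations` and the uniform fixation duration.
#' @return a [scanpath()] with `n_fixations` fixations. If every location
#'   with positive saliency gets inhibited first, the scanpath is
#'   truncated with a warning (locations of non-positive saliency are
#'   never attended).
#' @export
wta_scanpath <- function(master, n_fixations = NULL, exposure = 3) {
  stopifnot(inherits(master, "master_map"))
  if (is.null(n_fixations)) n_fixations <- max(1L, round(3 * exposure))
  n_fixations <- as.integer(n_fixations)
  stopifnot(n_fixations >= 1L)
  vals <- master$values
  h <- nrow(vals); w <- ncol(vals)
  r <- master$inhibition_radius_px
  if (r >= min(h, w)) {
    stop("inhibition radius must be smaller than the frame", call. = FALSE)
  }
  xs <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  ys <- matrix(seq_len(h) - 1, h, w, byrow = FALSE)
  fx <- numeric(0); fy <- numeric(0)
  m0 <- max(vals)
  for (k in seq_len(n_fixations)) {
    m <- max(vals)
    # non-positive saliency is never attended; the relative floor guards
    # against numerical dust left by FFT-based filtering
    if (!is.finite(m) || m <= 0 || m <= 1e-9 * m0) {
      warning(sprintf(
        "no attendable saliency left after %d fixation(s); scanpath truncated",
        k - 1L), call. = FALSE)
      break
    }
    cand <- which(vals == m)
    # row-major tie-break: smallest row, then smallest column
    rows <- (cand - 1L) %% h; cols <- (cand - 1L) %/% h
    pick <- order(rows, cols)[1L]
    cx <- cols[pick]; cy <- rows[pick]
    fx <- c(fx, cx); fy <- c(fy, cy)
    vals[(xs - cx)^2 + (ys - cy)^2 <= r^2] <- -Inf
  }
  n <- length(fx)
  if (n == 0L) {
    return(scanpath(numeric(0), numeric(0), duration = numeric(0),
                    frame_size = c(h, w)))
  }
  dur <- rep(exposure / n_fixations, n)
  scanpath(fx, fy, onset = cumsum(c(0, dur[-n])) , duration = dur,
           frame_size = c(h, w))
}
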