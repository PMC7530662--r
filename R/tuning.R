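#' Saliency map accumulated from fixations
#'
#' Builds an empirical saliency map by adding a Gaussian bump (width
#' `sigma_deg` degrees of visual angle) at every fixation, the standard
#' construction for NSS-based evaluation and tuning.
#'
#' @param fixations a [scanpath()] (or list of scanpaths, pooled).
#' @param frame_size `(H, W)` in pixels.
#' @param pixels_per_degree viewing-geometry scale.
#' @param sigma_deg bump width in degrees.
#' @return an H x W non-negative matrix.
#' @export
fixation_saliency_map <- function(fixations, frame_size,
                                  pixels_per_degree = 12.8,
                                  sigma_deg = 1) {
  if (inherits(fixations, "scanpath")) fixations <- list(fixations)
  h <- frame_size[1L]; w <- frame_size[2L]
  sigma <- deg2px(sigma_deg, pixels_per_degree)
  sal <- matrix(0, h, w)
  xs <- seq_len(w) - 1
  ys <- seq_len(h) - 1
  for (sp in fixations) {
    for (i in seq_len(nrow(sp))) {
      gx <- exp(-(xs - sp$x[i])^2 / (2 * sigma^2))
      gy <- exp(-(ys - sp$y[i])^2 / (2 * sigma^2))
      sal <- sal + outer(gy, gx)
    }
  }
  sal
}

#' Grid-search tuning of simulation parameters by NSS
#'
#' For each point of a parameter lattice, the model is simulated on a
#' set of held-out images, an empirical saliency map is accumulated from
#' the simulated fixations (Gaussian bump of 1 degree per fixation), and
#' the mean NSS of that map against the human fixations is computed. The
#' lattice point with maximal mean NSS wins; ties are broken by
#' first-in-grid order, so repeat runs are identical.
#'
#' @param stimuli a list of [retina_frame()]s or `mass_distribution`s
#'   (the held-out validation images).
#' @param humans a list (parallel to `stimuli`) of lists of human
#'   [scanpath()]s.
#' @param grid a data frame whose columns are [sim_params()] fields
#'   (e.g. `lam`, `beta`); each row is one lattice point.
#' @param base_params a [sim_params()] supplying every field the grid
#'   does not vary.
#' @param speed_threshold,min_duration fixation-detection settings used
#'   on the simulated trajectories.
#' @return a list with `best` (the winning [sim_params()]), `best_row`
#'   (its row index) and `scores` (`grid` plus an `nss` column).
#' @export
grid_search_tune <- function(stimuli, humans, grid,
                             base_params = sim_params(),
                             speed_threshold = 50, min_duration = 0.08) {
  stopifnot(is.data.frame(grid))
  if (nrow(grid) == 0L) {
    stop("the parameter grid is empty", call. = FALSE)
  }
  if (length(stimuli) < 1L || length(humans) != length(stimuli)) {
    stop("`humans` must have one entry per stimulus", call. = FALSE)
  }
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    p <- base_params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][g]
    class(p) <- "sim_params"
    img_scores <- vapply(seq_along(stimuli), function(i) {
      stim <- stimuli[[i]]
      res <- simulate_attention(stim, p)
      fix <- detect_fixations(res$trajectory,
                              speed_threshold = speed_threshold,
                              min_duration = min_duration)
      if (nrow(fix) == 0L) return(NA_real_)
      fs <- attr(res$trajectory, "frame_size")
      sal <- fixation_saliency_map(
        fix, fs, pixels_per_degree = stim$pixels_per_degree)
      if (stats::sd(sal) == 0) return(NA_real_)
      mean(vapply(humans[[i]], function(hu) nss(sal, hu), numeric(1L)))
    }, numeric(1L))
    scores[g] <- mean(img_scores, na.rm = TRUE)
  }
  best_row <- which.max(replace(scores, is.na(scores), -Inf))
  best <- base_params
  for (nm in names(grid)) best[[nm]] <- grid[[nm]][best_row]
  class(best) <- "sim_params"
  list(best = best, best_row = best_row,
       scores = cbind(grid, nss = scores))
}
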