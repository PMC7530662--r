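#' @title Desk-scale scanpath benchmark
#'
#' @description
#' A fully synthetic, reproducible benchmark comparing the gravitational
#' model against the winner-take-all baseline with the scanpath metrics.
#' Each stimulus is a textured-patch scene ([make_texture_scene()]): two
#' high-contrast texture patches (the salient objects) plus two weak
#' distractor patches on a uniform background. Synthetic observers tour
#' the salient patch centers in nearest-neighbor order with positional
#' jitter, emulating the short-saccade preference of human free viewing.
#' Both models run on the same frame; fixations are compared against the
#' observers with SED, TDE and STDE, and aggregated per image.
#'
#' @name benchmark
NULL

#' Simulation parameters used by the desk-scale benchmark
#'
#' The damping and the (equal) feature gains were calibrated once for the
#' sparse synthetic scenes with the package's own NSS grid-search tuning
#' protocol; sparse scenes carry far less total feature mass than natural
#' images, so the calibrated gain is well above 1 while the damping stays
#' near critical for single-object capture.
#'
#' @param duration viewing time in seconds.
#' @param a0 initial focus (see [sim_params()]).
#' @param seed integer seed.
#' @param lam damping; see [sim_params()].
#' @return a [sim_params()].
#' @export
benchmark_params <- function(duration = 5, a0 = "center", seed = 1L,
                             lam = 2) {
  sim_params(lam = lam, beta = 0.1, alphas = rep(60, 8L),
             duration = duration, dt = 0.02, time_scale = 16,
             a0 = a0, seed = seed)
}

#' Synthetic observers for a benchmark scene
#'
#' @param centers salient-patch centers (n x 2).
#' @param frame_size `(H, W)` of the scene.
#' @param n_subjects number of observers.
#' @param n_fix fixations per observer.
#' @param jitter_sd positional jitter (px).
#' @param seed integer seed.
#' @return a list of [scanpath()]s.
#' @export
benchmark_observers <- function(centers, frame_size = c(96L, 96L),
                                n_subjects = 10L, n_fix = 6L,
                                jitter_sd = 2, seed = 1L) {
  start <- c((frame_size[2L] - 1) / 2, (frame_size[1L] - 1) / 2)
  ord <- attractor_tour(centers, start, n_fix)
  lapply(seq_len(n_subjects), function(j) {
    make_synthetic_observers(centers[ord, , drop = FALSE],
                             n_subjects = 1L, jitter_sd = jitter_sd,
                             frame_size = frame_size,
                             seed = seed + 7L * j)[[1L]]
  })
}

#' Run the gravitational model on one benchmark scene
#'
#' Simulates the attention trajectory and detects fixations.
#'
#' @param frame the scene [retina_frame()].
#' @param params a [sim_params()], typically [benchmark_params()].
#' @return a [scanpath()].
#' @export
benchmark_grav_scanpath <- function(frame, params = benchmark_params()) {
  res <- simulate_attention(frame, params)
  suppressWarnings(detect_fixations(res$trajectory))
}

#' Run the winner-take-all baseline on one benchmark scene
#'
#' @param frame the scene [retina_frame()].
#' @param exposure viewing time in seconds.
#' @return a [scanpath()].
#' @export
benchmark_wta_scanpath <- function(frame, exposure = 5) {
  master <- combine_equal(
    feature_magnitudes(extract_features(frame)),
    inhibition_radius_px = deg2px(2, frame$pixels_per_degree)
  )
  suppressWarnings(wta_scanpath(master, exposure = exposure))
}

#' Run the full desk-scale benchmark
#'
#' Generates `n_images` textured-patch scenes and `n_subjects` synthetic
#' observers per scene, runs both models, and scores them against the
#' observers. Images where the gravitational scanpath has fewer
#' fixations than the embedding length are dropped (with a warning).
#'
#' @param n_images number of scenes.
#' @param n_subjects observers per scene.
#' @param seed integer seed controlling scenes and observers.
#' @param params gravitational-model parameters
#'   ([benchmark_params()] by default).
#' @param metric a [metric_params()].
#' @return a data frame with one row per image and model and columns
#'   `image`, `model`, `sed`, `tde`, `stde`.
#' @export
run_benchmark <- function(n_images = 20L, n_subjects = 10L, seed = 1L,
                          params = benchmark_params(),
                          metric = metric_params()) {
  rows <- list()
  for (i in seq_len(n_images)) {
    sseed <- seed * 1000L + i
    scene <- make_texture_scene(seed = sseed)
    obs <- benchmark_observers(scene$centers,
                               frame_size = dim(scene$frame),
                               n_subjects = n_subjects, seed = sseed)
    grav <- benchmark_grav_scanpath(scene$frame, params)
    if (nrow(grav) < metric$embed_k) {
      warning(sprintf("image %d dropped: %d gravitational fixation(s)",
                      i, nrow(grav)), call. = FALSE)
      next
    }
    wta <- benchmark_wta_scanpath(scene$frame, exposure = params$duration)
    if (nrow(wta) < metric$embed_k) {
      warning(sprintf("image %d dropped: %d WTA fixation(s)",
                      i, nrow(wta)), call. = FALSE)
      next
    }
    fs <- dim(scene$frame)
    for (model in c("grav", "wta")) {
      sp <- if (model == "grav") grav else wta
      vals <- suppressWarnings(evaluate_image(sp, obs, fs, metric))
      rows[[length(rows) + 1L]] <- data.frame(
        image = i, model = model,
        sed = vals[["sed"]], tde = vals[["tde"]], stde = vals[["stde"]]
      )
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark run per model
#'
#' Mean and standard deviation of each metric over images, the shape in
#' which scanpath-model comparisons are conventionally tabulated.
#'
#' @param results the data frame from [run_benchmark()].
#' @return a data frame with one row per model and metric.
#' @export
summarize_benchmark <- function(results) {
  out <- do.call(rbind, lapply(split(results, results$model), function(d) {
    data.frame(
      model = d$model[1L],
      metric = c("sed", "tde", "stde"),
      mean = c(mean(d$sed), mean(d$tde), mean(d$stde)),
      sd = c(stats::sd(d$sed), stats::sd(d$tde), stats::sd(d$stde))
    )
  }))
  rownames(out) <- NULL
  out
}
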