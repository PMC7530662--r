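#' Synthetic stimulus with known attractor structure
#'
#' Generates a parametric test stimulus: a constant gray background plus
#' optional Gaussian blobs, a uniform square, and a rectangular patch of
#' i.i.d. Gaussian noise. Blobs and squares produce feature mass
#' concentrated on their contours (gradients), with the contour's center
#' of mass at the blob/square center; the noise patch produces spatially
#' spread mass, emulating the classic texture-versus-object scenario.
#'
#' @param size `(H, W)` in pixels.
#' @param blobs list of blobs, each `list(center = c(x, y), sigma,
#'   amplitude = 0.5, channel = 0)`; `channel = 0` adds to all three
#'   channels, 1..3 to one.
#' @param square optional `list(rect = c(x0, y0, x1, y1), value = 1)`,
#'   a uniform axis-aligned square/rectangle.
#' @param noise_region optional `list(rect = c(x0, y0, x1, y1),
#'   sd = 0.25)`, i.i.d. Gaussian noise added inside the rectangle.
#' @param background background gray level.
#' @param pixels_per_degree viewing scale; the default treats the frame
#'   width as 17.5 degrees of visual field.
#' @param seed integer seed; generation is bit-reproducible per seed.
#' @return a [retina_frame()].
#' @export
make_blob_stimulus <- function(size = c(64L, 64L), blobs = list(),
                               square = NULL, noise_region = NULL,
                               background = 0.5,
                               pixels_per_degree = size[2L] / 17.5,
                               seed = 1L) {
  h <- size[1L]; w <- size[2L]
  px <- array(background, dim = c(h, w, 3L))
  xs <- seq_len(w) - 1
  ys <- seq_len(h) - 1
  for (b in blobs) {
    stopifnot(length(b$center) == 2L,
              b$center[1L] >= 0, b$center[1L] <= w - 1,
              b$center[2L] >= 0, b$center[2L] <= h - 1)
    amp <- if (is.null(b$amplitude)) 0.5 else b$amplitude
    ch <- if (is.null(b$channel)) 0L else b$channel
    gx <- exp(-(xs - b$center[1L])^2 / (2 * b$sigma^2))
    gy <- exp(-(ys - b$center[2L])^2 / (2 * b$sigma^2))
    bump <- amp * outer(gy, gx)
    for (k in if (ch == 0L) 1:3 else ch) px[, , k] <- px[, , k] + bump
  }
  if (!is.null(square)) {
    r <- square$rect
    val <- if (is.null(square$value)) 1 else square$value
    rows <- (floor(r[2L]) + 1L):(floor(r[4L]) + 1L)
    cols <- (floor(r[1L]) + 1L):(floor(r[3L]) + 1L)
    px[rows, cols, ] <- val
  }
  if (!is.null(noise_region)) {
    r <- noise_region$rect
    nsd <- if (is.null(noise_region$sd)) 0.25 else noise_region$sd
    rows <- (floor(r[2L]) + 1L):(floor(r[4L]) + 1L)
    cols <- (floor(r[1L]) + 1L):(floor(r[3L]) + 1L)
    noise <- withr::with_seed(seed, {
      matrix(stats::rnorm(length(rows) * length(cols), 0, nsd),
             length(rows), length(cols))
    })
    for (k in 1:3) px[rows, cols, k] <- px[rows, cols, k] + noise
  }
  px[px < 0] <- 0
  px[px > 1] <- 1
  retina_frame(px, pixels_per_degree = pixels_per_degree)
}

#' Synthetic free-viewing observers
#'
#' Generates "human-like" fixation sequences over a known ordered list of
#' salient locations: every observer visits the attractors in order,
#' with isotropic Gaussian positional jitter and lognormal fixation
#' durations (onsets cumulative, with a short saccade gap between
#' fixations). This is a stand-in for eye-tracking data in tests and
#' benchmarks, not a model of human eye-movement statistics.
#'
#' @param attractors an n x 2 matrix (or list of 2-vectors) of `(x, y)`
#'   locations, in visiting order.
#' @param n_subjects number of observers.
#' @param jitter_sd isotropic positional jitter in pixels (0 puts every
#'   fixation exactly on its attractor).
#' @param frame_size `(H, W)` in pixels; positions are clamped inside.
#' @param fix_dur median fixation duration in seconds.
#' @param dur_sdlog log-scale spread of the lognormal durations.
#' @param saccade_gap inter-fixation gap in seconds.
#' @param seed integer seed; generation is reproducible per seed.
#' @return a list of `n_subjects` [scanpath()]s.
#' @export
make_synthetic_observers <- function(attractors, n_subjects = 10L,
                                     jitter_sd = 2, frame_size,
                                     fix_dur = 0.25, dur_sdlog = 0.2,
                                     saccade_gap = 0.03, seed = 1L) {
  if (is.list(attractors)) attractors <- do.call(rbind, attractors)
  attractors <- as.matrix(attractors)
  stopifnot(ncol(attractors) == 2L, n_subjects >= 1L, jitter_sd >= 0)
  n <- nrow(attractors)
  h <- frame_size[1L]; w <- frame_size[2L]
  withr::with_seed(seed, {
    lapply(seq_len(n_subjects), function(s) {
      x <- pmin(pmax(attractors[, 1L] + stats::rnorm(n, 0, jitter_sd), 0),
                w - 1)
      y <- pmin(pmax(attractors[, 2L] + stats::rnorm(n, 0, jitter_sd), 0),
                h - 1)
      dur <- stats::rlnorm(n, meanlog = log(fix_dur), sdlog = dur_sdlog)
      onset <- cumsum(c(0, dur[-n] + saccade_gap))
      scanpath(x, y, onset = onset, duration = dur,
               frame_size = frame_size)
    })
  })
}

#' Materialize a demo eye-tracking dataset on disk
#'
#' Writes a small synthetic dataset shaped like an eye-tracking corpus:
#' `images/stim_<i>.png` plus `scanpaths/stim_<i>/subject_<j>.csv`.
#' Stimuli are multi-blob scenes; observers visit the blob centers with
#' jitter.
#'
#' @param dir output directory (created if needed).
#' @param n_images number of stimuli.
#' @param n_subjects observers per stimulus.
#' @param size frame size `(H, W)`.
#' @param n_blobs blobs per stimulus.
#' @param n_fix fixations per observer (a nearest-neighbor tour over the
#'   blob centers, with revisits once all are seen).
#' @param jitter_sd observer jitter (px).
#' @param seed integer seed.
#' @return `dir`, invisibly.
#' @export
make_demo_dataset <- function(dir, n_images = 5L, n_subjects = 5L,
                              size = c(64L, 64L), n_blobs = 3L,
                              n_fix = 6L, jitter_sd = 2, seed = 1L) {
  img_dir <- file.path(dir, "images")
  sp_dir <- file.path(dir, "scanpaths")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_images)) {
    scene <- make_blob_scene(size, n_blobs = n_blobs,
                             seed = seed + 1000L * i)
    save_frame_png(scene$frame,
                   file.path(img_dir, sprintf("stim_%03d.png", i)))
    start <- c((size[2L] - 1) / 2, (size[1L] - 1) / 2)
    tour <- attractor_tour(scene$centers, start, n_fix)
    obs <- make_synthetic_observers(scene$centers[tour, , drop = FALSE],
                                    n_subjects = n_subjects,
                                    jitter_sd = jitter_sd,
                                    frame_size = size,
                                    seed = seed + 1000L * i + 1L)
    d <- file.path(sp_dir, sprintf("stim_%03d", i))
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_along(obs)) {
      write_scanpath(obs[[j]], file.path(d, sprintf("subject_%02d.csv", j)))
    }
  }
  invisible(dir)
}

#' Random textured-patch scene
#'
#' Generates a stimulus made of square patches of i.i.d. Gaussian texture
#' on a uniform gray background: `n_strong` high-contrast patches (the
#' salient objects observers fixate) and `n_weak` low-contrast distractor
#' patches (minor clutter that gives a winner-take-all selector
#' additional candidate locations). Texture patches carry feature mass
#' across their whole area, so their center of mass coincides with the
#' patch center.
#'
#' @param size frame size `(H, W)`.
#' @param n_strong,n_weak number of salient and distractor patches.
#' @param side_strong,side_weak patch side lengths (px).
#' @param sd_strong texture contrast range (sd of the pixel noise) for
#'   salient patches; a value per patch is drawn uniformly from it.
#' @param sd_weak texture contrast of distractor patches.
#' @param min_sep minimum center-to-center separation (px).
#' @param pixels_per_degree viewing scale of the stimulus.
#' @param seed integer seed.
#' @return `list(frame = retina_frame, centers = strong-patch centers
#'   (n_strong x 2), all_centers = every patch center)`.
#' @export
make_texture_scene <- function(size = c(96L, 96L), n_strong = 2L,
                               n_weak = 2L, side_strong = 8L,
                               side_weak = 6L,
                               sd_strong = c(0.2, 0.35), sd_weak = 0.08,
                               min_sep = 30,
                               pixels_per_degree = 12.8, seed = 1L) {
  h <- size[1L]; w <- size[2L]
  n <- n_strong + n_weak
  margin <- max(side_strong, side_weak) / 2 + 3
  gen <- withr::with_seed(seed, {
    pts <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(pts) < n && tries < 20000L) {
      cand <- round(c(stats::runif(1, margin, w - 1 - margin),
                      stats::runif(1, margin, h - 1 - margin)))
      ok <- nrow(pts) == 0L ||
        all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2L,
                                       byrow = TRUE))^2)) >= min_sep)
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
    }
    if (nrow(pts) < n) {
      stop("could not place the requested patches; frame too small",
           call. = FALSE)
    }
    list(pts = pts,
         sds = c(stats::runif(n_strong, sd_strong[1L],
                              sd_strong[length(sd_strong)]),
                 rep(sd_weak, n_weak)))
  })
  px <- array(0.5, dim = c(h, w, 3L))
  sides <- c(rep(side_strong, n_strong), rep(side_weak, n_weak))
  for (i in seq_len(n)) {
    half <- sides[i] / 2
    rows <- (gen$pts[i, 2L] - half + 1L):(gen$pts[i, 2L] + half)
    cols <- (gen$pts[i, 1L] - half + 1L):(gen$pts[i, 1L] + half)
    noise <- withr::with_seed(seed * 131L + i, {
      matrix(stats::rnorm(length(rows) * length(cols), 0, gen$sds[i]),
             length(rows), length(cols))
    })
    for (k in 1:3) px[rows, cols, k] <- pmin(pmax(0.5 + noise, 0), 1)
  }
  list(
    frame = retina_frame(px, pixels_per_degree = pixels_per_degree),
    centers = unname(gen$pts[seq_len(n_strong), , drop = FALSE]),
    all_centers = unname(gen$pts)
  )
}

#' Nearest-neighbor tour over attractor locations
#'
#' Orders attractor visits the way free-viewing observers tend to scan a
#' sparse scene: starting from `start` (typically the frame center), the
#' nearest unvisited attractor is taken next; once all are visited the
#' tour keeps cycling (revisits), never repeating the current location.
#' Feeding the toured sequence to [make_synthetic_observers()] yields
#' observers with the short-saccade preference typical of human
#' scanpaths.
#'
#' @param centers an n x 2 matrix of attractor `(x, y)` locations.
#' @param start the 2-vector starting location.
#' @param n_fix total number of visits to emit.
#' @return an integer vector of row indices into `centers`.
#' @export
attractor_tour <- function(centers, start, n_fix) {
  centers <- as.matrix(centers)
  ord <- integer(0)
  cur <- start
  left <- seq_len(nrow(centers))
  while (length(ord) < n_fix) {
    if (length(left) == 0L) {
      left <- setdiff(seq_len(nrow(centers)), ord[length(ord)])
    }
    d <- sqrt((centers[left, 1L] - cur[1L])^2 +
              (centers[left, 2L] - cur[2L])^2)
    pick <- left[which.min(d)]
    ord <- c(ord, pick)
    cur <- centers[pick, ]
    left <- setdiff(left, pick)
  }
  ord
}

#' Random multi-blob scene with well-separated blobs
#'
#' Draws `n_blobs` blob centers, rejection-sampled to keep them at least
#' `min_sep` pixels apart and away from the borders, and renders the
#' stimulus. Used by the demo dataset and the desk-scale benchmarks.
#'
#' @param size frame size `(H, W)`.
#' @param n_blobs number of blobs.
#' @param sigma blob width (px).
#' @param min_sep minimum center separation (px).
#' @param amplitude blob amplitude.
#' @param seed integer seed.
#' @return `list(frame = retina_frame, centers = n x 2 matrix)`.
#' @export
make_blob_scene <- function(size = c(64L, 64L), n_blobs = 3L, sigma = 4,
                            min_sep = 20, amplitude = 0.5, seed = 1L) {
  h <- size[1L]; w <- size[2L]
  margin <- ceiling(3 * sigma)
  centers <- withr::with_seed(seed, {
    pts <- matrix(numeric(0), 0L, 2L)
    tries <- 0L
    while (nrow(pts) < n_blobs && tries < 10000L) {
      cand <- c(stats::runif(1, margin, w - 1 - margin),
                stats::runif(1, margin, h - 1 - margin))
      ok <- nrow(pts) == 0L ||
        all(sqrt(rowSums((pts - matrix(cand, nrow(pts), 2L,
                                       byrow = TRUE))^2)) >= min_sep)
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
    }
    if (nrow(pts) < n_blobs) {
      stop("could not place the requested blobs; frame too small",
           call. = FALSE)
    }
    pts
  })
  blobs <- lapply(seq_len(n_blobs), function(i) {
    list(center = centers[i, ], sigma = sigma, amplitude = amplitude)
  })
  list(
    frame = make_blob_stimulus(size, blobs = blobs, seed = seed),
    centers = unname(centers)
  )
}
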