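#' @title Scanpath similarity metrics
#'
#' @description
#' Three metrics compare a simulated scanpath against human ones:
#' string-edit distance (SED) on grid-quantized fixation sequences
#' (lower is better), time-delay embeddings (TDE), the mean over human
#' subsequences of the minimum Euclidean distance to any simulated
#' subsequence of the same length (lower is better), and scaled
#' time-delay embeddings (STDE), the same with coordinates normalized to
#' \[0, 1\] by the frame size and mapped through `exp(-d)` to a
#' similarity in (0, 1\] (higher is better). The NSS saliency score
#' supports parameter tuning.
#'
#' @name metrics
NULL

#' Metric hyper-parameters
#'
#' @param grid_m number of grid partitions per side for the string-edit
#'   quantization (the stimulus is divided into `grid_m x grid_m`
#'   regions).
#' @param embed_k subsequence (window) length for the time-delay
#'   embedding metrics.
#' @return a list of class `metric_params`.
#' @export
metric_params <- function(grid_m = 5L, embed_k = 3L) {
  grid_m <- as.integer(grid_m); embed_k <- as.integer(embed_k)
  stopifnot(grid_m >= 2L, embed_k >= 1L, grid_m^2 <= 1296L)
  structure(list(grid_m = grid_m, embed_k = embed_k),
            class = "metric_params")
}

# label alphabet: single characters up to 62 cells, two-character
# alphanumeric pairs beyond (up to 62^2 = 3844 >= 1296)
.cell_labels <- function(n_cells) {
  syms <- c(letters, LETTERS, as.character(0:9))
  if (n_cells <= length(syms)) {
    syms[seq_len(n_cells)]
  } else {
    as.vector(outer(syms, syms, paste0))[seq_len(n_cells)]
  }
}

#' Quantize a scanpath into a character sequence
#'
#' The frame is divided into `grid_m x grid_m` regions labeled with
#' characters in row-major order; each fixation is mapped to the label of
#' its containing cell. Cells are half-open (a fixation exactly on an
#' interior boundary belongs to the right/lower cell); the last row and
#' column are closed.
#'
#' @param sp a [scanpath()].
#' @param frame_size `(H, W)`; defaults to the scanpath's own frame.
#' @param grid_m partitions per side.
#' @return a character vector, one label per fixation, with the 0-based
#'   cell indices as attribute `"cell"`.
#' @export
scanpath_to_string <- function(sp, frame_size = NULL, grid_m = 5L) {
  stopifnot(inherits(sp, "scanpath"))
  if (is.null(frame_size)) frame_size <- attr(sp, "frame_size")
  h <- frame_size[1L]; w <- frame_size[2L]
  if (any(sp$x < 0 | sp$x >= w | sp$y < 0 | sp$y >= h)) {
    stop("fixation outside the frame", call. = FALSE)
  }
  col <- pmin(floor(sp$x * grid_m / w), grid_m - 1)
  row <- pmin(floor(sp$y * grid_m / h), grid_m - 1)
  cell <- as.integer(row * grid_m + col)
  labels <- .cell_labels(grid_m^2)[cell + 1L]
  attr(labels, "cell") <- cell
  labels
}

#' String-edit (Levenshtein) distance
#'
#' Minimal number of insertions, deletions and substitutions turning one
#' symbol sequence into the other, by dynamic programming with unit
#' costs. Sequences are compared element-wise, so both character vectors
#' (one symbol per element) and integer vectors are accepted.
#'
#' @param s1,s2 atomic vectors of symbols.
#' @return a non-negative integer.
#' @export
edit_distance <- function(s1, s2) {
  n <- length(s1); m <- length(s2)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (s1[i] == s2[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' String-edit distance between two scanpaths
#'
#' @param spA,spB non-empty [scanpath()]s on the same frame.
#' @param frame_size `(H, W)`; defaults to `spA`'s frame.
#' @param params a [metric_params()].
#' @return the edit distance between the quantized sequences (lower is
#'   better).
#' @export
sed <- function(spA, spB, frame_size = NULL, params = metric_params()) {
  if (nrow(spA) == 0L || nrow(spB) == 0L) {
    stop("SED is undefined for empty scanpaths", call. = FALSE)
  }
  if (is.null(frame_size)) frame_size <- attr(spA, "frame_size")
  edit_distance(
    scanpath_to_string(spA, frame_size, params$grid_m),
    scanpath_to_string(spB, frame_size, params$grid_m)
  )
}

# all length-k windows of a scanpath as rows of a (n-k+1) x 2k matrix of
# concatenated (x1, y1, ..., xk, yk) coordinates
.windows <- function(x, y, k) {
  n <- length(x)
  idx <- seq_len(n - k + 1L)
  out <- matrix(0, length(idx), 2L * k)
  for (j in seq_len(k)) {
    out[, 2L * j - 1L] <- x[idx + j - 1L]
    out[, 2L * j] <- y[idx + j - 1L]
  }
  out
}

#' Time-delay embedding distance between scanpaths
#'
#' For every subsequence of `embed_k` consecutive fixations of the human
#' scanpath, the minimum Euclidean distance to any length-`embed_k`
#' subsequence of the simulated scanpath is found (distances between the
#' concatenated coordinate vectors, divided by `embed_k` so values are a
#' per-fixation average); the metric is the mean of these minima. Zero
#' iff every human window occurs exactly in the simulation.
#'
#' @param human,sim [scanpath()]s with at least `embed_k` fixations.
#' @param embed_k window length.
#' @return a non-negative real, in pixels (lower is better).
#' @export
tde <- function(human, sim, embed_k = 3L) {
  k <- as.integer(embed_k)
  if (nrow(human) < k || nrow(sim) < k) {
    stop(sprintf("both scanpaths need at least %d fixations", k),
         call. = FALSE)
  }
  wh <- .windows(human$x, human$y, k)
  ws <- .windows(sim$x, sim$y, k)
  # exact per-pair distances (scanpaths are short; avoids the cancellation
  # error of the quadratic-expansion trick so identical windows give 0)
  mins <- vapply(seq_len(nrow(wh)), function(i) {
    diffs <- ws - matrix(wh[i, ], nrow(ws), ncol(ws), byrow = TRUE)
    sqrt(min(rowSums(diffs^2)))
  }, numeric(1L))
  mean(mins) / k
}

#' Scaled time-delay embedding similarity
#'
#' [tde()] computed on coordinates normalized to \[0, 1\] by the frame
#' width and height, mapped to a similarity score `exp(-d)` in (0, 1\]
#' (1 for identical scanpaths; higher is better).
#'
#' @param human,sim [scanpath()]s.
#' @param frame_size `(H, W)`; defaults to `human`'s frame.
#' @param embed_k window length.
#' @return a similarity in (0, 1\].
#' @export
stde <- function(human, sim, frame_size = NULL, embed_k = 3L) {
  if (is.null(frame_size)) frame_size <- attr(human, "frame_size")
  h <- frame_size[1L]; w <- frame_size[2L]
  norm_sp <- function(sp) {
    data.frame(x = sp$x / w, y = sp$y / h)
  }
  exp(-tde(norm_sp(human), norm_sp(sim), embed_k))
}

#' Normalized scanpath saliency (NSS)
#'
#' The saliency map is standardized to zero mean and unit standard
#' deviation over pixels; NSS is the mean standardized value at the
#' fixation locations (nearest-pixel sampling). Invariant under affine
#' rescaling of the map.
#'
#' @param saliency an H x W numeric matrix with nonzero variance.
#' @param fixations a non-empty [scanpath()].
#' @return the mean z-scored saliency at fixations.
#' @export
nss <- function(saliency, fixations) {
  saliency <- as.matrix(saliency)
  if (nrow(fixations) == 0L) {
    stop("NSS requires at least one fixation", call. = FALSE)
  }
  s <- stats::sd(saliency)
  if (!is.finite(s) || s == 0) {
    stop("NSS is undefined for a constant saliency map", call. = FALSE)
  }
  z <- (saliency - mean(saliency)) / s
  row <- pmin(pmax(round(fixations$y) + 1L, 1L), nrow(z))
  col <- pmin(pmax(round(fixations$x) + 1L, 1L), ncol(z))
  mean(z[cbind(row, col)])
}

#' Evaluate a simulated scanpath against human scanpaths on one image
#'
#' For each metric, the mean over human subjects of
#' `metric(sim, human_i)`. Pairs that fail a metric's preconditions
#' (e.g. fewer fixations than the embedding length) are skipped with a
#' warning.
#'
#' @param sim the simulated [scanpath()].
#' @param humans a list of human [scanpath()]s.
#' @param frame_size `(H, W)`; defaults to `sim`'s frame.
#' @param params a [metric_params()].
#' @return a named numeric vector `c(sed = , tde = , stde = )`.
#' @export
evaluate_image <- function(sim, humans, frame_size = NULL,
                           params = metric_params()) {
  stopifnot(length(humans) >= 1L)
  if (is.null(frame_size)) frame_size <- attr(sim, "frame_size")
  vals <- lapply(humans, function(hu) {
    tryCatch(
      c(sed = sed(hu, sim, frame_size, params),
        tde = tde(hu, sim, params$embed_k),
        stde = stde(hu, sim, frame_size, params$embed_k)),
      error = function(e) {
        warning(sprintf("human scanpath skipped: %s", conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
  })
  vals <- vals[!vapply(vals, is.null, logical(1L))]
  if (length(vals) == 0L) {
    stop("no human scanpath satisfied the metric preconditions",
         call. = FALSE)
  }
  colMeans(do.call(rbind, vals))
}
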