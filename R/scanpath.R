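#' Scanpath: an ordered sequence of fixations
#'
#' A scanpath is a data frame with columns `x`, `y` (pixels, 0-based,
#' x rightward / y downward), `onset` and `duration` (seconds), carrying
#' the stimulus `frame_size = c(H, W)` as an attribute. Onsets must be
#' strictly increasing and durations positive; coordinates must lie inside
#' the frame.
#'
#' @param x,y fixation coordinates in pixels.
#' @param onset fixation onset times in seconds, strictly increasing. If
#'   `NULL`, onsets are synthesized as cumulative durations.
#' @param duration fixation durations in seconds, all positive.
#' @param frame_size `(H, W)` of the stimulus frame in pixels.
#' @return an object of class `scanpath` (also a `data.frame`).
#' @export
scanpath <- function(x, y, onset = NULL, duration, frame_size) {
  n <- length(x)
  if (length(y) != n || length(duration) != n) {
    stop("`x`, `y` and `duration` must have equal length", call. = FALSE)
  }
  frame_size <- as.numeric(frame_size)
  if (length(frame_size) != 2L || any(frame_size <= 0)) {
    stop("`frame_size` must be positive (H, W)", call. = FALSE)
  }
  if (is.null(onset)) {
    onset <- if (n == 0L) numeric(0) else cumsum(c(0, duration[-n]))
  }
  if (length(onset) != n) {
    stop("`onset` must match the number of fixations", call. = FALSE)
  }
  sp <- data.frame(x = as.numeric(x), y = as.numeric(y),
                   onset = as.numeric(onset), duration = as.numeric(duration))
  if (n > 0L) {
    if (any(!is.finite(as.matrix(sp)))) {
      stop("scanpath fields must be finite", call. = FALSE)
    }
    if (any(diff(sp$onset) <= 0)) {
      stop("fixation onsets must be strictly increasing", call. = FALSE)
    }
    if (any(sp$duration <= 0)) {
      stop("fixation durations must be positive", call. = FALSE)
    }
    if (any(sp$x < 0 | sp$x >= frame_size[2L] |
            sp$y < 0 | sp$y >= frame_size[1L])) {
      stop("fixation coordinates must lie inside the frame", call. = FALSE)
    }
  }
  structure(sp, frame_size = frame_size, class = c("scanpath", "data.frame"))
}

#' @export
print.scanpath <- function(x, ...) {
  fs <- attr(x, "frame_size")
  cat(sprintf("<scanpath> %d fixations on a %g x %g px frame\n",
              nrow(x), fs[1L], fs[2L]))
  if (nrow(x) > 0L) print.data.frame(x, ...)
  invisible(x)
}

#' Column dialect for delimited fixation files
#'
#' Maps the columns of an eye-tracking fixation export onto the scanpath
#' schema, so listings in different column orders (or without timing
#' columns) can be ingested by [read_scanpath()] without bespoke parsers.
#' Columns are given as names (when the file has a header) or 1-based
#' indices.
#'
#' @param x,y,onset,duration column names or indices; `onset`/`duration`
#'   may be `NA` when the file lacks them.
#' @param sep field separator.
#' @param header whether the file has a header row.
#' @param default_duration duration (s) assigned when the file has no
#'   duration column.
#' @return a list of class `scanpath_dialect`.
#' @export
scanpath_dialect <- function(x = "x", y = "y", onset = "onset",
                             duration = "duration", sep = ",",
                             header = TRUE, default_duration = 0.25) {
  structure(
    list(x = x, y = y, onset = onset, duration = duration, sep = sep,
         header = header, default_duration = default_duration),
    class = "scanpath_dialect"
  )
}

.dialect_col <- function(df, key) {
  if (length(key) != 1L || is.na(key)) return(NULL)
  if (is.numeric(key)) {
    if (key >= 1 && key <= ncol(df)) df[[key]] else NULL
  } else if (key %in% names(df)) {
    df[[key]]
  } else {
    NULL
  }
}

#' Read a scanpath from a delimited fixation file
#'
#' Parses a delimited text file of fixations according to a column
#' dialect. Rows are ordered by onset (with a warning if the file was out
#' of order); missing onsets are synthesized as cumulative durations;
#' coordinates outside the frame are clamped inside with a warning.
#'
#' @param path path to the delimited file.
#' @param frame_size `(H, W)` of the stimulus frame; if `NULL`, it is
#'   inferred as the smallest frame containing all fixations.
#' @param dialect a [scanpath_dialect()].
#' @return a [scanpath()].
#' @export
read_scanpath <- function(path, frame_size = NULL,
                          dialect = scanpath_dialect()) {
  if (!file.exists(path)) {
    stop(sprintf("scanpath file does not exist: '%s'", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.table(path, sep = dialect$sep, header = dialect$header,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop(sprintf("no parseable fixation rows in '%s': %s",
                   path, conditionMessage(e)), call. = FALSE)
    }
  )
  if (nrow(df) == 0L) {
    stop(sprintf("no parseable fixation rows in '%s'", path), call. = FALSE)
  }
  x <- .dialect_col(df, dialect$x)
  y <- .dialect_col(df, dialect$y)
  if (is.null(x) || is.null(y)) {
    stop(sprintf("file '%s' lacks the x/y columns named by the dialect",
                 path), call. = FALSE)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(is.na(x)) || any(is.na(y))) {
    stop(sprintf("non-numeric fixation coordinates in '%s'", path),
         call. = FALSE)
  }
  duration <- .dialect_col(df, dialect$duration)
  duration <- if (is.null(duration)) {
    rep(dialect$default_duration, length(x))
  } else {
    as.numeric(duration)
  }
  onset <- .dialect_col(df, dialect$onset)
  if (!is.null(onset)) {
    onset <- as.numeric(onset)
    if (is.unsorted(onset, strictly = TRUE)) {
      warning(sprintf("fixations in '%s' reordered by onset", path),
              call. = FALSE)
      ord <- order(onset)
      x <- x[ord]; y <- y[ord]; onset <- onset[ord]
      duration <- duration[ord]
    }
  }
  if (is.null(frame_size)) {
    frame_size <- c(floor(max(y)) + 1, floor(max(x)) + 1)
  } else {
    frame_size <- as.numeric(frame_size)
    eps <- 1e-9
    out_of_frame <- x < 0 | x > frame_size[2L] - 1 + eps |
      y < 0 | y > frame_size[1L] - 1 + eps
    if (any(out_of_frame)) {
      warning(sprintf("%d fixation(s) in '%s' clamped into the frame",
                      sum(out_of_frame), path), call. = FALSE)
      x <- pmin(pmax(x, 0), frame_size[2L] - 1)
      y <- pmin(pmax(y, 0), frame_size[1L] - 1)
    }
  }
  scanpath(x, y, onset = onset, duration = duration, frame_size = frame_size)
}

#' Write a scanpath to CSV
#'
#' Writes the fixations as CSV with header `x,y,onset,duration`, 6 decimal
#' digits, so that [read_scanpath()] round-trips within 1e-6 per field.
#'
#' @param sp a [scanpath()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scanpath <- function(sp, path) {
  stopifnot(inherits(sp, "scanpath"))
  df <- as.data.frame(sp)
  for (col in names(df)) df[[col]] <- sprintf("%.6f", df[[col]])
  ok <- tryCatch({
    utils::write.table(df, file = path, sep = ",", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write scanpath to '%s': %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(path)
}
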