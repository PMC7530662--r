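#' Velocity-threshold fixation detection (I-VT)
#'
#' Converts a continuous attention trajectory into discrete fixations
#' with the same kind of detector applied to human eye-tracking records:
#' instantaneous speed is estimated by central differences on the
#' uniformly sampled trajectory, samples slower than `speed_threshold`
#' are grouped into maximal runs, runs shorter than `min_duration` are
#' discarded, and each surviving run becomes one fixation at the run's
#' centroid, with onset at the run start and duration equal to the run
#' length.
#'
#' @param traj a `trajectory` from [simulate_attention()].
#' @param speed_threshold speed below which a sample counts as fixational,
#'   in px/s.
#' @param min_duration minimum fixation duration in seconds.
#' @return a [scanpath()]; empty (with a warning) if no run survives.
#' @export
detect_fixations <- function(traj, speed_threshold = 50,
                             min_duration = 0.08) {
  stopifnot(inherits(traj, "trajectory"),
            is.numeric(speed_threshold), speed_threshold > 0,
            is.numeric(min_duration), min_duration > 0)
  fs <- attr(traj, "frame_size")
  n <- nrow(traj)
  empty <- scanpath(numeric(0), numeric(0), duration = numeric(0),
                    frame_size = fs)
  if (n < 3L) {
    warning("trajectory too short for fixation detection", call. = FALSE)
    return(empty)
  }
  dt <- traj$t[2L] - traj$t[1L]
  if (n * dt < min_duration) {
    warning("trajectory shorter than `min_duration`; no fixations",
            call. = FALSE)
    return(empty)
  }
  # central-difference speed (px/s); one-sided at the ends
  ix <- 2:(n - 1L)
  speed <- numeric(n)
  speed[ix] <- sqrt((traj$x[ix + 1L] - traj$x[ix - 1L])^2 +
                    (traj$y[ix + 1L] - traj$y[ix - 1L])^2) / (2 * dt)
  speed[1L] <- sqrt((traj$x[2L] - traj$x[1L])^2 +
                    (traj$y[2L] - traj$y[1L])^2) / dt
  speed[n] <- sqrt((traj$x[n] - traj$x[n - 1L])^2 +
                   (traj$y[n] - traj$y[n - 1L])^2) / dt

  slow <- speed < speed_threshold
  runs <- rle(slow)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  fx <- numeric(0); fy <- numeric(0); on <- numeric(0); du <- numeric(0)
  for (j in keep) {
    i0 <- starts[j]; i1 <- ends[j]
    dur <- (i1 - i0 + 1L) * dt
    if (dur < min_duration) next
    fx <- c(fx, mean(traj$x[i0:i1]))
    fy <- c(fy, mean(traj$y[i0:i1]))
    on <- c(on, traj$t[i0])
    du <- c(du, dur)
  }
  if (length(fx) == 0L) {
    warning("no fixation runs above `min_duration`", call. = FALSE)
    return(empty)
  }
  scanpath(fx, fy, onset = on, duration = du, frame_size = fs)
}
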