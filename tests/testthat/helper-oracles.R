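# Independent oracles used across the suite. These deliberately use the
# plainest possible formulations (double loops, direct formulas) so they
# stay independent of the vectorized/compiled paths they check.

# Direct double-loop evaluation of the attraction field of a mass grid.
brute_force_field <- function(mu, focus, epsilon = 0.25) {
  ex <- 0; ey <- 0
  for (r in seq_len(nrow(mu))) {
    for (c in seq_len(ncol(mu))) {
      if (mu[r, c] == 0) next
      dx <- (c - 1) - focus[1]
      dy <- (r - 1) - focus[2]
      w <- mu[r, c] / (dx^2 + dy^2 + epsilon)
      ex <- ex + dx * w
      ey <- ey + dy * w
    }
  }
  c(ex, ey) / (2 * pi)
}

# Exhaustive window-enumeration TDE.
brute_force_tde <- function(human, sim, k) {
  nh <- nrow(human); ns <- nrow(sim)
  total <- 0
  for (i in 1:(nh - k + 1)) {
    best <- Inf
    wh <- c(rbind(human$x[i:(i + k - 1)], human$y[i:(i + k - 1)]))
    for (j in 1:(ns - k + 1)) {
      ws <- c(rbind(sim$x[j:(j + k - 1)], sim$y[j:(j + k - 1)]))
      d <- sqrt(sum((wh - ws)^2))
      if (d < best) best <- d
    }
    total <- total + best / k
  }
  total / (nh - k + 1)
}

# Direct bilinear sampling at one output pixel under the package's
# area-alignment convention, written as scalar arithmetic.
bilinear_oracle_pixel <- function(m, r_out, c_out, h_out, w_out) {
  src_r <- (r_out - 0.5) * nrow(m) / h_out - 0.5
  src_c <- (c_out - 0.5) * ncol(m) / w_out - 0.5
  src_r <- min(max(src_r, 0), nrow(m) - 1)
  src_c <- min(max(src_c, 0), ncol(m) - 1)
  r0 <- floor(src_r); c0 <- floor(src_c)
  r1 <- min(r0 + 1, nrow(m) - 1); c1 <- min(c0 + 1, ncol(m) - 1)
  fr <- src_r - r0; fc <- src_c - c0
  m[r0 + 1, c0 + 1] * (1 - fr) * (1 - fc) +
    m[r0 + 1, c1 + 1] * (1 - fr) * fc +
    m[r1 + 1, c0 + 1] * fr * (1 - fc) +
    m[r1 + 1, c1 + 1] * fr * fc
}

# Random scanpath with valid invariants.
random_scanpath <- function(n, frame_size = c(100, 100)) {
  dur <- runif(n, 0.1, 0.4)
  scanpath(
    x = runif(n, 0, frame_size[2] - 1),
    y = runif(n, 0, frame_size[1] - 1),
    onset = cumsum(c(0, dur[-n] + 0.02)),
    duration = dur,
    frame_size = frame_size
  )
}

# A small mass distribution from an explicit matrix.
mass_from_matrix <- function(mu, ppd = 12.8) {
  saliency_as_mass(mu, pixels_per_degree = ppd)
}

# Uniform-gray frame helper.
gray_frame <- function(h = 32, w = 32, value = 0.5, ppd = 12.8) {
  retina_frame(array(value, dim = c(h, w, 3)), pixels_per_degree = ppd)
}
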