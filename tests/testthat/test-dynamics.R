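test_that("the equation of motion has the damped-Newtonian form", {
  zero_mass <- suppressWarnings(mass_from_matrix(matrix(0, 16, 16)))
  st <- focus_state(c(8, 8), c(0, 0))
  d <- grav_rhs(st, zero_mass, lam = 1)
  expect_equal(d$da, c(0, 0))
  expect_equal(d$dv, c(0, 0))

  st <- focus_state(c(8, 8), c(1, 0))
  d <- grav_rhs(st, zero_mass, lam = 1)
  expect_equal(d$dv, c(-1, 0))  # pure damping

  set.seed(10)
  mu <- matrix(runif(256), 16, 16)
  mass <- mass_from_matrix(mu)
  for (i in 1:10) {
    st <- focus_state(runif(2, 0, 15), rnorm(2))
    lam <- runif(1, 0.1, 3)
    d <- grav_rhs(st, mass, lam)
    E <- field_at(mass, st$a)
    # Eq. rearrangement: dv - E + lam v = 0
    expect_equal(d$dv - E + lam * st$v, c(0, 0), tolerance = 1e-12)
    expect_equal(d$da, st$v)
  }
})

test_that("with no mass and no velocity the focus stays put", {
  zero_mass <- suppressWarnings(mass_from_matrix(matrix(0, 16, 16)))
  res <- simulate_attention(zero_mass, sim_params(duration = 1, beta = 0))
  expect_true(all(res$trajectory$x == 7.5))
  expect_true(all(res$trajectory$y == 7.5))
})

test_that("identical parameters give bit-identical trajectories", {
  fr <- make_blob_stimulus(c(32, 32),
                           blobs = list(list(center = c(20, 12), sigma = 3)),
                           seed = 1)
  p <- sim_params(duration = 1)
  r1 <- simulate_attention(fr, p)
  r2 <- simulate_attention(fr, p)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$inhibition$I, r2$inhibition$I)
})

test_that("the compiled and reference steppers agree", {
  fr <- make_blob_stimulus(c(32, 32),
                           blobs = list(list(center = c(20, 12), sigma = 3)),
                           seed = 1)
  p <- sim_params(duration = 1, a0 = c(4, 4))
  rc <- simulate_attention(fr, p, engine = "cpp")
  rr <- simulate_attention(fr, p, engine = "r")
  expect_lt(max(abs(as.matrix(rc$trajectory) - as.matrix(rr$trajectory))),
            1e-10)
  expect_lt(max(abs(rc$inhibition$I - rr$inhibition$I)), 1e-12)
})

test_that("the focus converges onto a single blob and is step-size robust", {
  fr <- make_blob_stimulus(c(64, 64),
                           blobs = list(list(center = c(40, 36), sigma = 4)),
                           seed = 1)
  mass <- compute_masses(extract_features(fr))
  idx <- which(mass$mu > 0)
  cx <- sum(((idx - 1) %/% 64) * mass$mu[idx]) / sum(mass$mu[idx])
  cy <- sum(((idx - 1) %% 64) * mass$mu[idx]) / sum(mass$mu[idx])

  end_at <- function(dt) {
    p <- sim_params(lam = 4, beta = 0, duration = 10, a0 = c(2, 2), dt = dt)
    tr <- simulate_attention(fr, p)$trajectory
    c(tr$x[nrow(tr)], tr$y[nrow(tr)])
  }
  e1 <- end_at(0.01)
  expect_lt(sqrt(sum((e1 - c(cx, cy))^2)), 2)
  e2 <- end_at(0.005)
  expect_lt(sqrt(sum((e1 - e2)^2)), 0.5)
})

test_that("the discrete potential is consistent with the field", {
  set.seed(12)
  mu <- matrix(runif(256), 16, 16)
  mass <- mass_from_matrix(mu)
  h <- 1e-5
  for (i in 1:10) {
    a <- runif(2, 2, 13)
    U <- function(p) mechanical_energy(focus_state(p, c(0, 0)), mass)
    grad <- c((U(a + c(h, 0)) - U(a - c(h, 0))) / (2 * h),
              (U(a + c(0, h)) - U(a - c(0, h))) / (2 * h))
    expect_equal(-grad, field_at(mass, a), tolerance = 1e-4)
  }
})

test_that("energy decays under damping and is conserved without it", {
  fr <- make_blob_stimulus(c(32, 32),
                           blobs = list(list(center = c(20, 16), sigma = 3)),
                           seed = 2)
  mass <- compute_masses(extract_features(fr))
  p <- sim_params(lam = 1, beta = 0, duration = 5, a0 = c(5, 5))
  tr <- simulate_attention(mass, p)$trajectory
  E <- vapply(seq(1, nrow(tr), by = 25), function(k) {
    mechanical_energy(
      focus_state(c(tr$x[k], tr$y[k]), c(tr$vx[k], tr$vy[k]) / 10), mass)
  }, numeric(1))
  expect_true(all(diff(E) <= 1e-6))

  # conservative case: a gentle circular orbit around a smooth ring mass
  xs <- matrix(0:31, 32, 32, byrow = TRUE)
  ys <- matrix(0:31, 32, 32)
  r <- sqrt((xs - 15.5)^2 + (ys - 15.5)^2)
  ring <- exp(-(r - 6)^2 / 2)
  ring_mass <- mass_from_matrix(ring / sum(ring))
  E0 <- field_at(ring_mass, c(27.5, 15.5))
  vc <- sqrt(sqrt(sum(E0^2)) * 12)
  p0 <- sim_params(lam = 0, beta = 0, duration = 5, dt = 0.01,
                   a0 = c(27.5, 15.5), v0 = c(0, vc))
  tr <- simulate_attention(ring_mass, p0)$trajectory
  E <- vapply(seq(1, nrow(tr), by = 50), function(k) {
    mechanical_energy(
      focus_state(c(tr$x[k], tr$y[k]), c(tr$vx[k], tr$vy[k]) / 10),
      ring_mass)
  }, numeric(1))
  expect_lt(max(abs(E - E[1])), 1e-6)
})

test_that("the focus never leaves the frame", {
  # heavy mass hugging a border pulls the focus against the wall
  mu <- matrix(0, 32, 32)
  mu[16, 31:32] <- 50
  mass <- mass_from_matrix(mu)
  p <- sim_params(lam = 0.2, beta = 0, duration = 5, a0 = c(3, 15))
  tr <- simulate_attention(mass, p)$trajectory
  expect_true(all(tr$x >= 0 & tr$x <= 31))
  expect_true(all(tr$y >= 0 & tr$y <= 31))
  expect_true(all(is.finite(as.matrix(tr))))
})

test_that("simulation parameter validation catches misuse", {
  expect_error(sim_params(duration = 0.5), "1, 30")
  expect_error(sim_params(beta = 1), NULL)
  expect_error(simulate_attention(list(), sim_params()), "retina_frame")
  zero_mass <- suppressWarnings(mass_from_matrix(matrix(0, 16, 16)))
  expect_error(
    simulate_attention(zero_mass, sim_params(duration = 1, dt = 50)),
    "10 steps")
})
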