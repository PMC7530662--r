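#' Focus-of-attention state
#'
#' The instantaneous state of the unit attention mass: position `a`
#' (pixels) and velocity `v` (pixels per model-time unit).
#'
#' @param a 2-vector position `(x, y)` in pixels.
#' @param v 2-vector velocity.
#' @return an object of class `focus_state`.
#' @export
focus_state <- function(a, v = c(0, 0)) {
  stopifnot(length(a) == 2L, length(v) == 2L,
            all(is.finite(a)), all(is.finite(v)))
  structure(list(a = as.numeric(a), v = as.numeric(v)),
            class = "focus_state")
}

#' Simulation parameters
#'
#' Bundles every tunable of the attention simulation. Times are split
#' between wall-clock viewing seconds (`duration`) and model-time units:
#' `time_scale` model units elapse per viewing second, and the solver
#' advances `dt` model units per step.
#'
#' @param lam damping coefficient `lambda > 0`; prevents the orbital
#'   oscillations typical of gravitational systems and produces ballistic
#'   movements onto targets.
#' @param beta inhibition-of-return relaxation rate per model-time unit,
#'   in (0, 1); 0 disables inhibition.
#' @param sigma_ior width of the inhibition bump in pixels, or `NULL` to
#'   use 2 degrees of visual angle converted through the stimulus
#'   `pixels_per_degree`.
#' @param alphas per-feature mass weights, or `NULL` for equal weights.
#' @param duration simulated viewing time in seconds, in \[1, 30\]
#'   (typical free-viewing exposures are 3 to 5 s).
#' @param dt solver step in model-time units.
#' @param time_scale model-time units per viewing second.
#' @param epsilon kernel singularity regularizer (squared pixels).
#' @param a0 initial focus: `"center"`, `"random"`, or a 2-vector (px).
#' @param v0 initial velocity (px per model-time unit).
#' @param seed integer seed, used only when `a0 = "random"`.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(lam = 1, beta = 0.1, sigma_ior = NULL,
                       alphas = NULL, duration = 3, dt = 0.01,
                       time_scale = 10, epsilon = 0.25,
                       a0 = "center", v0 = c(0, 0), seed = NULL) {
  stopifnot(is.numeric(lam), length(lam) == 1L, lam >= 0,
            is.numeric(beta), length(beta) == 1L, beta >= 0, beta < 1,
            is.numeric(duration), length(duration) == 1L,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(time_scale), length(time_scale) == 1L,
            time_scale > 0,
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0,
            length(v0) == 2L)
  if (duration < 1 || duration > 30) {
    stop("`duration` must lie in [1, 30] seconds", call. = FALSE)
  }
  if (!is.null(sigma_ior)) {
    stopifnot(is.numeric(sigma_ior), length(sigma_ior) == 1L,
              sigma_ior > 0)
  }
  if (is.character(a0)) {
    a0 <- match.arg(a0, c("center", "random"))
  } else {
    stopifnot(length(a0) == 2L, all(is.finite(a0)))
  }
  structure(
    list(lam = lam, beta = beta, sigma_ior = sigma_ior, alphas = alphas,
         duration = duration, dt = dt, time_scale = time_scale,
         epsilon = epsilon, a0 = a0, v0 = as.numeric(v0), seed = seed),
    class = "sim_params"
  )
}

#' Right-hand side of the equation of motion
#'
#' The damped Newtonian law `a'' + lambda a' - E(a) = 0` written as a
#' first-order system: `da = v`, `dv = -lambda v + E(a)`, with `E` the
#' gravitational field of the (inhibition-discounted) mass distribution.
#'
#' @param state a [focus_state()].
#' @param mass_eff the effective `mass_distribution`.
#' @param lam damping coefficient.
#' @param kernel a [gravity_kernel()].
#' @return `list(da = , dv = )`, the state derivative.
#' @export
grav_rhs <- function(state, mass_eff, lam, kernel = gravity_kernel()) {
  stopifnot(inherits(state, "focus_state"))
  E <- field_at(mass_eff, state$a, kernel)
  list(da = state$v, dv = -lam * state$v + E)
}

# One RK4 step for (a, v) under a frozen effective mass given as a
# support list (px, py, mu). Positions are not clamped here.
.rk4_step <- function(a, v, sup, mu_eff, lam, eps, dt) {
  accel <- function(a_, v_) {
    -lam * v_ + .field_from_support(sup, mu_eff, a_, eps)
  }
  k1a <- v;                 k1v <- accel(a, v)
  k2a <- v + dt / 2 * k1v;  k2v <- accel(a + dt / 2 * k1a, k2a)
  k3a <- v + dt / 2 * k2v;  k3v <- accel(a + dt / 2 * k2a, k3a)
  k4a <- v + dt * k3v;      k4v <- accel(a + dt * k3a, k4a)
  list(a = a + dt / 6 * (k1a + 2 * k2a + 2 * k3a + k4a),
       v = v + dt / 6 * (k1v + 2 * k2v + 2 * k3v + k4v))
}

#' Simulate the attention trajectory on a stimulus
#'
#' Integrates the damped Newtonian motion of the focus of attention in
#' the gravitational field of the stimulus masses, coupled to the
#' inhibition-of-return field, with an operator-split fixed-step loop:
#' at each step the effective mass `mu (1 - I)` is frozen, the focus
#' state is advanced by one RK4 step, and the inhibition field is
#' advanced by its exact exponential update. The result is deterministic
#' given `params` (the seed matters only for `a0 = "random"`).
#'
#' The focus is confined to the frame: positions are clamped to the
#' frame rectangle and the outward velocity component is zeroed at the
#' walls.
#'
#' @param x a [retina_frame()] or a `mass_distribution`.
#' @param params a [sim_params()].
#' @param engine `"cpp"` runs the compiled stepper (default); `"r"` runs
#'   the pure-R reference loop. Both implement the same scheme and agree
#'   to floating-point accumulation order.
#' @return a list with components `trajectory` (a `trajectory` data
#'   frame with columns `t` (s), `x`, `y` (px), `vx`, `vy` (px/s)) and
#'   `inhibition` (the final [inhibition_field()]).
#' @export
simulate_attention <- function(x, params = sim_params(),
                               engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "sim_params"))
  mass <- if (inherits(x, "retina_frame")) {
    stack <- extract_features(x)
    if (is.null(params$alphas)) compute_masses(stack)
    else compute_masses(stack, params$alphas)
  } else if (inherits(x, "mass_distribution")) {
    x
  } else {
    stop("`x` must be a retina_frame or a mass_distribution", call. = FALSE)
  }
  h <- mass$height_px; w <- mass$width_px
  sigma_ior <- if (is.null(params$sigma_ior)) {
    deg2px(2, mass$pixels_per_degree)
  } else {
    params$sigma_ior
  }
  n_steps <- round(params$duration * params$time_scale / params$dt)
  if (n_steps < 10L) {
    stop("duration/dt must give at least 10 steps", call. = FALSE)
  }

  a <- if (identical(params$a0, "center")) {
    c((w - 1) / 2, (h - 1) / 2)
  } else if (identical(params$a0, "random")) {
    if (!is.null(params$seed)) {
      withr::with_seed(params$seed,
                       c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1)))
    } else {
      c(stats::runif(1, 0, w - 1), stats::runif(1, 0, h - 1))
    }
  } else {
    as.numeric(params$a0)
  }
  v <- params$v0

  ior <- inhibition_field(c(h, w), beta = params$beta,
                          sigma_ior = sigma_ior)
  sup <- .mass_support(mass)
  eps <- params$epsilon
  dt <- params$dt
  ts <- params$time_scale

  if (engine == "cpp") {
    res <- .grav_sim_cpp(sup$px, sup$py, sup$mu, sup$idx,
                         h, w, params$lam, params$beta, sigma_ior, eps,
                         dt, n_steps, ts, a, v)
    traj <- as.data.frame(res$traj)
    names(traj) <- c("t", "x", "y", "vx", "vy")
    ior$I <- res$I
    return(structure(
      list(
        trajectory = structure(traj, frame_size = c(h, w),
                               class = c("trajectory", "data.frame")),
        inhibition = ior
      ),
      class = "grav_sim"
    ))
  }

  out <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 5L)
  out[1L, ] <- c(0, a, v * ts)
  for (k in seq_len(n_steps)) {
    mu_eff <- if (params$beta == 0) sup$mu else sup$mu * (1 - ior$I[sup$idx])
    st <- .rk4_step(a, v, sup, mu_eff, params$lam, eps, dt)
    a <- st$a; v <- st$v
    if (any(!is.finite(a)) || any(!is.finite(v))) {
      stop(sprintf("simulation diverged at step %d", k), call. = FALSE)
    }
    # wall clamp: zero the outward velocity component
    if (a[1L] < 0) { a[1L] <- 0; v[1L] <- max(v[1L], 0) }
    if (a[1L] > w - 1) { a[1L] <- w - 1; v[1L] <- min(v[1L], 0) }
    if (a[2L] < 0) { a[2L] <- 0; v[2L] <- max(v[2L], 0) }
    if (a[2L] > h - 1) { a[2L] <- h - 1; v[2L] <- min(v[2L], 0) }
    if (params$beta > 0) ior <- ior_step(ior, a, dt)
    out[k + 1L, ] <- c(k * dt / ts, a, v * ts)
  }
  traj <- as.data.frame(out)
  names(traj) <- c("t", "x", "y", "vx", "vy")
  structure(
    list(
      trajectory = structure(traj, frame_size = c(h, w),
                             class = c("trajectory", "data.frame")),
      inhibition = ior
    ),
    class = "grav_sim"
  )
}

#' @export
print.grav_sim <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf(
    "<grav_sim> %d samples over %.2f s; final focus (%.1f, %.1f) px\n",
    nrow(tr), tr$t[nrow(tr)], tr$x[nrow(tr)], tr$y[nrow(tr)]))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' @param traj a `trajectory` (from [simulate_attention()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Mechanical energy of the focus in a static mass field
#'
#' Test instrument for the damping contract. The potential is chosen so
#' that its negative gradient is exactly the (regularized) field:
#' `U(a) = (1/(4 pi)) sum_x mu(x) log(||a - x||^2 + epsilon)`, and the
#' energy is `||v||^2 / 2 + U(a)` (velocity in px per model-time unit).
#' Along a trajectory with static mass and inhibition off, the energy is
#' non-increasing for `lambda > 0` and conserved (up to integrator
#' tolerance) for `lambda = 0`.
#'
#' @param state a [focus_state()].
#' @param mass a `mass_distribution`.
#' @param kernel a [gravity_kernel()].
#' @return the scalar mechanical energy.
#' @export
mechanical_energy <- function(state, mass, kernel = gravity_kernel()) {
  stopifnot(inherits(state, "focus_state"),
            inherits(mass, "mass_distribution"))
  sup <- .mass_support(mass)
  dx <- sup$px - state$a[1L]
  dy <- sup$py - state$a[2L]
  U <- sum(sup$mu * log(dx * dx + dy * dy + kernel$epsilon)) / (4 * pi)
  0.5 * sum(state$v^2) + U
}
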