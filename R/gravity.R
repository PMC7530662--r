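#' Gravitational attraction kernel
#'
#' The field kernel `e(z) = z / (2 pi ||z||^2)`, regularized near the
#' singularity as `z / (2 pi (||z||^2 + epsilon))` so the discrete sum is
#' bounded when the focus coincides with a pixel center.
#'
#' @param epsilon singularity regularizer in squared pixels.
#' @return an object of class `gravity_kernel`.
#' @export
gravity_kernel <- function(epsilon = 0.25) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop("`epsilon` must be a single positive number", call. = FALSE)
  }
  structure(list(epsilon = epsilon), class = "gravity_kernel")
}

#' Evaluate the attraction kernel at an offset
#'
#' @param z a 2-vector offset in pixels.
#' @param kernel a [gravity_kernel()].
#' @return the 2-vector `z / (2 pi (||z||^2 + epsilon))`.
#' @export
kernel_eval <- function(z, kernel = gravity_kernel()) {
  stopifnot(length(z) == 2L, all(is.finite(z)))
  z / (2 * pi * (sum(z^2) + kernel$epsilon))
}

# Precomputed flat view of a mass distribution for fast field sums:
# pixel-center coordinates and masses of the pixels with nonzero mass.
.mass_support <- function(mass) {
  idx <- which(mass$mu != 0)
  list(
    px = ((idx - 1L) %/% mass$height_px),        # x = column - 1
    py = ((idx - 1L) %% mass$height_px),         # y = row - 1
    mu = mass$mu[idx],
    idx = idx
  )
}

.field_from_support <- function(sup, mu, focus, epsilon) {
  dx <- sup$px - focus[1L]
  dy <- sup$py - focus[2L]
  w <- mu / (dx * dx + dy * dy + epsilon)
  c(sum(dx * w), sum(dy * w)) / (2 * pi)
}

#' Gravitational field of a mass distribution at the focus
#'
#' Direct discrete sum of the attraction field
#' `E(a) = sum_x e(x - a) mu(x)` over all pixel centers `x`; the field
#' points toward mass concentrations.
#'
#' @param mass a `mass_distribution` (see [compute_masses()]).
#' @param focus a 2-vector `(x, y)` in pixels, inside the frame.
#' @param kernel a [gravity_kernel()].
#' @return the 2-vector field at `focus`.
#' @export
field_at <- function(mass, focus, kernel = gravity_kernel()) {
  stopifnot(inherits(mass, "mass_distribution"),
            length(focus) == 2L, all(is.finite(focus)))
  if (focus[1L] < 0 || focus[1L] > mass$width_px - 1 ||
      focus[2L] < 0 || focus[2L] > mass$height_px - 1) {
    stop("`focus` lies outside the frame", call. = FALSE)
  }
  sup <- .mass_support(mass)
  .field_from_support(sup, sup$mu, focus, kernel$epsilon)
}

#' Inhibition-of-return field
#'
#' The inhibition memory `I(x, t)` in \[0, 1\] relaxes toward a Gaussian
#' bump `g(x - a) = exp(-||x - a||^2 / (2 sigma^2))` centered on the
#' current focus at rate `beta`:
#' `dI/dt + beta I = beta g(x - a(t))`.
#' Applied to the masses as `mu_eff = mu (1 - I)`, it discounts
#' already-visited locations so the trajectory explores the whole scene.
#'
#' @param size frame size `(H, W)` in pixels.
#' @param beta relaxation rate per model-time unit, in (0, 1); `beta = 0`
#'   is accepted and freezes the field (inhibition off).
#' @param sigma_ior Gaussian width of the inhibition bump, in pixels
#'   (default: 2 degrees at 12.8 px/degree).
#' @return an object of class `inhibition_field` with a zero field.
#' @export
inhibition_field <- function(size, beta = 0.1, sigma_ior = 25.6) {
  size <- as.integer(size)
  stopifnot(length(size) == 2L, all(size >= 1L))
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0 || beta >= 1) {
    stop("`beta` must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(sigma_ior) || length(sigma_ior) != 1L || sigma_ior <= 0) {
    stop("`sigma_ior` must be positive", call. = FALSE)
  }
  structure(
    list(I = matrix(0, size[1L], size[2L]), beta = beta,
         sigma_ior = sigma_ior),
    class = "inhibition_field"
  )
}

#' @export
print.inhibition_field <- function(x, ...) {
  cat(sprintf(
    "<inhibition_field> %d x %d px, beta = %g, sigma = %g px, max I = %.3f\n",
    nrow(x$I), ncol(x$I), x$beta, x$sigma_ior, max(x$I)))
  invisible(x)
}

# Gaussian inhibition bump g(x - a) on the full grid, peak value 1 (not
# renormalized, so 1 - I can never go negative).
.ior_bump <- function(size, focus, sigma) {
  xs <- seq_len(size[2L]) - 1
  ys <- seq_len(size[1L]) - 1
  gx <- exp(-(xs - focus[1L])^2 / (2 * sigma^2))
  gy <- exp(-(ys - focus[2L])^2 / (2 * sigma^2))
  outer(gy, gx)
}

#' Advance the inhibition field over a time step
#'
#' Uses the exact exponential solution of the linear relaxation under a
#' focus frozen over the step:
#' `I <- g + (I - g) exp(-beta dt)` with `g = g(x - focus)`.
#' Unconditionally stable and exact in the stationary case; preserves
#' \[0, 1\].
#'
#' @param field an [inhibition_field()].
#' @param focus the current focus `(x, y)` in pixels.
#' @param dt time step in model-time units, positive.
#' @return the advanced `inhibition_field`.
#' @export
ior_step <- function(field, focus, dt) {
  stopifnot(inherits(field, "inhibition_field"),
            length(focus) == 2L, is.numeric(dt), dt > 0)
  if (field$beta == 0) {
    return(field)
  }
  g <- .ior_bump(dim(field$I), focus, field$sigma_ior)
  field$I <- g + (field$I - g) * exp(-field$beta * dt)
  field
}

#' Mass distribution discounted by inhibition of return
#'
#' Applies the inhibition field to every feature mass:
#' `mu_i_eff = mu_i - mu_i I = mu_i (1 - I)`, pointwise. Since
#' `0 <= I <= 1`, the effective mass is never negative and never exceeds
#' the original.
#'
#' @param mass a `mass_distribution`.
#' @param field an [inhibition_field()] on the same grid.
#' @return the discounted `mass_distribution`.
#' @export
effective_mass <- function(mass, field) {
  stopifnot(inherits(mass, "mass_distribution"),
            inherits(field, "inhibition_field"))
  if (!identical(dim(field$I), c(mass$height_px, mass$width_px))) {
    stop("inhibition field and mass distribution shapes differ",
         call. = FALSE)
  }
  keep <- 1 - field$I
  mu_i <- lapply(mass$mu_i, function(m) m * keep)
  .mass_distribution(mass$mu * keep, mu_i, mass$alphas,
                     mass$pixels_per_degree)
}
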