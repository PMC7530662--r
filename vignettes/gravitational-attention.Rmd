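---
title: "A gravitational model of visual attention scanpaths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gravitational model of visual attention scanpaths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gravatt)
```

## The model

Free viewing of a static image produces a *scanpath*: an ordered sequence
of fixations separated by rapid saccades. Classical computational accounts
reduce the image to a saliency map and generate the sequence with a
winner-take-all (WTA) selector — repeatedly attend the global maximum,
then suppress it locally. That scheme is discrete and has no intrinsic
temporal dynamics.

`gravatt` implements an alternative with continuous dynamics. Low-level
feature activations act as *masses* that attract a unitary
focus-of-attention mass through an inverse-square field. On the retina
domain, with `a(t)` the focus position and `mu(x, t)` the mass density,

* field: `E(a) = -(1/2*pi) * integral dx (a - x) / ||a - x||^2 * mu(x)`,
  i.e. the convolution of `mu` with the kernel
  `e(z) = z / (2*pi*||z||^2)`;
* motion: `a'' + lambda a' - E(a) = 0`, a damped Newtonian law. The
  damping `lambda > 0` suppresses the orbital oscillations natural to
  gravitational systems and yields ballistic, saccade-like movements onto
  targets;
* inhibition of return (IOR): a memory field `I(x, t)` in `[0, 1]`
  relaxing toward a Gaussian bump at the current focus,
  `dI/dt + beta I = beta g(x - a(t))` with
  `g(u) = exp(-||u||^2 / (2 sigma^2))`, discounts the masses as
  `mu_eff = mu (1 - I)` so the focus does not remain trapped and the
  scene gets explored.

The masses come from `N = 8` pre-attentive features: the spatial gradient
of intensity, of the three colour channels, and of four orientation-energy
maps (0/45/90/135 degrees, an even-symmetric Gabor bank). Each feature
contributes `mu_i = alpha_i ||f_i||` (pointwise Euclidean norm of the
gradient 2-vector); all `alpha_i` are equal by default. A precomputed
saliency map can be substituted for the basic features
(`saliency_as_mass()`), in which case the map itself is the single mass
component.

## Discretization and numerical choices

* **Field evaluation.** `field_at()` is the direct sum over all pixel
  centers, which *is* the discrete definition; the kernel is regularized
  as `z / (2*pi*(||z||^2 + epsilon))` with `epsilon = 0.25` px² so the sum
  stays bounded when the focus coincides with a pixel center. A
  brute-force double-loop oracle pins the implementation in the tests.
* **Integration.** A fixed-step operator-split loop: per step the
  effective mass is frozen, `(a, v)` advances by one classical RK4 step,
  and `I` advances by the *exact* exponential solution of its linear
  relaxation (unconditionally stable, exact for a frozen focus). A
  compiled stepper and a pure-R reference loop implement the same
  arithmetic and are tested for agreement; trajectories are bit-for-bit
  reproducible given the parameters.
* **Time units.** The solver works in model-time units; `time_scale`
  units elapse per second of viewing (default 10), and `dt` (default
  0.01) is the step. These two and the mass gains set the only genuinely
  free temporal calibration of the model, since the mapping between model
  time and viewing seconds is not identified by the equations themselves.
* **Boundaries.** The focus is clamped to the frame and its outward
  velocity component zeroed at the walls, preventing escape when masses
  hug a border.
* **Initial state.** Frame center with zero velocity by default — the
  conventional first-fixation assumption in free viewing; a seeded random
  start is available.
* **Energy instrument.** `mechanical_energy()` uses the log-potential
  `U(a) = (1/4*pi) * sum mu(x) log(||a - x||^2 + eps)`, whose negative
  gradient is exactly the regularized field. With static mass and IOR off
  it is non-increasing under damping and conserved (to integrator
  tolerance, measured at ~1e-15 per 1e4 steps on a circular orbit) for
  `lambda = 0`.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lam` | damping (per model-time unit) | 1 | grid-search tunable; see below |
| `beta` | IOR relaxation rate | 0.1 | insensitive in a broad range |
| `sigma_ior` | IOR bump width (px) | 2 degrees | via `pixels_per_degree` |
| `alphas` | per-feature mass gains | all 1 | equal weighting |
| `epsilon` | kernel regularizer (px²) | 0.25 | guards the singularity |
| `dt`, `time_scale` | step, units per second | 0.01, 10 | temporal calibration |
| `duration` | viewing time (s) | 3 | 3–5 s typical exposures |
| `pixels_per_degree` | viewing geometry | 12.8 | 224 px ≈ 17.5 degrees |

The working resolution is 224×224 (`resize_frame()`), and every angular
quantity — the IOR width, the WTA inhibition radius (2 degrees), the
1-degree bump used to accumulate fixation saliency maps for tuning — is
converted through the single `pixels_per_degree` scale. The default
treats a 224-px frame as about 17.5 degrees of visual field, a typical
desktop eye-tracking geometry; no published value pins this, so it is
exposed in the configuration.

## The baseline and the metrics

`wta_scanpath()` implements the classical selector: the first fixation is
the master-map maximum (equal-weight linear combination of the feature
magnitude maps, or a supplied saliency map), after which the chosen
location is inhibited within 2 degrees and the next maximum is taken.
Ties break in row-major order so tests are exact. Locations with no
positive saliency are never attended: when nothing positive remains, the
scanpath truncates with a warning (a relative floor of 1e-9 of the
initial maximum guards against numerical dust from FFT filtering). The
original proposal's qualitative proximity/similarity preference rules are
deliberately not implemented — only the quantified selector is.

Simulated trajectories are discretized by the same kind of detector used
on human recordings: a velocity-threshold (I-VT) pass with central-
difference speeds, a 50 px/s threshold and an 80 ms minimum duration.
Thresholds are configuration; the detector identity is the point, not the
specific values.

Three scanpath comparisons are provided. SED quantizes fixations onto an
`m x m` grid of labeled cells (`grid_m = 5`) and takes the unit-cost
Levenshtein distance of the label strings — unnormalized, so values grow
with sequence length. TDE slides a window of `embed_k = 3` consecutive
fixations along the human scanpath and, for each, finds the closest
equal-length window of the simulated scanpath in concatenated-coordinate
Euclidean distance (divided by `embed_k`, so values are a per-fixation
average and comparable across window lengths); the mean of these minima
is the distance. STDE is TDE on coordinates normalized by the frame size,
mapped through `exp(-d)` to a similarity in `(0, 1]` — the standard
distance-to-similarity transform, chosen because the metric is reported
as a higher-is-better score bounded by 1. NSS z-scores a saliency map
over pixels and averages it at fixation locations; it backs the tuning
protocol: a grid search over parameter lattices maximizing the mean NSS
of Gaussian-accumulated simulated fixation maps against held-out
observers (`grid_search_tune()`), the same procedure used to select the
damping in the original study, which reports no numeric value for it.

## What the synthetic data emulate — and what they do not

All tests and the shipped benchmark run on synthetic stimuli and
observers (`make_blob_stimulus()`, `make_texture_scene()`,
`make_synthetic_observers()`), so every number is reproducible from a
seed without downloads.

Two stimulus families matter. *Gaussian blobs and uniform squares*
produce gradient mass concentrated on their contours — hollow rings. By
the two-dimensional shell property of the log-potential, the field inside
a symmetric ring nearly vanishes, so a lone blob captures the focus at
its center of mass (the package verifies convergence to within 2 px),
but in multi-object scenes the ring interior offers no restoring force
against the pull of the other objects. *Textured patches* carry mass
across their area and therefore hold a genuine interior minimum at their
centroid. This mirrors the qualitative contrast between a uniform square
and a noise patch: the noise region, with its large total gradient mass,
is the stronger attractor, and the model fixates such regions near their
centers of mass while the WTA baseline lands on high-gradient borders.

The synthetic observers visit known attractor locations (patch centers)
in a nearest-neighbor tour from the frame center, with isotropic Gaussian
jitter and lognormal fixation durations. The tour encodes the
short-saccade preference of human scanning; the gravitational dynamics
share that preference intrinsically (attraction decays with distance),
whereas the implemented WTA selector ranks purely by magnitude. This is
deliberately the *simplest* process under which centroid-seeking,
proximity-aware scanning should outscore magnitude-ranked edge selection.
The generator is not a model of human eye-movement statistics: there is
no saccadic main sequence, no center-bias field, no fixation-duration
dependence on content. Passing the benchmark therefore shows that the
implementation realizes the model's claimed qualitative advantages under
controlled conditions — not that it matches human data at large, which
requires real eye-tracking corpora.

## Desk-scale calibration

Sparse synthetic scenes carry one to two orders of magnitude less total
feature mass than a natural photograph at the same resolution, which
rescales the force/damping balance of the dynamics. The benchmark
therefore fixes a calibration selected once with the package's own NSS
tuning protocol on held-out synthetic scenes: equal gains
`alpha_i = 60`, damping `lambda = 2`, `time_scale = 16`, `dt = 0.02`,
IOR width 2 degrees (`benchmark_params()`). Two regimes of the damping
are scientifically meaningful and both are exercised: near-critical
damping (`lambda ~ 1-4`) for precise capture of individual objects, and
weak damping (`lambda ~ 0.03`, used in the three-blob exploration test)
where ballistic sweeps of hollow-ring attractors cover the whole scene
within a 5-second exposure. The parameter-recovery test runs at equal
gains of 10, where the lattice `{0.3, 1, 3}` produces visibly distinct
fixation maps; at much higher gain the overdamped lattice points become
NSS-degenerate because they differ only in timing, which NSS cannot see.

Problem sizes used throughout (chosen once for the synthetic study
conditions): 64–96 px frames, 20 benchmark scenes × 10 observers × 5
seeds, 20-seed exploration runs, tuning over 2 held-out scenes × 5
observers.

## Known limitations

* Static images only; the per-step loop would accept time-varying masses,
  but no video path is implemented.
* One shared inhibition field discounts all features; no per-feature
  schedules.
* The hollow-ring physics above means fixations on *uniform* objects in
  cluttered scenes sit on the object's inner contour rather than its
  exact centroid; textured regions do not have this limitation.
* Absolute metric values on real corpora depend on unpublished metric
  hyper-parameters (`grid_m`, `embed_k`, the STDE transform); the
  defaults here are sensible but cannot be guaranteed to reproduce
  published absolute numbers, only the model ordering.

## A worked run

```{r, eval = FALSE}
scene <- make_texture_scene(seed = 1)
obs <- benchmark_observers(scene$centers, dim(scene$frame), seed = 1)
grav <- benchmark_grav_scanpath(scene$frame, benchmark_params())
wta <- benchmark_wta_scanpath(scene$frame)
evaluate_image(grav, obs)  # sed / tde / stde vs the observers
evaluate_image(wta, obs)

res <- run_benchmark(n_images = 20, n_subjects = 10, seed = 1)
summarize_benchmark(res)
```
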