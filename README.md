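# gravatt — gravitational simulation of visual attention scanpaths

`gravatt` simulates where and in what order visual attention moves over a
static image, for researchers who model eye movements: computational
neuroscientists comparing scanpath generators, and vision/eye-tracking
practitioners who need a continuous-dynamics alternative to
winner-take-all (WTA) selection.

## The model

Pre-attentive features of the image — the spatial gradients of intensity,
of the three colour channels, and of four orientation-energy maps
(0°/45°/90°/135°, Gabor bank) — act as masses,

    mu_i(x) = alpha_i * ||f_i(x)||,       mu = sum_i mu_i,

that attract a unitary focus-of-attention mass `a(t)` through an
inverse-square field,

    E(a) = -(1/2π) ∫ dx (a - x) / ||a - x||² · mu(x),

under damped Newtonian motion

    ä + λ ȧ - E(a) = 0.

An inhibition-of-return field `I(x, t) ∈ [0, 1]`,

    ∂I/∂t + β I = β exp(-||x - a(t)||² / 2σ²),      mu_eff = mu (1 - I),

discounts already-visited locations so the trajectory explores the scene.
The continuous trajectory is discretized into fixations by a
velocity-threshold detector (I-VT), the same kind of algorithm applied to
human recordings. A classical WTA baseline (argmax selection with
2°-radius inhibition on an equal-weight master map) and scanpath metrics
— string-edit distance (SED), time-delay embeddings (TDE), scaled
time-delay embeddings (STDE), and the NSS saliency score used for
grid-search parameter tuning — complete the pipeline. A synthetic
stimulus/observer generator makes every result reproducible from a seed.

## A worked example

```r
library(gravatt)

scene <- make_texture_scene(seed = 1)        # 96x96, two textured patches
obs   <- benchmark_observers(scene$centers, dim(scene$frame), seed = 1)

grav <- benchmark_grav_scanpath(scene$frame, benchmark_params())
wta  <- benchmark_wta_scanpath(scene$frame)

evaluate_image(grav, obs)
#>       sed       tde      stde
#> 3.0000000 2.3156181 0.9761765
evaluate_image(wta, obs)
#>       sed       tde      stde
#> 4.1000000 16.9575012 0.8380931
```

The gravitational scanpath needs about 3 string edits to match a typical
observer (lower is better), its fixation windows sit ~2 px from the
observers' (TDE, lower is better), and its STDE similarity is 0.98
(higher is better) — against 4.1 / 17.0 / 0.84 for the WTA baseline,
whose fixations sit on high-gradient borders rather than on the patches'
centers of mass. Over the full shipped benchmark (20 scenes × 10
observers, seed 1):

```r
summarize_benchmark(run_benchmark(n_images = 20, n_subjects = 10, seed = 1))
#>   model metric       mean         sd
#> 1  grav    sed  2.3750000 1.12898417
#> 2  grav    tde  4.4641311 6.75922698
#> 3  grav   stde  0.9566886 0.06141539
#> 4   wta    sed  4.3300000 0.38539112
#> 5   wta    tde 21.8704293 3.97629829
#> 6   wta   stde  0.7969204 0.03256405
```

A command-line wrapper over the same functions lives at
`inst/cli/gravatt.R` (`simulate`, `wta`, `evaluate`, `tune`,
`make-demo`).

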