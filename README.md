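# pestavision

Deep-sea shrimps of the *Sergestes* sensu lato group carry bioluminescent
light organs ("organs of Pesta") whose arrangement — bilobed in
*Parasergestes armatus*, trilobed in *Allosergestes sargassi*, fringed in
*Deosergestes henseni* — is species-specific. Could that variation serve
conspecific recognition? `pestavision` is an R package for the visual
ecology needed to answer that question quantitatively. It is aimed at
researchers in sensory ecology and deep-sea biology who want the full
pipeline — from morphometrics to a recognition decision matrix — as tested,
reusable, tidyverse-style functions.

The package implements four linked analyses:

1. **Allometry** — eye-to-body scaling `E = α·BL^β` fitted on
   log10–log10 data, with sexual-dimorphism ANCOVA (slope test, then
   intercept test, critical α = 0.016).
2. **Sighting distance** — the maximum range at which a bioluminescent
   point source emitting `E` photons/s is detectable by an eye with
   aperture `A`, photoreceptor diameter `d` and integration time `Δt` in
   water with beam attenuation `c`:

   `r = (2/c) · W( (cA/8) · sqrt(E·Δt / T) )`,

   the Lambert-W closed form of the photon budget
   `E·Δt·A²/(16r²)·e^(−cr) = T`, with detection threshold
   `T = T₀·(1 + sqrt(1 + 2.8·d²·N₀·Δt))` (darkness: `N₀ = 0`,
   `T = 4.215` photons). An independent bisection solver cross-checks the
   closed form, and `calibrate_attenuation()` recovers `c` from anchor
   distances.
3. **Spatial resolution** — interommatidial angle `Δϕ = facet/radius`
   (circle fits of eye contours give the radius), minimum resolvable angle
   `α_min = 2·Δϕ`, and the across-species one-way ANOVA + Tukey HSD.
4. **Acuity-limited rendering** — a Gaussian-MTF Fourier low-pass that
   removes spatial information a viewer with a given `α_min` cannot see,
   plus a discriminability index with a self-noise null that turns "can
   they tell the patterns apart?" into a reproducible decision matrix.

Seeded generators (`generate_morphometrics()`, `generate_eye_contour()`,
`generate_pattern()`) produce every input class, so the whole pipeline runs
without any external data.

## Worked example

```r
library(pestavision)

# calibrate the attenuation coefficient on the conservative half-aperture
# published distances, then model the full grid
ref <- published_sighting_distances()
cal <- calibrate_attenuation(ref[ref$aperture_class == "half", ])
cal
#> <attenuation_fit> c = 0.047017 /m, rms residual = 0.0029 m

grid <- build_sighting_grid(env = optical_environment(cal$attenuation_per_m))
glance(grid)
#> # A tibble: 1 × 4
#>   full_aperture_mean_m half_aperture_mean_m minimum_condition_mean_m grand_mean_m
#> 1                 2.40                 1.28                    0.119         1.84

dplyr::filter(tidy(grid), emission_photons_per_s == 1e11,
              aperture_class == "full")
#>   species                aperture_mm distance_m
#> 1 Parasergestes armatus         0.83       6.18
#> 2 Allosergestes sargassi        0.72       5.45
#> 3 Deosergestes henseni          1.05       7.57
```

So even at the brightest plausible emission (`1e11` photons/s) a
conspecific's glow is visible at most ~6–7.6 m away, and on average across
conditions at ~1.8 m: bioluminescence can support approach, not long-range
search. Can it support recognition? The eyes resolve only

```r
min_resolvable_angle(published_eye_geometry()$facet_diameter_mean_um,
                     published_eye_geometry()$radius_of_curvature_mean_mm)
#> [1] 9.931268 7.792226 5.385803   # degrees; P. armatus, A. sargassi, D. henseni
```

— several degrees at best. Filtering each species' organ pattern through
each viewer's acuity at 2 cm and scoring pairwise discriminability against
a self-noise threshold:

```r
rec <- recognition_experiment(distances_cm = 2, seed = 1)
tibble::as_tibble(rec)[, c("viewer", "index", "threshold", "distinguishable")]
#> # A tibble: 9 × 4
#>   viewer                   index threshold distinguishable
#> 1 Parasergestes armatus  0.0123     0.0293 FALSE
#> 2 Parasergestes armatus  0.00880    0.0293 FALSE
#> 3 Parasergestes armatus  0.0107     0.0186 FALSE
#> 4 Allosergestes sargassi 0.0206     0.0638 FALSE
#> 5 Allosergestes sargassi 0.0153     0.0638 FALSE
#> 6 Allosergestes sargassi 0.0157     0.0312 FALSE
#> 7 Deosergestes henseni   0.0457     0.0784 FALSE
#> 8 Deosergestes henseni   0.0395     0.0784 FALSE
#> 9 Deosergestes henseni   0.0264     0.0589 FALSE
```

Every between-species index falls below the within-pattern noise threshold:
even at touching distance the shrimps cannot resolve which arrangement they
are looking at (a 0.01° control viewer separates every pair), although the
filtered organ cluster keeps positive contrast — the glow itself remains
detectable. `autoplot()` methods exist for fits, grids, patterns and the
recognition matrix, and `run_pipeline(pipeline_config(seed = 1))` executes
all four stages end to end into a JSON-serialisable report.

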