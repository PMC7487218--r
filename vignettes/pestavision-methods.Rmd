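---
title: "Models and methods: can deep-sea sergestid shrimps see each other's light-organ patterns?"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pestavision)
```

## The scientific question

Shrimps of the *Sergestes* sensu lato group carry unlensed bioluminescent
organs (organs of Pesta) whose arrangement — bilobed, trilobed or fringed —
is species-specific and prominent enough to key species by. `pestavision`
implements the quantitative pipeline for asking whether that variation could
function in conspecific recognition: it requires (a) that individuals can
detect one another's bioluminescence at behaviourally relevant ranges, and
(b) that their eyes can resolve the arrangement of the organs, not merely
the glow. The package answers (a) with a photon-budget sighting-distance
model and (b) with compound-eye optics plus acuity-limited image rendering,
wrapped by allometric scaling analyses of eye size and seeded generators
for every synthetic input.

## Allometry

Eye diameter scales with body length as a power law,
$E = \alpha\,\mathrm{BL}^{\beta}$, fitted by ordinary least squares on
$\log_{10}$-transformed data; $\beta < 1$ is negative allometry. We use
base-10 logarithms throughout: it is the convention in allometry and the
magnitudes of published intercepts for these species (for example $-0.72$
for a 0.9 mm eye on a 32 mm body) are only consistent with a $\log_{10}$
intercept, not with a multiplicative prefactor. Reported "intercepts" in
this package are therefore always $\log_{10}\alpha$.

Sexual dimorphism is tested by ANCOVA operationalised as nested
linear-model F-tests, the textbook sequence: first the sex-by-covariate
interaction (slope homogeneity), then, only if slopes are homogeneous, the
sex main effect in the common-slope model. The critical level defaults to
0.016, the Bonferroni-corrected threshold for testing three species (we
keep 0.016 exactly rather than 1/60 ≈ 0.0167). Under the null each F-test
is exact, which the test suite verifies by simulation (type-I rate and
p-value uniformity over 2,000 replicates of 25 records per sex).

Preservation state (fresh vs fixed) is carried as metadata but not
modelled: fixation shrinkage plausibly affects eye and body proportionally
and the measured ratios show no separation.

## Sighting distance

A point source emitting $E$ photons s$^{-1}$ viewed through an aperture of
diameter $A$ delivers
$N(r) = \frac{E\,\Delta t\,A^2}{16\,r^2}\,e^{-cr}$
photons per integration time $\Delta t$ at range $r$, where $c$ is the beam
attenuation coefficient of the water at 480 nm. The source is just
detectable when $N(r)$ equals the detection threshold $T$, giving the
closed form
$$ r = \frac{2}{c}\,W\!\left(\frac{cA}{8}\sqrt{\frac{E\,\Delta t}{T}}\right), $$
with $W$ the principal branch of the Lambert W function. The threshold is
$T = T_0\,(1 + \sqrt{1 + 2.8\,d^2 N_0 \Delta t})$ photons, where $d$ is the
photoreceptor diameter (3 µm), $N_0$ the ambient photon rate through a
one-metre aperture, and $T_0$ the base threshold coefficient. All
reproduction runs use darkness ($N_0 = 0$), where $T = 2\,T_0$; the
background term is kept so the model extends to lit water.

Two numeric constants are not printed anywhere usable: the attenuation
coefficient (given only by citation to an external source) and $T_0$ (the
published rendering of the equation is typographically garbled). Both were
fixed **once**, jointly, by requiring the closed form to reproduce the full
published 24-row grid of sighting distances within its printed rounding
(±0.005 m): $c = 0.047$ m$^{-1}$ — a physically sensible value for clear
oceanic water below 200 m — and $T_0 = 2.1075$ (so $T = 4.215$ photons in
darkness). The grid pins both tightly: the darkness threshold is only
consistent within about [4.21, 4.22] photons, and no neighbouring "natural"
constant (e.g. $4\pi/3$, $1.96^2$) stays within rounding. As a
leave-group-out check, calibrating $c$ on the twelve conservative
half-aperture rows alone predicts the twelve full-aperture rows within
rounding. One further convention recovered from the published grid: the
half apertures enter the model rounded to the 0.01 mm measurement precision
(0.42, 0.36, 0.53 mm), not as exact halves — exact halves cannot reproduce
the published values under any $(c, T_0)$.

`calibrate_attenuation()` refits $c$ (only) from any set of anchor rows at
runtime; `sighting_distance_numeric()` solves the pre-Lambert-W photon
budget by bracketing bisection and serves as an independent oracle, agreeing
with the closed form to better than $10^{-6}$ relative error across
randomized parameter sweeps (including $N_0 > 0$). Lambert W itself is
computed by Halley iteration with a branch-point series start and is tested
against its defining identity at $10^{-12}$ and against an independent
library implementation.

Species apertures default to the mean eye diameters 1.05, 0.72 and 0.83 mm
(*D. henseni*, *A. sargassi*, *P. armatus*); emission intensities span
$10^8$–$10^{11}$ photons s$^{-1}$, the range reported for deep-sea fauna.
Internally everything is SI; interfaces take mm/µm with unit-suffixed
argument names.

## Spatial resolution

The interommatidial angle is $\Delta\phi = D_f / R$ (mean facet diameter
over mean radius of curvature) and the minimum resolvable angle is
$\alpha_{\min} = 2\,\Delta\phi$ in degrees. Radii of curvature come from
least-squares circle fits of traced eye contours; we use the algebraic Kåsa
formulation — closed-form, exact on noiseless arcs of any span ≥ 30°, and
adequate at the low noise of traced outlines (the generator-based tests
recover a 0.5 mm radius within 0.01 mm at 0.01 mm contour noise). Species
are compared by classical one-way ANOVA with Tukey HSD (studentized-range
quantiles via `stats`); both the between-group and error degrees of freedom
are reported, since published summaries sometimes quote only the error df
(df = 9 for 3 groups of 4).

Recomputing $\alpha_{\min}$ from the published *rounded* per-species means
gives 9.9°, 7.8° and 5.4° against published 10.8°, 8.5° and 5.9° — an 8–13%
gap with the ordering preserved. The published numbers were computed from
per-individual measurements that were never released, and one-digit rounding
of a 0.3 mm radius alone moves the result by ~10%, so the package's
acceptance check uses a 15% band plus the ordering. The rounding explanation
is the plausible cause but cannot be verified without the raw data, and we
do not assert it.

## Acuity-limited rendering and discriminability

`acuity_filter()` re-implements Fourier-domain acuity rendering as a
radially symmetric Gaussian modulation transfer function,
$\mathrm{MTF}(f) = \exp\!\big(\ln(\varepsilon)\,(f\,\alpha_{\min})^2\big)$,
so the MTF is exactly 1 at DC (mean intensity conserved to $10^{-9}$) and
falls to $\varepsilon$ at the resolution-limit frequency
$1/\alpha_{\min}$ cycles/degree. The fraction $\varepsilon$ is configurable
with default $e^{-3.56} \approx 0.028$, the convention of the published
acuity-rendering package this follows. The implied spatial blur has
$\sigma \approx 0.42\,\alpha_{\min}$, which reproduces the classic two-point
behaviour: sources $0.5\,\alpha_{\min}$ apart merge into one intensity
maximum, sources $3\,\alpha_{\min}$ apart stay separate.

The published analysis judged the filtered images by eye; `pestavision`
replaces that with a quantitative index. `discriminability()` is a
normalised L2 distance between centroid-aligned, total-intensity- and
L2-normalised images, a pseudometric in $[0, 1]$ that is non-increasing as
$\alpha_{\min}$ grows (filtering is contractive on pattern differences).

"Distinguishable" needs a threshold the source study never defined. We
construct it from within-pattern variability: the 95th percentile of the
index between a pattern and geometrically jittered copies of itself
(per-lobe position jitter, SD = 10% of lobe diameter; diameter jitter,
SD = 5%), rendered through the same filter. Two design points matter and
were settled during development:

* **Noise scale.** Positional jitter scales with each lobe's own diameter,
  not with lobe spacing or an absolute length: placement noise plausibly
  grows with the structure being placed, and this keeps the
  jitter-to-feature-size ratio — which is what the pixel-domain index
  responds to — identical across bilobed, trilobed and fringed arrays.
  Pixel-intensity noise is useless here: the low-pass filter annihilates
  it, degenerating the null.
* **Pair-specific thresholds.** A pair (a, b) is tested against
  $\max(q_a, q_b)$ of the two patterns' own null quantiles. A single global
  threshold would let the noisiest pattern decide comparisons it is not
  part of.

With this construction the decision pattern is stable across null seeds
(20/20 seeds at every acuity level tested): at 2 cm the three shrimp
viewers (10.8°, 8.5°, 5.9°) merge every between-species pair while a sharp
control viewer (0.01°, human-like) separates every pair — and the filtered
organ cluster retains positive contrast against the dark carapace, i.e. the
glow is detectable as a unit even when its arrangement is not resolvable.

## The synthetic-data generators

No raw data accompany the source study, so every pipeline input is
generated:

* **Morphometrics** — body lengths uniform on the observed species ranges
  (the simplest range-respecting choice; the study reports only ranges and
  moments), $\log_{10}$ eye diameter linear in $\log_{10}$ body length with
  Gaussian residuals, and additive male coefficient deltas for dimorphism
  scenarios. Published per-sex coefficients serve as generator truth.
* **Eye contours** — evenly spaced points on a circular arc with isotropic
  Gaussian noise.
* **Organ patterns** — rows of filled circular lobes, white on black
  (luminous organ on opaque carapace), parameterised by count, diameter and
  spacing; binary-valued with the physical pixel pitch recorded. The
  species defaults (bilobed 2 × 1.2 mm, trilobed 3 × 0.9 mm, fringed
  8 × 0.3 mm) share a common ~3 mm array extent, following the published
  photographs in which arrays of similar span differ in internal structure;
  only count/size/spacing are contractual, not silhouettes.

What the generators deliberately do **not** emulate: photographic texture,
brightness gradients within organs, body curvature, or emission spectra.
Tests passing on these fixtures therefore demonstrate the behaviour of the
*models* under the study's stated conditions, not image-level fidelity to
real animals.

## Numerical choices and problem sizes

* Lambert W: Halley iteration, branch-point series start below $-0.25$,
  log start above $e$; identity satisfied to $10^{-12}$ relative.
* Bisection oracle: bracket by doubling/halving, `uniroot` tolerance
  $10^{-9}$ m.
* Circle fit: Kåsa linear solve; collinearity rejected via rank test.
* FFT filtering uses periodic boundaries; recognition canvases leave ≥ 70
  px of dark margin so wraparound is negligible at the 1–2 cm distances
  that carry the conclusions.
* Default rendering: 192 px over a 12 mm canvas (0.0625 mm/px), shared by
  all species so filtered images are comparable; recognition nulls use 40
  jitter draws. Monte-Carlo test sizes: 500 replicates (slope recovery,
  n = 200 records), 2,000 replicates (ANCOVA calibration), 1,000
  replicates (ANOVA calibration) — sizes chosen to keep binomial CIs tight
  around the nominal rates.
* Degenerate inputs are rejected with typed conditions
  (`pestavision_input_error`, `pestavision_domain_error`,
  `pestavision_numeric_error`): collinear contours, zero within-group
  variance everywhere (F undefined), constant covariates in the ANCOVA,
  lobes crossing the canvas border, mismatched angular sampling.

## Known limitations

* The detection-threshold coefficient $T_0$ and the default $c$ are
  calibrated to the published grid rather than transcribed from a
  derivation; they reproduce that grid within rounding but are not
  independently traceable.
* Morphological acuity estimates are upper bounds — reflecting
  superposition optics pools light across facets, so true resolution is
  likely worse; this only strengthens the "cannot resolve" conclusion but
  the package does not model the optics beyond the facet/radius
  approximation.
* The discriminability index and its self-noise null are this package's
  constructions (the source analysis was a visual assessment); conclusions
  about *which* pairs are distinguishable inherit those design choices.
* Published per-species $\alpha_{\min}$ values are not exactly recoverable
  from rounded summary statistics (8–13% gap, documented above).
* Extended sources, counterillumination contrast against downwelling light,
  and depth-dependent attenuation are out of scope; the sighting model is a
  point source in darkness, the study's stated best case.
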