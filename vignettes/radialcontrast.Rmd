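---
title: "Radially generalized contrast energy and crowding predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radially generalized contrast energy and crowding predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialcontrast)
```

## The model

Most classical image-contrast statistics (Weber, Michelson, RMS) treat
pixels as independent coordinates. Neurons in the early visual stream do
not: from the retina onward, cells respond through center-surround
receptive fields, classically modeled as the difference of a narrow and a
wide Gaussian, and the size of those fields grows with distance from the
fovea. This package implements a contrast measure built directly on that
anatomy and a minimal mapping from the measure to behavioral accuracy in
crowded-target identification tasks.

**Receptive-field kernel.** At eccentricity $e$ the foreground (center)
mask is a 2-D Gaussian with SD $\sigma_F$ pixels and the background
(surround) mask a Gaussian with SD $\sigma_B = K\sigma_F$, with $K = 5$ by
default, an approximately fixed center-to-surround ratio reported
psychophysically. Their difference
$\varsigma = M_{\sigma_F} - M_{\sigma_B}$ is a zero-DC bandpass filter:
low spatial frequencies are cancelled by the surround, high frequencies
by the center blur, leaving a single radial passband — the familiar shape
of human contrast-sensitivity curves. The anatomical anchor for
$\sigma_F$ is a power-law fit of midget ganglion cell dendritic field
diameter against retinal eccentricity, $y = 8.64\,x^{1.04}$ (µm against
mm), exposed as `dendriticDiameter()`.

**The semi-norm.** For an image $i$ with vectorization $v$, convolution
by $\varsigma$ is a linear map $J$ (a Jacobian in image space), and the
radially generalized contrast energy is the per-pixel Euclidean
semi-norm of the filtered image,

$$C(v) = \sqrt{\tfrac{1}{n}\sum_{x,y} (\varsigma * i)^2_{x,y}}.$$

It is nonnegative, absolutely homogeneous and subadditive (verified on
randomized images in the test suite), and annihilates constant images
because the kernel is mean-subtracted to an exactly zero sum. When the
foreground collapses to a unit impulse and the background to the uniform
distribution over the image, $C$ reduces exactly to classical RMS
contrast (`degenerateContrastEnergy()` against `rmsContrast()`, equal to
1e-12 in the tests). A `sum-square` convention (no $1/n$) is selectable;
all shipped analyses use the per-pixel `mean-square` convention, whose
scale is consistent with the magnitudes of the tabulated target energies.

**Contrast to behavior.** The mapping uses two Gaussians in
contrast-energy space sharing the target-alone mean $\mu_\tau$:

* $G_\tau$, SD $\sigma_\tau$, for the target presented alone. It is
  fixed, not fitted, by the convention that a 10% change in target
  contrast yields a 1% identification rate:
  $\sigma_\tau = 0.1\mu_\tau/\sqrt{-h}$ with $h = 2\ln(0.01)$.
* $G_\phi$, SD $\sigma_\phi = k_\phi \sigma_\tau$, for the target among
  flankers. Its width is set by the sole experiment-derived parameter
  $E_\alpha$, the contrast energy at which flankers first impede
  identification, via $k_\phi = |E_\alpha - \mu_\tau| / (0.1\mu_\tau)$.

Predicted proportion correct is $p = 0.85\,[G_\tau + (1 - G_\phi)]$,
where 0.85 is the empirical performance ceiling observed in the source
experiments. With $k_\phi \ge 1$, $p$ is guaranteed to stay in
$[0, 0.85]$; configurations implying $k_\phi < 1$ are rejected rather
than clipped because they break that bound. The absolute value in
$k_\phi$ reflects that only squared deviations enter the Gaussians, so
$E_\alpha$ may lie above or below $\mu_\tau$.

```{r mapping}
m <- mappingModel(0.016057, 0.032)
m
proportionCorrect(c(0.016057, 0.022, 0.032), m)
```

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `pixelPitch` | mm/px | 0.282 | monitor pitch; with distance fixes px/deg |
| `sigmaF` | px | per condition | center Gaussian SD at the target's eccentricity |
| `K` | — | 5 | surround-to-center SD ratio |
| `truncationFactor` | ×σB | 6 | kernel support radius |
| `delta`, `rate` | — | 0.1, 0.01 | psychometric calibration (10% → 1%) |
| `ceiling` | — | 0.85 | empirical performance ceiling |
| `convention` | — | mean-square | per-pixel vs total energy normalization |

Degree conversion uses the exact `atan`, not the small-angle
approximation; at the tabulated distances the two differ by less than
1e-6 relative, and the tabulated pixels-per-degree values reproduce
within 0.01% either way.

`rfProfile()` has two modes. Reproduction mode takes the tabulated
per-condition sigma verbatim; this is what every shipped experiment
uses. Model mode derives sigma from the dendritic power law through a
retinal magnification of 0.29 mm/deg and sigma = diameter/2; these two
constants are crude, are exposed in the arguments, and are *not*
validated against the tabulated sigmas — the tabulated values cannot be
reproduced from the power law under any single pair of constants across
conditions (the 17.2° anatomical collection window involved in their
derivation is recorded but its exact role is unspecified), which is why
reproduction mode bypasses them. A single kernel, evaluated at the
target center's eccentricity, is used per image; sigma is not varied
across the image.

## Numerical choices

* **Kernel truncation.** The support radius is
  `ceiling(6 * sigmaB)`. At a factor of 4 the truncated surround mass
  (~1e-4) leaks into the spectrum at the same order, while at 6 the
  discrete kernel's DFT matches the closed-form difference of Gaussian
  transforms to ~1e-8, comfortably inside the 1e-6 the spectral tests
  require. After truncation the mean weight is subtracted, making the
  kernel sum exactly zero so constant images map to exactly zero energy.
* **Boundary handling.** Images are padded with their declared
  `backgroundLevel` out to the kernel radius, avoiding spurious edge
  contrast; the background is subtracted before filtering (free, because
  the kernel annihilates constants) for numerical conditioning.
* **Convolution path.** Kernels up to side 64 use a direct spatial sum;
  larger kernels (the high-resolution condition has a ~650 px kernel)
  use FFT convolution on a canvas padded so circular wraparound never
  reaches the retained region. Both paths agree to 1e-8 on test images.
* **Degenerate inputs.** Empty images, non-positive sigmas and
  sub-resolution glyphs (Landolt diameter < 5 px, letters < 3 px) are
  rejected with informative errors; `K = 1` yields the all-zero kernel
  (the two Gaussians cancel), which is permitted and maps every image to
  zero energy.
* **Rasterization ties.** Stimuli are binary ink with no anti-aliasing,
  so pixel-count oracles in the tests are exact; glyphs are fixed
  embedded bitmaps rather than system fonts, making renders bit-identical
  across platforms. Right-angle gap orientations use `cospi`/`sinpi` so
  90° rotations are exact on the grid. Canvases are forced to odd side
  lengths so centering is exact and mirrored specs render as exact
  mirror images.

## The experiment runner and the energy anchor

`runExperiment()` renders every stimulus in a condition's sweep, computes
its contrast energy with the condition's kernel, and maps it through the
psychometric model. Absolute energy depends on free rendering parameters
(glyph shapes, canvas area — under per-pixel normalization, blank canvas
dilutes energy) that the source experiments do not pin down. The runner
therefore anchors the scale once per experiment: the target-alone
stimulus, rendered on the same canvas at the reference (first)
eccentricity, is assigned the tabulated $\mu_\tau$, and all energies are
scaled by that one factor. This keeps flanked energies on the same scale
as the tabulated $E_\alpha$ while preserving raw eccentricity and
flanker-distance dependence. With anchoring, the no-flanker condition
predicts exactly the 0.85 ceiling, the pipeline's sanity limit.

```{r ka, eval = FALSE}
ka <- runExperiment(experimentConfig("KA"))
ka[, c("flank_distance_arcmin", "contrast_energy", "proportion_correct")]
```

## What the generator emulates — and what it does not

Four deterministic stimulus families cover the reproduced experiments:
letters with letter flankers, a Landolt C with four tangential flanking
bars (distances in arcminutes), a vernier with 2–16 flanking lines of
varying height, and a Landolt C with 1–5 concentric C or circle
flankers. Sizes the source papers do not restate are package defaults,
chosen once, as follows, and recorded in `inst/extdata/experiments.yaml`:

* *Bar-flanked Landolt C*: target diameter 6 arcmin with bars of equal
  length, black on gray, chosen so the rendered flanked-to-alone energy
  ratios reproduce the reported curve levels (close-distance value
  slightly above an interior minimum, recovery to an asymptote roughly
  1.8× the target-alone energy by ~3 arcmin). Flank distance is
  edge-to-edge, in arcminutes.
* *Letters*: 0.4° (large) and 0.2° (small) letter heights, gray on
  white, flankers at the four cardinal positions, edge-to-edge spacing.
* *Vernier*: 0.33° segments, ~0.05° offset, flanker pitch 0.25°,
  heights 0.5/1/2× the vernier.
* *Concentric flankers*: 1.25° target; flanker rings carry the target's
  stroke width but their own diameter-proportional gap (the paradigm's
  convention); radial ring spacing swept over 0.35–0.50°, matching the
  source geometry's ~0.36° step. Below ~0.30° target-stroke rings would
  have sub-stroke clearance and fuse into a single annulus, a
  configuration the source stimuli do not contain.

The generator emulates geometry and intensity structure only: binary
ink, exact background levels, no luminance noise, no anti-aliasing, no
glyph-font variability, no temporal dynamics, no jittered flanker
arrangements (the jittered conditions of the vernier study are outside
the scope of a pure contrast account and are deliberately not
generated). Passing tests therefore demonstrate properties of the metric
and mapping under clean rasterized stimuli — not that the metric
predicts human data for photographs, textured stimuli, or the exact
fonts and luminances of the original displays.

## Design choices where the design was open

* **Tabulated-constants inconsistency.** The tabulated $k_\phi$ for the
  two letter conditions (10.8333, 9.9999) match the $k_\phi$ formula
  only if their $E_\alpha$ entries (0.010, 0.025) are exchanged.
  `reproduceTable1()` flags this rather than failing, and
  `exchangePLPS = TRUE` evaluates the exchanged reading; no attempt is
  made to guess which was intended.
* **Normalization of $C$.** Whether the semi-norm divides by pixel count
  is not stated where the semi-norm is introduced; the per-pixel
  convention is the one under which the degenerate case reduces exactly
  to RMS contrast and tabulated target energies have plausible
  magnitudes, so it is the default, with `sum-square` selectable.
* **Reported contrast scale of the bar-flanker condition.** The prose
  values around that experiment's contrast curve are internally
  inconsistent by a factor of ten with the tabulated $\mu_\tau$ (0.220
  at the closest distance against a 0.016 target-alone energy and a
  0.0216 minimum); the package treats the curve as living on the
  tabulated scale (≈0.022 at the closest distance), under which the
  reported ~41% accuracy at 0.06 arcmin follows from the model.
* **Eccentricity of the bar-flanker condition.** The figure caption
  places it at 3°, the summary table at 5°; the configuration follows
  the table, and the value is editable in the YAML.
* **Flank-distance convention.** Bar and letter distances are
  edge-to-edge (an 0.06-arcmin center-to-center distance would put
  flankers inside the target); center-to-center is available via
  `spacingMode` for the letter family.

## Problem sizes

The shipped sweeps are the analysis sizes: 13 flank distances at
1423 px/deg (≈530 px canvases, ≈650 px kernels, FFT path) for the
bar-flanker condition, 8×4 distance-by-eccentricity points for each
letter condition, 15 count-by-height points for the vernier, and 8
spacing-by-gap points per concentric condition. A full run of all six
experiments takes well under a minute on a single core; the complete
test suite, including the 200-image semi-norm property sweep, runs in
about one minute.

## Known limitations

* The anatomical power law is taken as given; nasal/temporal asymmetry
  and inter-individual variability are not modeled.
* One kernel per image: spatially varying sigma across a wide stimulus
  is not attempted (conditions tabulate a single sigma).
* The mapping predicts proportion correct only; it contains no
  representation of letter identity, gap orientation or any other
  feature, so it cannot predict *which* errors are made.
* Absolute (un-anchored) contrast energies depend on canvas area and
  glyph shape; only anchored energies are comparable to the tabulated
  constants.
* No fitting of $E_\alpha$ to new behavioral data is provided, and
  trial-level observer simulation is out of scope.
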