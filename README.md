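# radialcontrast

Visual crowding — the failure to *identify* (not detect) a target when
other objects sit nearby, especially in the periphery — has resisted
simple explanation: adding flankers usually hurts identification, yet
adding even more flankers can paradoxically help. `radialcontrast`
implements, in R, a contrast-based account of these effects for
researchers in visual psychophysics and computational neuroscience: a
**radially generalized contrast-energy semi-norm** derived from
center-surround receptive fields, plus a **single-parameter mapping**
from contrast energy to identification accuracy. Classic crowding
stimulus families are rendered deterministically in code, so entire
experiments are regenerated end-to-end with no external data.

## The model

At eccentricity *e*, pixels are weighted by a difference-of-Gaussians
(DoG) receptive field: a foreground Gaussian of SD σ_F (pixels, set by
midget-cell dendritic field size, power law *y* = 8.64 *x*^1.04 µm at
*x* mm of retinal eccentricity) minus a background Gaussian of SD
σ_B = *K*·σ_F (*K* = 5). The kernel ς = M_{σF} − M_{σB} is a zero-DC
bandpass filter. For an image vectorized as **v**, convolution by ς is a
linear map **J**, and the contrast energy is the per-pixel Euclidean
semi-norm

&nbsp;&nbsp;&nbsp;&nbsp;C(**v**) = sqrt( mean[ (ς∗i)² ] )

— nonnegative, absolutely homogeneous, subadditive; classical RMS
contrast is its degenerate special case (impulse foreground, uniform
background). Behavior is predicted from two Gaussians in contrast-energy
space sharing the target-alone mean μ_τ: σ_τ = 0.1·μ_τ/√(−h) with
h = 2·ln(0.01) (a 10% contrast change ⇒ 1% identification), and
σ_φ = k_φ·σ_τ with k_φ = |E_α − μ_τ|/(0.1·μ_τ), where E_α — the contrast
energy at which flankers first impede identification — is the model's
sole experiment-derived parameter. Predicted proportion correct:

&nbsp;&nbsp;&nbsp;&nbsp;p = 0.85 · [ G_τ(C) + 1 − G_φ(C) ]

## Worked example

The highest-resolution condition: a Landolt C viewed at 23 m, flanked by
four bars at distances of 0.06–3.6 arcmin.

```r
library(radialcontrast)

viewingGeometry(2300, 0.282)
#> ViewingGeometry: 2300 cm distance, 0.282 mm/px (1423.4955 px/deg)

rfProfile(5, sigmaPx = 10.8793)
#> ReceptiveFieldProfile at 5 deg: sigmaF = 10.879 px, K = 5 (sigmaB = 54.397 px)

mappingModel(0.016057, 0.032)
#> MappingModel: muT = 0.016057, sigmaT = 0.0005291, eAlpha = 0.032, kPhi = 9.9290, ceiling = 0.85

ka <- runExperiment(experimentConfig("KA"))
head(ka[, c("flank_distance_arcmin", "contrast_energy", "proportion_correct")], 4)
#>   flank_distance_arcmin contrast_energy proportion_correct
#> 1                  0.06         0.02202             0.4038
#> 2                  0.12         0.02182             0.3841
#> 3                  0.18         0.02151             0.3539
#> 4                  0.24         0.02140             0.3433
tail(ka[, c("flank_distance_arcmin", "contrast_energy", "proportion_correct")], 3)
#>    flank_distance_arcmin contrast_energy proportion_correct
#> 11                   2.4         0.02673             0.7420
#> 12                   3.0         0.02752             0.7715
#> 13                   3.6         0.02789             0.7827
```

Reading the numbers: at the tightest flanker distance the whole image's
contrast energy (0.0220) sits just above the interior minimum (≈0.0214
near 0.24′) — the crowding "sweet spot" — and predicted identification
accuracy bottoms out near 34%; as the bars recede toward 3.6′ the
energy recovers toward an asymptote and accuracy climbs back toward the
0.85 empirical ceiling. The closest-distance prediction (≈40% correct)
matches the reported value for this experiment (~41%).

Other entry points: `reproduceTable1()` recomputes every derived
experiment constant (pixels/degree, σ_τ, k_φ) from primitives and flags
the known internal inconsistency of the two letter-condition rows;
`rmsConfoundReport()` shows which manipulations are confounded even with
plain RMS contrast; `contrastEnergy()`/`rmsContrast()` evaluate the
metric on arbitrary grayscale images (`readStimulus()` reads PNG/TIFF).
A thin CLI over these functions is in `inst/scripts/radial-contrast.R`.

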