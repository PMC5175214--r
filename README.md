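# ptcontrast

Quantitative assessment of contrast-enhanced micro-CT preparations.

Contrast agents (phosphotungstic acid, iodine, Lugol's solution) are soaked
into fixed specimens — classically small insects — to give soft tissue
enough X-ray attenuation to image. Whether the resulting scan can be
segmented *automatically* depends on how well separated the greyvalue
distributions of neighbouring tissues are. `ptcontrast` provides the
statistics to answer that question, plus the segmentation, morphometry and
stain-uptake tools that build on it, and a synthetic phantom generator so
the whole pipeline can be validated without scan data.

## The statistics

**Probabilistic tissue contrast (PTC).** Model the greyvalues of two
tissues as Gaussians N(μ₁, σ₁²) and N(μ₂, σ₂²). The PTC is the overlap of
the two densities,

    PTC = ∫ min(f₁(x), f₂(x)) dx ∈ [0, 1],

evaluated in closed form from the normal CDF at the intersection points of
the densities (the roots of the quadratic obtained by equating them; for
σ₁ = σ₂ the single midpoint (μ₁+μ₂)/2, giving PTC = 2Φ(−|μ₁−μ₂|/2σ)).
It is the sum of the two conditional misclassification probabilities when
voxels are assigned by thresholding at the intersection: a PTC of 10⁻³
means one voxel in a thousand is misassigned — the practical limit for
automatic thresholding. PTC = 1 means the tissues are indistinguishable.

**Simple contrast ratio.** `(mean tissue greyvalue − mean background
greyvalue) / mean background greyvalue` — scale-free, cheap, and suitable
for tracking stain progression day by day.

**Morphometry.** Threshold segmentation inside a region of interest
(26-connected components), volumes as `voxel count × pitch³` with bounds
for a ±0.5 μm voxel-pitch uncertainty, equivalent-area cylinder diameters,
and distance-transform sheet thickness.

**Stain uptake.** The stain diffuses in from an incision; the front
position over staining days gives an uptake rate (mm/day) by least squares,
or an error-function front model (the 1-D Fickian picture) can be fitted to
per-slab stained-fraction profiles.

## Worked example

```r
library(ptcontrast)

# a fly-like phantom: five tissues with Gaussian greyvalues, fully stained
spec <- default_phantom_spec(seed = 1)
ph   <- generate_phantom(spec, day = 16)
pops <- populations_from_mask(ph$volume, ph$mask)

ptc_vs_background(pops$large_muscle, pops$background)
#> <ptc_result> large_muscle vs background: PTC = 2.298e-29 (two_intersection)
#>   intersections at x_A = -0.175484, x_B = 0.163172

contrast_ratio(measure_regions(ph$volume, ph$mask, "large_muscle", seed = 12))$ratio
#> [1] 9.009691

threshold_segment(ph$volume, region_of_interest(z = c(40, 200)), threshold = 0.4)
#> <segmentation_result> threshold 0.4, 4 component(s), 989771 voxel(s)
#>   volume 0.989771 mm^3 [0.848605, 1.14578] at 10 +/- 0.5 um pitch
```

The muscle-vs-background PTC of ~10⁻²⁹ is far below the 10⁻³ guideline, so
thresholding the muscle out of the background is safely automatic; the
contrast ratio of ~9 matches what a well-stained muscle preparation shows;
and the segmented volume reproduces the phantom's 0.99 mm³ muscle, with
bounds showing how a ±0.5 μm pitch error propagates cubically.

A command-line interface wraps the same functions
(`inst/cli/ptcontrast <phantom|ptc|contrast|segment|uptake> --flags`).

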