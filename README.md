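# punctakit

Early endocytic proteins such as the F-BAR-domain protein FCHo2 organize
into sub-micrometric assemblies — bright fluorescent puncta on membranes,
nanometer-tall molecular clusters in AFM topography. Quantifying them
raises the same questions across studies: how many structures are there,
how large are they, how bright, how tall, how fast do proteins accumulate,
and how often do new particles dock onto a growing cluster? punctakit is an
R package for membrane biophysicists and quantitative cell biologists that
answers these questions reproducibly for 2D fluorescence images,
time-lapse stacks, and AFM/HS-AFM height maps and movies.

At its core is a **scale-space spot detector**. The image is filtered with
scale-normalized Laplacian-of-Gaussian kernels at blob radii *r* (with
σ = r/√2),

> ∇²_norm L(x, y; σ) = σ² (∂²/∂x² + ∂²/∂y²) [G_σ ∗ I](x, y),

so that a bright punctum of radius *r* produces a response **minimum** at
its center at the matching scale. Starting points are local minima of the
across-scale minimum projection (plus minima of the smallest scale) above a
noise tolerance; each is linked through the scales to its extremal
response, giving center, radius, and area; finally, two spots are merged
whenever at least 20% of the surface of one disc is covered by the other
(analytic lens area over the smaller disc), transitively closed so the
output contains no mergeable pair. Around the detector sit modules for
intensity normalization and fold changes, line/kymograph profiles with
recruitment-kinetics fitting (I(t) = I∞(1 − e^(−t/τ))), AFM plane leveling
+ cluster segmentation + particle tracking + docking-interval statistics,
Welch/ANOVA–Dunnett testing, and synthetic-data generators with exact
ground truth for every stage.

## Worked example

```r
library(punctakit)

## synthesize a calibrated two-channel image with 12 planted puncta
g <- generatePunctaImage(punctaSpec(nSpots = 12L, seed = 7))

## detect on the protein channel with a quarter-octave scale grid
det <- detectSpots(g$image,
                   detectionParams(scales = geomScales(2, 12, 2^0.25)),
                   channel = "protein")
det
#> SpotSet: 12 spot(s) @ 0.05 um/px
#>   area (um^2): mean 0.08108, median 0.06283

spotIntensityDistribution(det, getPlane(g$image, 1, "protein"),
                          label = "+FCHo2")
#> ConditionSummary '+FCHo2': n = 12, mean = 161.3, sd = 36.49, median = 164.2
```

All 12 planted spots are recovered; the median detected area (0.063 µm²)
sits on the planted population mean (0.067 µm²), and per-spot mean
intensities carry the planted peak distribution. The same flow works on
AFM maps:

```r
afm <- generateHeightMap(afmSpec(seed = 7))       # tilted plane + 3 patches
cl  <- segmentClusters(levelPlane(afm$map))
cl[, c("areaUm2", "heightNm", "maxHeightNm")]
#>   areaUm2 heightNm maxHeightNm
#> 1   0.005  47.0019     49.4202
#> 2   0.005  47.0828     50.1013
#> 3   0.005  46.8830     50.0859

welchTTest(rnorm(20, 47, 3), rnorm(20, 15, 2))    # low vs high setpoint force
#> Welch t-test: statistic = 42.06, df = 36.01, p = 3.27e-32 ****
```

Leveling removes the plane tilt and the planted 47 nm patches of
0.005 µm² are recovered to within a fraction of the 1 nm surface
roughness.

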