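---
title: "punctakit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{punctakit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctakit)
```

punctakit quantifies sub-micrometric protein assemblies ("puncta",
"molecular clusters") on membranes, in two imaging modalities: fluorescence
microscopy (confocal/Airyscan-type 2D images and time-lapse stacks) and
AFM/HS-AFM topography. This vignette explains the models and procedures,
the parameters that matter, what the synthetic-data generators emulate, and
the numerical choices made where the design was genuinely open.

## The scale-space spot detector

Puncta of different sizes are detected with a Laplacian-of-Gaussian (LoG)
scale space. For each blob radius $r$ in a configured list, the image is
filtered with a scale-normalized LoG kernel at $\sigma = r/\sqrt{2}$
(the standard blob-radius convention: a binary disc of radius $R$ gives its
extremal normalized response at $\sigma = R/\sqrt{2}$). The normalization
by $\sigma^2$ makes responses comparable across scales. Two conventions are
fixed deliberately:

* **Sign.** Bright blobs on a dark background give negative responses, so
  blob centers are response *minima*. The detector therefore targets bright
  puncta.
* **Zero-sum kernels.** Each discrete kernel is recentred to sum exactly to
  zero, so a constant image yields an exactly zero response and detection
  is exactly invariant under additive intensity offsets. Both properties
  are asserted in the test suite.

Starting points are strict 8-neighborhood local minima of the pixel-wise
minimum projection across scale planes, united with local minima of the
smallest-scale plane ("minimum projection" is read as the pixel-wise
minimum; no other reading makes its minima well defined). Candidates below
the noise tolerance are discarded.

**Noise tolerance.** The tolerance is a per-series choice in practice, so a
manual value is first-class. The `"auto"` mode estimates the smallest-scale
response noise by the median absolute deviation and multiplies it by $k=5$.
On noise-free images the MAD collapses to zero and the auto mode is
ill-posed (LoG ringing sidelobes, at about 1% of the peak response, become
candidates); noise-free fixtures therefore set a manual tolerance, exactly
as one would on real data with exotic noise structure.

**Cross-scale linking.** Each starting point is walked through the scales
in ascending order; at every scale the walker moves to the response minimum
within the current spot radius of its current position. The spot's final
scale is the one with the most negative visited response (the
extremal-response reading; the alternative "last visited" reading is not
adopted), and its radius is that scale's radius.

**Overlap merging.** Two spots are merged when at least 20% of the surface
of one is covered by the other. The coverage fraction is the analytic
circle-circle lens area divided by the smaller disc's area — i.e. the
larger of the two mutual coverage fractions. Merging is transitively
closed (disjoint-set grouping) and iterated until no pair meets the
criterion, so the output satisfies the post-merge invariant by
construction. A merged group becomes one spot at the response-weighted
center; its area is the *union* of the member discs (the larger-member
alternative is not adopted) and its radius the equivalent-disc radius.
For three or more mutually overlapping discs no closed form exists for the
union, so it is rasterized at 1/8-px resolution; the test suite checks the
two-disc case against the closed form and the general case against an
independent brute-force closure oracle on 1,000 random configurations.

**Scale grid.** The default grid is a geometric series covering 2–20 px at
ratio $\sqrt{2}$, a conventional compromise between coverage and cost.
Because the selected radius is quantized to the grid, area estimates
benefit from a finer grid: the recovery studies use a quarter-octave grid
($2^{1/4}$) over 2–12 px, which brings the population mean-area error on
planted fixtures to a few percent. Radius quantization is at most half a
grid step in log-radius either way.

## Intensity quantification

* **Binding normalization** is the mean gray value of the protein channel
  divided by the mean gray value of the membrane channel in the same frame,
  averaged over frames at or after the steady-state time (default 240 s;
  see kinetics below). It is exactly invariant under rescaling the image.
* **Per-spot intensity** is the mean over the spot's analytic disc
  footprint rasterized at pixel resolution (merged spots use their
  equivalent disc), matching the detector's area convention.
* **Normalized intensity on reference structures** divides each spot's
  mean target intensity by the background mean of the normalization plane,
  where background is every pixel outside all reference footprints. A
  rolling-ball or condition-mean alternative would be a one-line swap in
  `normalizedIntensityOnReference()`; the background convention is the
  simplest reading for sparse structures and is isolated there on purpose.
* **Fold change** is the ratio of condition means (the median ratio is also
  reported). On planted-enrichment fixtures the detection-based pipeline
  underestimates the planted factor by roughly 5–10%: the detected
  equivalent disc is slightly larger than (and sub-pixel offset from) the
  planted footprint, so the footprint mean mixes in unenriched background.
  This dilution is a real property of equivalent-disc quantification, is
  stable across seeds, and is left uncorrected rather than hidden.

Line profiles sample the image at 1-px steps along a polyline with bilinear
interpolation and odd-width perpendicular averaging. Nano-dome radial
profiles average 360 rays (1° spacing) at 0.5-px radial steps through each
dome center; each dome's curve is normalized to its own maximum before
averaging, and mean ± SD over domes is reported with n. Dome classification
(`present` / `excluded` / `rim-enriched`) uses reference-normalized means
on the footprint (top plane) and on a 0.9–1.4 R annulus versus a 0.6 R
central disc (bottom plane): the rim ring straddles the footprint edge, so
contrasting it against the whole footprint would dilute it. The thresholds
(exclusion 0.5, rim 1.3) are declared configuration, not recovered
constants.

## Kymographs and recruitment kinetics

Kymographs assemble the per-frame path profile into a position × time
matrix (bilinear sampling, perpendicular averaging, path length in
physical units). Recruitment curves fit mean ROI intensity with the
saturating first-order model $I(t) = I_\infty (1 - e^{-t/\tau})$ by
Levenberg–Marquardt. Steady state is defined as 95% of the fitted plateau,
i.e. $t_{ss} = \tau \ln 20$; a fixed criterion makes a statement like
"steady state in under 4 minutes" checkable. With the default fixture
$\tau = 60$ s, $t_{ss} \approx 180$ s. Near-constant traces are reported as
already at steady state ($\tau = 0$); a non-convergent fit returns the
curve with the fit flagged absent rather than failing. The dwell-time
threshold separating long-lived from transient puncta (default 60 s) is a
declared configuration value — the class boundary is not a recoverable
physical constant.

## AFM analysis

**Leveling** fits a first-order (planar) background by least squares,
iterated once with the fit mask grown by positive outliers (above 3 robust
SD) so protruding clusters do not bias the plane, then references heights
to the background median. Only planar leveling is offered: higher-order or
line-by-line flattening would distort the planted flat-topped features the
package is meant to recover exactly.

**Segmentation** takes connected components above a height threshold
(default: background + 5 robust SD). The per-cluster height statistic is
the component **median** by default. The mean of the top decile — offered
as `heightStat = "topDecile"` — is attractive for rim-heavy components but
is biased upward by $\approx 1.75 \times$ the roughness SD on flat-topped
clusters under Gaussian roughness (the expectation of the top decile of a
standard normal), which at 1 nm roughness is a 12% error on a 15 nm
cluster. The median is unbiased there and equally robust to rim pixels, so
it is the default.

**Tracking** links per-frame component centroids by greedy nearest-neighbor
assignment within a maximum link distance; unmatched detections open
tracks, unmatched tracks close. The occupancy heat map is the time-summed
count of track positions. A new detection whose neighborhood contains two
or more previous track positions is labelled a coalescence event
(operationalizing ring–ring merging without shape recognition). Docking
intervals are successive differences of track birth times; birth times are
quantized to the frame grid, which cancels in the interval mean except at
the margins. The tracking-based operationalization of docking times is this
package's own and is labelled as such in outputs.

**Particle size** is the equivalent-disc diameter of the connected
half-maximum footprint around a centroid, flagged `unresolvable` below
2 px and `ambiguous` when the footprint swallows another given centroid.

## Statistics

Welch's two-tailed unpaired t-test wraps the standard implementation, with
zero-variance groups handled as a degenerate limit (p = 1 for equal means,
p = 0 otherwise) instead of an error. One-way ANOVA uses the ordinary
linear-model fit; Dunnett's comparisons against the control use the single
pooled variance (the ANOVA mean square error) and adjust p-values over the
joint multivariate-t distribution of the comparison statistics, evaluated
numerically (quasi-Monte-Carlo with absolute tolerance $10^{-8}$) rather
than from hard-coded tables; the test suite cross-checks against an
independent implementation. Significance stars follow the four fixed
levels (*p<0.05, **p<0.01, ***p<0.001, ****p<0.0001). The simulated null
calibration (10,000 replicates) asserts the empirical size of both tests
at $\alpha = 0.05$ within the binomial confidence band, and the two-group
ANOVA is verified to coincide with the pooled-variance t-test.

## What the synthetic generators emulate — and what they do not

Every generator returns machine-readable ground truth, is bit-reproducible
for a fixed spec + seed, and defaults to the magnitudes its analysis stage
is meant to operate on:

* **Puncta images**: smooth radially symmetric bumps (a disc edge smoothed
  by a 0.5 px Gaussian edge) whose planted "radius" is the half-maximum
  disc radius — the same equivalent-disc convention the detector reports.
  The default population mean half-max area is 0.067 µm² at 0.05 µm/px
  (with the mean radius set so that $\pi(\mu^2+\sigma^2)$, not $\pi\mu^2$,
  hits the target). The edge width is kept small because edge smoothing
  adds $\approx 2\sigma_e^2$ to the squared radius the LoG selects; at
  0.5 px this is a few percent on the smallest spots, analogous to PSF
  broadening in real images. Noise is Poisson on photon counts (gain
  parameter) followed by additive Gaussian read noise, both individually
  switch-off-able for exact tests.
* **Recruitment stacks**: the puncta pattern scaled in time so the protein
  channel's mean gray value follows the saturating model exactly, plus the
  noise model per frame.
* **AFM maps**: a tilted plane bearing sharp flat-topped disc patches
  (default 0.005 µm², 47 nm) plus Gaussian roughness (1 nm).
* **Docking movies**: renewal-process arrival times (exponential by
  default — the maximum-entropy choice for a memoryless docking process;
  gamma available to reproduce an empirical interval SD below the mean,
  e.g. 115 ± 94 s, without asserting a mechanism), with particles that
  persist once docked.
* **Nano-dome images**: two channels (reference lipid, protein) with
  uniform, rim-enriched (Gaussian ring at the dome radius, default
  R = 150 nm) or excluded lateral profiles.

They do **not** emulate: realistic optical PSFs beyond the bump edge,
background structure or autofluorescence gradients, stage drift, AFM tip
convolution or scanning artifacts, membrane mechanics, or ring
self-assembly dynamics. Passing recovery tests therefore demonstrates the
correctness of the computations under controlled conditions — not detector
performance on arbitrary real data, where noise tolerance and scale lists
must be chosen per series.

## Study sizes and numerical choices

The recovery studies use 50 images of 5–20 spots for detector
characterization, 3 maps × 3 patches per setpoint condition for AFM,
a 1,200-frame movie targeting on the order of 200 docking events, and
10,000 replicates for test-size calibration; these sizes give the
sampling-error margins quoted in the tests while keeping the full suite in
the minutes range. Ties in merging are broken by a $10^{-9}$ tolerance on
the coverage fraction so the exactly-at-threshold case merges despite
floating-point rounding. Degenerate inputs (empty spot sets, single-frame
stacks, zero-length paths, empty cluster tables, fewer than two events)
return typed empties or raise the documented errors rather than guessing.

## Known limitations

* No sub-pixel localization refinement and no 3-D detection; centers are
  integer-pixel response minima.
* Greedy nearest-neighbor linking has no motion model; crossing particles
  within the link radius can swap identities (planted fixtures avoid
  crossings, and the docking fixtures use stationary particles).
* The equivalent-disc footprint dilutes planted intensity enrichment by
  5–10% (see above).
* `"auto"` noise tolerance requires actual noise; use manual tolerances on
  denoised or synthetic noise-free data.
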