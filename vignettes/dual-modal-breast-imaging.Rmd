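---
title: "Dual-modal photoacoustic and ultrasound breast tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-modal photoacoustic and ultrasound breast tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The imaging problem

A half-ring ultrasound transducer array (512 elements on a 176-degree,
130-mm-radius arc by default) images a pendant breast cross section in
two complementary ways. In photoacoustic computed tomography (PACT) a
laser pulse deposits energy in optical absorbers — overwhelmingly
hemoglobin — and the resulting pressure transients are received by all
reception elements; the reconstructed amplitude maps vasculature. In
reflection-mode ultrasound tomography (URCT), a few elements (30 by
default) fire one at a time with a wide in-plane diffraction cone and
the rest of the array receives the echoes; compounding the per-emitter
images maps anatomy (tumor core, halo, tissue texture). Malignant
masses differ from benign ones both hemodynamically (angiogenesis in
and around the tumor) and anatomically (irregular, elongated,
heterogeneous masses), so a classifier over features from both
modalities can separate them better than either alone.

`duotomo` implements this entire computational chain on simulated
data: phantom generation, both forward models, both reconstructions,
vessel post-processing and morphometry, zone-based feature extraction,
feature selection, a small 1D convolutional classifier producing a
probability of malignancy (POM), and exact binomial confusion
statistics.

## Coordinate conventions

One convention is used everywhere: the array center is the origin,
`+y` points up, elements sit on an arc opening upward with inward
normals, and the imaging grid is a pixel-centered `n_y x n_x` matrix
whose first row is the top of the field of view (120 mm x 50 mm,
centered 5 mm below the array center, by default). Depth used by the
fluence model and all depth-dependent processing is measured below the
per-column skin line, not below the grid top.

## Forward models

Both forward models are linear single-scattering superpositions with a
single speed of sound (1.52 mm/us, warm water) and `1/r` geometric
decay, with distances floored at one pixel pitch to avoid
singularities. The exact decay law is immaterial to the reconstruction
contracts being tested (localization, linearity, time of flight), which
is why a simple monotone choice is preferred over a full-wave model.

* PACT: each absorbing pixel, weighted by the depth-dependent optical
  fluence, emits a derivative-of-Gaussian bipolar pulse whose spectral
  peak sits at the transducer center frequency (3 MHz); arrival time is
  the one-way time of flight.
* URCT: each scatterer inside the emitter's diffraction cone
  (half-angle 48 degrees, the upper end of the 38-48-degree interval)
  returns a Gaussian-windowed tone burst at the two-leg time of flight
  with `1/(r_tx * r_rx)` decay; scatterers outside the cone contribute
  nothing.

The fluence profile is a parametric exponential `exp(-mu_eff z)` with
`mu_eff` fixed by the surface-to-50-mm fluence ratio: 62-fold for
dark-field illumination (the default) and 220-fold for bright-field.
This stands in for full optical transport; it reproduces exactly the
depth-attenuation ratio that matters to depth compensation and to
deep-vessel contrast, and nothing else.

Sampling defaults to 40 MHz (a comfortable margin above the 3-MHz
center frequency for linear delay interpolation); channel noise is
additive white Gaussian, calibrated so peak signal over noise RMS
matches a requested SNR in dB.

## Reconstruction

PACT uses weighted delay-and-sum (DAS): one global speed of sound,
linear interpolation between samples, and an apodization weight over
the detection angle (cosine by default; uniform and cosine-squared are
available). The bipolar variant is the plain weighted sum. The
unipolar variant combines each delayed sample with its time derivative,
`s - kappa * ds/dt` with `kappa = 1/(2 pi f_c)`, which turns the
N-shaped pulse's zero crossing into a positive peak; each element
contribution is half-wave rectified before summation. The
per-contribution rectification is deliberate: rectifying only the
summed image leaves bipolar-scale negative lobes in place, whereas the
per-contribution form drives the negative signal mass of a point-target
image to zero while moving its peak by at most one pixel — the two
properties that define this variant's contract. Delays that fall
outside the recorded window contribute zero and are counted in a
truncation warning rather than silently clipped.

URCT reconstruction forms, per emitter frame, the analytic signal of
every gated receiver channel (FFT Hilbert transform, checked in the
tests against the closed form on pure tones), sums it complexly
per pixel at the two-leg delay, and takes the envelope; frames are
combined by incoherent compounding, implemented as the arithmetic mean
of envelopes after sorting frames by emitter index so the result is
exactly independent of input order. "Axis direction less than 90
degrees" is interpreted as a positive inner product between the
receiver's and emitter's inward normals — elements on a ring have
well-defined axes through the center. Display conditioning is
logarithmic compression to a 50-dB dynamic range followed by CLAHE;
the CLAHE clip limit uses `EBImage::clahe`'s parameterization (default
`limit = 2`, 8 x 8 tiles), recorded in the image provenance.

Display-rate grids use 0.25-mm pixels (480 x 200); refined offline
grids use 0.1 mm. Outside the well-resolved field of view (an 82 x
63-mm ellipse), spatial undersampling artifacts are replaced by a
Gaussian-smoothed interpolation; pixels inside the ellipse are
preserved bit for bit.

## Vessel post-processing

The angiogram chain is: skin-line detection (per-column first
threshold crossing, median filtered, jumps clamped to 5 px); adaptive
depth compensation (per-depth gain from the bright-structure amplitude
of sliding 2-mm bands relative to the first populated band, clipped to
`[1, 20]`, made nondecreasing by isotonic regression — the cap of 20
accommodates the 62-fold dark-field attenuation over 50 mm, of which
roughly 12-fold accrues by 40 mm); multiscale Frangi vesselness for
2-7-px diameters (scales from a quarter of the smallest to half of the
largest diameter), blended onto the normalized image with weight 0.1.

Skeletonization follows the fixed order: Gaussian smoothing (sigma 1
px), Frangi, hysteresis thresholding (high threshold at the 0.7
quantile of positive vesselness, low at 0.4 of the high), small-object
removal, small-hole filling, Zhang-Suen thinning, branch-point
elimination, spur clearing, and removal of components under 5 px. Two
numerical details matter in practice and are part of the design:
vesselness decays at vessel tips (a tube end looks blob-like to a
ridge filter) and thinning erodes free ends by about half the vessel
width, so the segmentation is first extended by morphological
reconstruction into connected pixels above half the in-mask intensity,
and each skeleton endpoint is then marched back out along its chain
direction through the segmentation (never creating a branch). With
both corrections a straight synthetic tube's skeleton length is within
5% of its true centerline. Connected-component labeling of skeletons
is 8-connected (its complement, used for hole filling, 4-connected);
a 4-connected labeling silently fragments diagonal 1-px chains.

Volumes are assembled by translation-only rigid registration of each
slice to its registered predecessor (subpixel cross-correlation peak
with quadratic refinement) — the motion being corrected is bulk
drift/heartbeat, which has no in-plane rotation component to speak of
— followed by linear interpolation along the scan direction to voxels
matching the in-plane pitch. Depth-encoded projections take the
maximum amplitude through a depth slab and color each projected voxel
by its shortest 3D Euclidean distance to the skin surface, with one
fixed color map for all outputs.

## Zones and features

On the ultrasound image, the tumor zone is the given hypoechoic mass
segmentation; the boundary zone is a 3-mm dilation band (the
echogenic halo; the width is a package default, chosen as a typical
halo thickness, since no standard value exists); the reference zone
collects breast pixels in the tumor's depth-below-skin band more than
5 mm beyond the boundary's outer edge. Eleven features are frozen in
code:

| feature | definition |
|---|---|
| `v_count_tumor`, `v_count_boundary` | skeleton segments intersecting the zone |
| `v_density_tumor`, `v_density_boundary` | skeleton px / zone px |
| `amp_mean_tumor_rel`, `amp_p90_tumor_rel` | mean / 90th-percentile unipolar PA amplitude in the tumor relative to the same statistic in the reference zone |
| `amp_hetero_sd_tumor`, `amp_hetero_sd_boundary` | SD of PA amplitude over vessel pixels in the zone |
| `form_factor` | `4 pi A / P^2` of the mass, marching-squares perimeter |
| `axis_ratio` | major/minor axis of the second-moment ellipse |
| `echo_sd_tumor` | SD of conditioned US amplitude inside the tumor |

The amplitude features are reference-normalized (and therefore
invariant to global rescaling of the PA image) because the relative
hemoglobin signal at matched depth, not its absolute scale, carries the
diagnostic information; the heterogeneity SDs are deliberately
absolute. The form-factor perimeter uses the 0.5-level
marching-squares contour of the lightly smoothed mask: pixel-count
perimeters overestimate a disk's circumference by roughly a quarter,
which would push a perfect disk's form factor to about 0.6.

Whole-breast morphometry for tumor-free analyses: the angiogenesis
occurrence rate counts nonoverlapping 4 x 4-mm tiles whose vascular
density exceeds 1.5x the whole-breast mean; the vascular distance
metric is each vessel's endpoint chord over its path length (1 =
straight, 0 = closed); features within 6 mm of the skin are excluded
first so superficial vessels do not dominate.

## The synthetic cohort

The phantom generator emulates the contrast structure the diagnosis
relies on, not breast acoustics in full. Each phantom has a curved
skin line with an absorbing, echogenic band; a half-elliptical breast
of speckle-generating scatterers; a background vascular tree of random
smooth thick polylines (apparent diameters 0.2-3 mm); and one tumor.
The two archetypes differ in exactly the directions the features
measure: malignant tumors have three times the tumor- and boundary-zone
vessel rates (9 versus 3 vessels/cm^2), stronger boundary irregularity
(0.22 versus 0.06 radial Fourier amplitude, lowering the form factor),
a higher mean axis ratio (1.9 versus 1.25), more tortuous vessels, and
stronger multiplicative echo texture inside the hypoechoic core (0.65
versus 0.25 log-amplitude SD). These values were fixed once, as
moderate overlaps typical of radiomic cohorts — each feature
separates the arms at roughly one standard deviation, so single
features are weak classifiers and the value of combining them is
visible.

What the generator does not emulate: acoustic heterogeneity (a single
speed of sound end to end, mirroring the single-speed reconstruction),
frequency-dependent attenuation, elevational beam profiles, strong
skin-artifact clutter, and real class overlap in lesion morphology.
Passing recovery tests on this cohort therefore demonstrates that the
pipeline preserves and combines the injected contrasts — not clinical
performance.

## The diagnostic model

Features are standardized to zero mean and unit variance with the
scaler fit on training rows only (population SD, the convention of
standard machine-learning scalers). Selection proceeds in three fixed
steps: two-sided Welch t tests (keep p < 0.01; Welch because equal
variances are not guaranteed), correlation dedup (among pairs with
|r| > 0.85 keep the smaller p, ties broken by name so the result is
order-stable), and per-class Gaussian-KDE overlap (Silverman bandwidth
on the pooled sample, shared 512-point grid; keep overlap < 75%).

The classifier is a 1D CNN over the selected feature vector treated as
a length-k single-channel sequence: four same-padded Conv1D stages
(kernel 3; channels 16, 16, 32, 32) with ReLU, ceil-mode max pooling
after stages two and four, and three dense stages (32 and 16 units
with ReLU and 0.5 dropout, then a sigmoid head giving the POM). It is
implemented directly in R (im2col convolutions, full-batch Adam at
learning rate 1e-3 for 200 epochs, binary cross-entropy), with the
backward pass verified against numerical gradients; training is
bit-deterministic given the seed, which also drives the dropout masks.
Kernel sizes, channel counts and the optimizer are package defaults
kept in one configuration list, not hard-coded.

The operating threshold is the largest POM threshold whose test-set
sensitivity is at least 95%; the package reports its own threshold
with provenance rather than treating any particular printed value as
reproducible, since a threshold is a property of a dataset. Confusion
statistics come with exact two-sided Clopper-Pearson 99% intervals
(beta-quantile form; degenerate tails pinned at 0 and 1). Permutation
importance is the mean test-AUC drop over seeded permutations of one
feature column. Paired specificities can be compared by an exact
McNemar test on discordant pairs — an interpretation choice, recorded
as such.

## Study orchestration and problem sizes

`run_study()` simulates the cohort case by case (each case seeded by a
deterministic function of the study seed and case id, so cases are
independent and individually reproducible), extracts the feature
table, splits at the mass level (stratified, masses treated as
independent observations; patient-level grouping would be a config
option), and runs selection, training and evaluation. The default
study is 80 benign + 80 malignant masses imaged with a 128-element,
8-emitter array on a 0.5-mm grid at 20 MHz sampling — a size chosen so
a complete study runs on a single CPU core in a few minutes while
leaving every stage (both forward models, both reconstructions, the
full post-processing chain) genuinely exercised; the full 512-element,
30-emitter clinical layout at 0.25-0.1-mm pitch is the geometry-module
default and is used in the resolution and localization tests.
`run_modality_ablation()` refits the model on photoacoustic-only and
ultrasound-only feature subsets with the identical split and seed.

## Known limitations

* The forward models are single-scattering and 2D; no speckle
  decorrelation, attenuation or aberration physics.
* The element layout is uniform on the arc; the clinical array's
  nonuniform table is unpublished, so a custom per-element angle table
  is accepted but not shipped.
* The unipolar weighting of the clinical reconstruction chain is not
  public; the implementation here is defined by its contract (peak
  preservation, nonnegativity) rather than by reproducing a specific
  published kernel. The same holds for the adaptive depth-compensation
  formula and the registration algorithm.
* The transducer bandwidth is not publicly stated; the 0.7 fractional
  bandwidth default is a free choice.
* Channel data serialize via RDS containers with the acquisition
  attributes; volumes can be exported through standard imaging writers
  if needed.
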