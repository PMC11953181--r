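---
title: "Methods: automated dural-sac measurement and stenosis classification on CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated dural-sac measurement and stenosis classification on CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The clinical problem

Lumbar central canal stenosis (LCCS) is a narrowing of the central spinal
canal that compresses the dural sac — the cerebrospinal-fluid-filled sheath
around the cauda equina.  The accepted quantitative criterion is the dural
sac cross-sectional area (DSA), measured in a plane perpendicular to the
spinal axis at each intervertebral disc level: DSA below 100 mm2 defines
stenosis, below 75 mm2 severe stenosis.  Radiologists assess each level at
its *narrowest* slice.  duralseg automates this chain on CT: locate the
vertebral column, reformat each disc level perpendicular to a virtual
spinal curve, segment the dural sac with a semi-supervised neural network,
measure the area, and classify.

Because patient CTs cannot ship with a package, every stage is developed
and verified against a synthetic spine-CT phantom whose dural-sac geometry
is known analytically.  The phantom is first-class, tested code: all
acceptance-style experiments in `tests/` and `scripts/acceptance.R` run on
it alone.

## The phantom

`generate_phantom()` builds a stack of elliptic-cylinder vertebral bodies
along a smooth spinal curve (a sinusoid in the lateral and
antero-posterior directions, amplitude `curve_amplitude_mm`, default 6 mm —
a mild degenerative-curve magnitude; 0 gives a perfectly straight spine).
Posterior to the bodies runs an elliptical dural-sac tube with aspect ratio
`ellipse_aspect` (default 0.7, minor/major).  Its cross-sectional area in
the plane perpendicular to the local curve tangent is prescribed
analytically: at each disc centre it equals `level_dsa_mm2` for that level
and tapers as a half-cosine over +-5 mm to an inter-level baseline
(`max(135, max(level_dsa) + 5)` mm2), so the disc-centre slice is the
narrowest of its level *by construction* — this makes the narrowest-slice
rule testable with a known answer.  A ligamentum-flavum band wraps the
posterior half of the sac and a disc-posterior-margin band sits between
disc and sac at disc levels.

Voxels are classified in the curve's local rotation-minimizing frame by a
closest-point projection onto a finely sampled (0.25 mm) version of the
curve, so the tube's perpendicular cross-section is exact up to voxelization
(the area-recovery tests demand agreement within 5% at 0.5-mm pixels and
observe about 2%).

Attenuation uses a fixed pseudo-HU palette (bone +700, disc +60, ligament
+80, dural sac +15, background -30): only the *relative* contrasts matter
for segmentation learning, and no attempt is made at realistic bone
texture, osteophytes, or scanner noise spectra.  `apply_acquisition_mode()`
emulates the two clinical protocols: non-contrast lumbar CT keeps the
native 1-mm slices; contrast abdominal CT adds +40 HU to soft tissue (disc
and ligament, not the sac) and resamples slice thickness to 2 mm by
partial-volume averaging.  Gaussian attenuation noise (default sd 10 HU)
is seeded and reproducible.

Geometry is desk-scale: default grid 128 x 128 x 160 voxels at 0.5 x 0.5 x
1.0 mm, six vertebrae of 18 mm with 6-mm discs.  Real lumbar bodies are
taller (~27 mm); the phantom compresses the column so five disc levels fit
a small volume while sacs of 50-135 mm2 stay well resolved.  The morphology
of stenosis (disc bulge vs ligament hypertrophy) is not modelled
separately; narrowing is a generic canal indentation, which is the only
property the downstream measurement can see anyway.

What passing on phantoms does *not* show: robustness to real anatomy,
pathology variety, metal artefacts, or scanner differences.  The vertebra
localizer in particular (`locate_centroids()`: bone threshold at 300 HU,
3D 26-connected components, centre of mass) is valid on phantoms and makes
no claim on clinical scans, where a dedicated localizer would stand in.

## Spinal curve and curved planar reformation

`fit_spinal_curve()` interpolates the centroids with natural cubic splines
parameterized by chord length, then re-parameterizes by numeric arc length
(trapezoid integration on a fine grid; the tests require 0.1-mm accuracy).
Disc centres are the arc-length midpoints between adjacent centroids.

`reformat_level()` samples 11 planes per level at arc offsets -5..+5 mm
(1-mm interval and thickness).  In-plane orientation uses a
rotation-minimizing frame propagated by the double-reflection method from
an initial frame whose first axis is the projection of world x — this
avoids frame flips between adjacent slices; the choice of initial axis is
otherwise arbitrary.  Intensities are interpolated trilinearly, labels
nearest-neighbour on identical frames.  The reformatted field of view and
pixel size are nowhere prescribed clinically, so they are configurable;
the default is 80 x 80 mm at 0.5 mm.  Pixel (n/2, n/2) (0-based) lies
exactly on the slice centre, which is what makes the straight-spine
reformat an exact identity in the tests.  In-plane samples beyond the
volume get a soft-tissue fill value; a slice *centre* leaving the volume is
an error naming the offending offset.

## The dual-decoder U-Net

The segmentation model is a 2D U-Net with one contracting path and two
expansive paths.  Each encoder stage is conv(3x3)-batchnorm-ReLU twice,
then 2x2 max pooling; channels double per stage from `base_channels`
(default 16) over `depth` (default 4) stages.  Both decoders consume the
same skip connections by concatenation and differ *only* in how they grow
feature maps: decoder A uses 2x2 stride-2 transposed convolutions, decoder
B fixed nearest-neighbour interpolation followed by a 3x3 convolution.  A
1x1 convolution and softmax yield per-pixel class probabilities
(background / dural sac).  Inference uses decoder A; the choice is
arbitrary and configurable, since either decoder is a complete
segmentation network.

There being no deep-learning framework for R in scope, the network is
implemented directly in RcppArmadillo: im2col + SGEMM convolutions,
hand-written backpropagation, and Adam.  Weight init is He-normal from a
seeded generator, so building twice with one config is bit-identical, and
training is reproducible given (seed, config, data).

Channel widths, depth and normalization are not clinically prescribed;
depth 4 with base 16 is small enough to train on one CPU core in minutes
while keeping four pooling stages.  Slices are z-score normalized
per-slice before entering the network.

## Semi-supervised training

Labeled slices contribute the sum over the two decoders of pixel-averaged
cross-entropy (probabilities clamped at 1e-7).  Unlabeled slices contribute
an L2 consistency penalty between the decoders' probability maps — the
"mutual soft pseudo-label" reading: each decoder supervises the other with
its full probability map rather than a hardened argmax.  The reduction is
fixed and documented: squared differences summed over class channels,
averaged over pixels (two fully confident, fully disagreeing maps score
2.0).  The batch objective is `supervised + lambda * consistency` with
constant `lambda = 1` by default; the weight is a free parameter surfaced
in `training_config()`.

Batches mix equal labeled and unlabeled halves (default batch size 8, so
4 + 4) to keep both loss terms active every step; with `lambda = 0` the
unlabeled set is skipped entirely, so training is invariant to its
contents — including through batch-norm statistics.  Optimization is Adam
at learning rate 0.001 for 50 epochs, no decay, no early stopping.
Augmentation applies elastic deformation (alpha = 10 px, sigma = 4 px),
scaling 0.9-1.1 and rotation +-15 degrees to image and mask jointly
(bilinear / nearest), plus Gaussian blur (sigma up to 1 px) and Gaussian
noise (5% of range) to the image only, each with probability 0.5; the
magnitudes are conventional since only the transform families are
prescribed.

### The recovery experiment

`recovery_experiment()` is the package's calibration-free sanity check:
40 labeled and 160 unlabeled slices are drawn from two random phantoms
(both acquisition modes), the network is trained 50 epochs, and mean Dice
is measured on slices of a held-out phantom.  Slices are reformatted on a
48-mm field of view — the smallest frame that contains body, canal and
ligament with margin — at 1.0-mm pixels (48 x 48) in the three-seed test
suite and at 0.75-mm pixels (64 x 64) by default, keeping one full
experiment within a few CPU-minutes.  Several `lambda` values share
phantoms, initialization and data order, isolating the consistency term's
effect.  The tests require mean held-out Dice >= 0.80 and that `lambda = 1`
is within 0.02 of `lambda = 0` averaged over three seeds; observed values
are typically ~0.95 with the consistency arm on par or slightly ahead.

## Measurement, classification, evaluation

DSA is positive-pixel count times pixel area on the 0.5-binarized
probability map; no connected-component filtering is applied by default
(an optional largest-component flag would be easy to add, but the
measurement chain is defined without it).  Levels are classified on the
minimum of their 11 slices.  Both published two-group splits are
implemented (100 mm2 and 75 mm2); the three-tier relative grading is
deliberately out of scope.

Evaluation mirrors the clinical reporting: Dice (two empty masks count as
1.0), ICC(2,1) — two-way random effects, absolute agreement, single
measure, with the Shrout-Fleiss F-based 95% CI — and accuracy /
sensitivity / specificity as percentages with exact Clopper-Pearson
binomial CIs (this method reproduces the worked-example intervals the
tests assert, e.g. 281/391 giving 67.1-76.3).  The ICC form is stated in
every report because "ICC" alone is ambiguous.  The narrowest-slice
comparison scores each level as equal / algorithm-narrower /
reader-narrower with a 1-mm2 tie tolerance; "narrower" is read as "smaller
DSA", the only operational reading available, and is flagged in the
output.  ICC strata are computed at slice level.

## Numerical choices and degenerate inputs

* Probability clamp 1e-7 in cross-entropy; batch-norm epsilon 1e-5,
  momentum 0.1; Adam (0.9, 0.999, 1e-8).
* Mask binarization threshold 0.5.
* Curve fitting rejects non-monotone or duplicated centroids; fewer than
  two bone components is an error, as is an all-background volume.
* `icc()` signals zero between-subject variance explicitly instead of
  returning NaN.
* Zero denominators in confusion metrics yield NA for that metric only.
* All generators and training runs are pure functions of (config, seed);
  the pipeline derives per-stage seeds from one root seed.

## Problem sizes in the shipped experiments

Training experiments in the test-suite and acceptance script run at
48 x 48-pixel slices (1.0 mm), 40 + 160 slices, 50 epochs, three seeds in
the suite and two in the script; the end-to-end pipeline smoke test uses
2 development + 1 test patient with 2 epochs, and the acceptance
pipeline the full 50.  These sizes were chosen so a full verification
pass stays in the tens of minutes on a single CPU core while exercising
every stage at full fidelity; the model itself accepts any input
divisible by 2^depth (the configured default is 160 x 160).

## Known limitations

* Phantoms only: no claim of clinical performance transfers from these
  experiments; the published clinical figures for this kind of pipeline
  (slice-level Dice ~0.85, ICC ~0.8, accuracy ~84%) come from private
  cohorts and are not reproducible here.
* The centroid finder is intensity-threshold based and phantom-grade.
* 2D slice-wise segmentation; no 3D context across the 11 slices.
* Two modalities are emulated by a contrast offset and slice-thickness
  change, not by scanner physics.
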