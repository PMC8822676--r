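---
title: "Autocontouring organs at risk on planning CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autocontouring organs at risk on planning CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Radiotherapy treatment planning requires contouring the organs at risk
(OARs) — brain, brainstem, cochleae, parotid and submandibular glands,
larynx, spinal cord, brachial plexus — on the planning CT.  Done by hand
this takes hours per patient.  `oarseg` implements a complete, inspectable
deep-learning autocontouring pipeline for this task: DICOM CT series in,
DICOM-compliant RT Structure Set out, with one independently trained 2D
U-Net per organ and a quantitative contour-evaluation suite.  A synthetic
head-phantom generator makes every stage testable on a laptop with no
clinical data.

## Data representation and preprocessing

A CT series is read into a `ct_volume`: a `[row, col, slice]` array of
Hounsfield units (recovered from stored pixels via the DICOM rescale slope
and intercept), with pixel spacing, slice positions, orientation cosines and
per-slice SOP instance UIDs.  Slices are sorted by patient z regardless of
file order; series with mixed identifiers, non-uniform slice gaps (beyond
0.01 mm) or non-axial orientation (cosines more than 1e-3 from
(1,0,0)/(0,1,0)) are rejected rather than silently resampled.

Each slice then passes through a fixed chain:

1. **In-plane resampling to 1 × 1 mm** (bilinear for images, nearest
   neighbour for label masks).  The output grid shares the first pixel
   center with the input and has `round(dim × spacing)` pixels.  No
   through-plane resampling: the model is 2D and the native slice thickness
   is preserved.
2. **Center crop to 256 × 256** (offset `floor((dim − 256)/2)`), padding
   undersized fields of view symmetrically with −1000 HU (air).  The crop is
   geometric; no body-centroid recentering.
3. **Window/level normalization**: the interval `[L − W/2, L + W/2]` maps
   linearly onto [0, 1] with clamping.  Two presets ship: the tissue filter
   (W/L 400/40) used by most organs and the bone filter (W/L 2000/400) used
   by the spinal cord and brachial plexus, whose context is mostly bony.

For training, all slices where the organ's label is present are kept; of the
remaining empty slices, enumerated in ascending order, every 20th is added
(anchored at the first empty slice).  This lets the network learn organ-free
anatomy without drowning the positive slices: a head-and-neck study can
exceed 200 slices while a gland appears on ten.

**Validation split.** The last 15% is held out for validation.  "Last 15%"
is ambiguous between slices and patients; `oarseg` splits at *patient*
granularity (`ceil(0.15 n)` patients, stable input order), which is strictly
more conservative — adjacent slices of one patient are nearly identical, and
a slice-level split would leak them across the partition boundary.  The
split is taken after empty-slice subsampling.

## Network, loss and training

Each organ gets its own 2D U-Net (no weight sharing): an encoder–decoder
with skip connections at every level, two 3 × 3 ReLU convolutions per block,
2 × 2 max pooling, 2 × 2 stride-2 transposed-convolution upsampling, dropout
(rate 0.5) after the deepest encoder block and the bottleneck, and a 1 × 1
sigmoid output head.  The exact filter schedule is not fundamental to the
approach, so depth and width are configurable
(`model_params()`); the shipped defaults are depth 4 and 32 base filters,
doubling per level, on 256 × 256 input.

The loss is the sum of a soft Dice term and binary cross-entropy:

$$L = \left(1 - \frac{2\sum Y\hat P + s}{\sum Y + \sum \hat P + s}\right) +
\mathrm{mean}\left(-[Y\log \hat P_c + (1-Y)\log(1-\hat P_c)]\right)$$

with smoothing $s = 10^{-6}$ and $\hat P_c$ clipped to
$[10^{-7}, 1-10^{-7}]$.  Three numerical choices matter and are tested:
the BCE term is averaged over pixels so the two terms share scale; the Dice
term uses raw (unclipped) probabilities so that perfect agreement on an
empty structure scores ≈ 0; and the smoothing appears in numerator and
denominator so the empty–empty case (otherwise 0/0) is defined as
agreement.

Weights are Glorot-uniform; the output bias starts at the logit of the
expected foreground fraction (`fg_prior`, default 1%) rather than zero.
An organ occupies a tiny fraction of a 256 × 256 field, and a network whose
untrained output is 0.5 spends its first epochs driving every logit far
negative — a violent transient that saturates the Dice gradient and can
strand training in an all-background optimum.  Starting at the prior
removes the transient; this initialization is standard practice for
segmentation and detection under extreme class imbalance.

Training uses Adam with an initial learning rate of 5 × 10⁻⁵, reduced by a
factor of 0.25 on a validation-loss plateau (no strict improvement for
`plateau_patience` epochs, default 10) down to a floor of 10⁻⁶, for 200
epochs at batch size 32.  On-the-fly augmentation applies one random affine
transform per sample per epoch — rotation ≤ 10°, translation ≤ 15% per axis,
zoom ≤ 10%, shear ≤ 0.2° (interpreted as degrees), drawn uniformly — identically to image (bilinear) and
label (nearest).  All randomness (initialization, shuffling, augmentation,
dropout) flows from one seed through R's RNG, so a run is reproducible on a
fixed BLAS.

**The engine.** No deep-learning framework exists for R in this package's
dependency footprint, so the forward/backward passes, Adam and the
augmentation warps are implemented in `src/unet.cpp` on top of the BLAS
(single precision, panel-fused im2col + GEMM so the im2col matrix is never
materialized).  The backward pass is verified in the test suite against an
independent pure-R double-precision reference implementation
(`helper-unet-reference.R`), layer by layer, to 10⁻⁶.

## Inference and post-processing

`predict_volume()` runs the preprocessing chain on every slice, infers
independently per slice, and maps the 256 × 256 probability map back to the
native grid (inverse crop, then bilinear inverse resampling; everything
outside the crop window gets probability 0).  The binary contour is then
cleaned by three rules, in order:

1. **Threshold 0.33** (a tie at exactly 0.33 counts positive; the tie
   direction is this package's documented convention).
2. **Largest single volume**: only the largest 26-connected 3D component is
   accepted; discontinuous positives are discarded as outliers.
   26-connectivity is the permissive choice, merging diagonal
   slice-to-slice touches that 2D slice-wise predictions commonly produce.
   Size ties break to the smallest minimum slice index, then row index.
3. **Axial height limit**, for the parotid glands, submandibular glands,
   brainstem and larynx only: organ heights (axial extent × slice thickness,
   in mm) are measured per training patient, and predictions taller than
   mean + k·SD (sample SD, n − 1; k ∈ {1, 2}, default 2 with a per-organ
   override; "one or two" SDs is the operating range, with the per-organ
   assignment left to the clinic) are trimmed by removing positive slices
   farthest from the mask's
   center-of-mass slice, alternating between the far ends with ties toward
   the superior end.  The center-of-mass anchor is chosen over
   "largest-area slice" for noise robustness; either is defensible.

Each stage only shrinks the positive set, and the composition is idempotent
— both are enforced as property tests.

Height statistics are serialized in the per-organ JSON manifest next to the
weights, so inference needs no access to training data.

## Contour evaluation

`evaluate_cohort()` scores predicted against ground-truth masks per
patient × organ × method:

- **DSC** = 2|A∩B|/(|A|+|B|); two empty masks score 1 (agreement on
  absence).
- **MSD**: the symmetric mean of nearest-surface distances, in mm.
- **HD95**: the 95th percentile (linear interpolation between order
  statistics) of the *pooled* directed nearest-distance multisets.
  Conventions differ here — some authors take the maximum of per-direction
  percentiles — and the two can disagree, so the pooled convention is named
  in the documentation and reports.

The surface of a mask is the set of positive voxels with a face-adjacent
(6-connectivity) background or out-of-bounds neighbour, taken as voxel
*centers* scaled by spacing.  Surface metrics are undefined (NA) when
either mask is empty — a failed structure must not fake a good (or
catastrophic) score — and NA records are excluded pairwise from tests, with
counts reported.

Method pairs are compared per organ and metric with a paired two-tailed
Student t test (p < 0.05 significant; all-zero differences give t = 0,
p = 1 by convention).

## DICOM handling

The package contains its own DICOM codec (part-10 files, explicit and
implicit VR little endian, nested sequences) because no R DICOM package is
part of its dependency set.  CT stored pixels are written with slope 1 /
intercept −2048 so integer-rounded HU survive the round trip within 0.5 HU.
RT Structure Sets populate the Referenced Frame of Reference, Structure Set
ROI, ROI Contour and RT ROI Observations sequences, with every contour
referencing the SOP instance UID of its CT slice.

Masks become contours by tracing the 0.5 iso-level of the (zero-padded)
binary slice image — the polygon runs midway between inside and outside
pixel centers, so re-rasterization under the pixel-center rule recovers the
mask essentially exactly (round-trip DSC ≥ 0.99 whenever every nonempty
slice has ≥ 100 pixels; single-pixel structures are exempt).  Contours
become masks by the even-odd pixel-center rule, with boundary-grazing
centers resolved deterministically by the half-open crossing rule.
Interior holes are filled on export (inner/outer polarity is not modeled):
none of the 11 OARs is topologically annular at the fidelity needed.  How
the original clinical ground truth was rasterized is not documented
anywhere; the pixel-center rule is this package's choice.

## The synthetic phantom

`generate_phantom()` paints, in order: air (−1000 HU), an elliptical
soft-tissue head (40 HU), a bony ring (700 HU), and simple organs
(ellipsoids/cylinders), then adds seeded Gaussian noise (SD 10 HU).  The
ground-truth structure set holds the exact pre-noise organ supports.
Defaults emulate the head-and-neck acquisition this pipeline targets —
512 × 512 matrix, 0.977 mm pixels (deliberately not 1.0 mm, so in-plane
resampling is always exercised), 2.5 mm slices — over a 12-slice (30 mm)
axial range around the organs, which keeps desk-scale training tractable.
`make_cohort()` derives per-patient seeds from the cohort seed and jitters
organ centers (±6 mm) and semi-axes (±15%), re-drawing up to 100 times if
an organ escapes the body.

Three default organs cover the pipeline's shape cases: a bright central
cylinder ("stem", 160 HU, 16 mm radius, 15 mm tall — exercising the axial
limit path) and two dark lateral ellipsoid glands (−80 HU, 16 × 13 × 8 mm
semi-axes).  Sizes are at glandular scale (1–2% of the cropped field):
the generator's design goal is that a small network can demonstrably learn
the geometry from a small cohort, validating the plumbing end to end.  What
the phantom deliberately does **not** emulate: realistic anatomy and
texture, CT physics (beam hardening, partial volume), low-contrast
boundaries, metal artifacts.  Passing phantom tests therefore demonstrates
that the pipeline is wired correctly and can learn, not that any particular
clinical accuracy will be reached.

## The desk-scale study

The acceptance test and `scripts/acceptance.R` run the whole pipeline at a
size chosen to finish in minutes on one CPU: a 25-phantom cohort, one organ
("stem"), a reduced network (depth 3, 8 base filters), 30 epochs at batch
size 8, trained on 20 patients (the last 3 of which form the validation
split) and scored on 5 held-out patients; the pass mark is held-out mean
DSC ≥ 0.8.

One parameter is deliberately rescaled with the problem: the learning rate.
The full-scale recipe (5 × 10⁻⁵ over 200 epochs × ~200 patients) amounts to
roughly 10⁵ Adam steps; the desk-scale run has ~500.  At 5 × 10⁻⁵ such a
short run stays in the all-background local optimum that extreme
foreground/background imbalance creates (the Dice term's gradient is tiny
once the sigmoid saturates).  The desk-scale study therefore uses
10⁻³ — scaling the step size with the inverse step budget — while the
package defaults keep the full-scale recipe, and the schedule contract
(×0.25 on plateau, floored at 10⁻⁶ from 5 × 10⁻⁵) is asserted separately on
recorded loss series.

## Known limitations

- 2D slice-wise inference: no through-plane context except the axial-limit
  rule; cranio-caudal boundary slices are the weak point, as in any 2D
  approach.
- Axial-aligned series only; oblique and gantry-tilted geometry is
  rejected, not corrected.
- The RTSTRUCT writer emits filled outer contours only (no holes), and the
  reader rasterizes with a fixed pixel-center rule that may differ from the
  planning system that drew the original contours by a boundary pixel.
- Single-precision training: bitwise reproducibility holds for a fixed
  BLAS/compiler, not across platforms.
- The t test assumes paired differences are approximately normal; with the
  typical n ≈ 19 test cohort this is an approximation, as in the standard
  practice this package follows.
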