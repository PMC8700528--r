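---
title: "Automatic cervical vertebral maturation staging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic cervical vertebral maturation staging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvmstage)
```

## The problem

Orthodontists time growth-modification treatment by skeletal maturity, and
the cervical vertebral maturation (CVM) method reads that maturity off the
lateral cephalogram the patient already has: as an adolescent matures, the
lower borders of the second to fourth cervical vertebrae (C2–C4) develop a
visible concavity and the C3/C4 bodies elongate from trapezoids through
horizontal rectangles and squares to vertical rectangles. The Baccetti
six-stage scheme (CS1–CS6) codifies this; CS3 marks the pubertal growth
spurt, CS6 maturity.

`cvmstage` implements the full automated pipeline around that scheme:
landmark annotations in, millimetre-calibrated morphometrics, a thresholded
staging decision, and an agreement-evaluation suite out — plus a synthetic
generator and a compact convolutional landmark detector so the pipeline can
be trained and exercised end to end without any clinical data.

## Landmarks, calibration and measurements

Fifteen named points drive everything: a calibration pair `R1`/`R2` marking
a segment of known 10 mm physical length, and thirteen anatomic points —
for each lower border its posterior corner (`lp`), anterior corner (`la`)
and deepest concavity point (`m`), and for C3/C4 additionally the upper
corners (`up`, `ua`). Annotations use the LabelMe point-JSON dialect;
pixel coordinates are 0-based with the origin at the top-left and y growing
downward. Calibration is per image (`mm_per_pixel = 10 / |R1R2|`), because
radiographic magnification varies between cephalostats.

Five scalars summarise the morphology:

* `C2Conc`, `C3Conc`, `C4Conc` — the perpendicular distance (mm) from `m`
  to the chord `lp`–`la`, clamped at zero when the border is flat or convex
  (immature vertebrae have *no* concavity, never a negative one);
* `C3BAR`, `C4BAR` — the base-to-anterior-height ratio
  `|lp − la| / |ua − la|`, dimensionless, so calibration cancels.

One geometric subtlety: the sign of the point-to-chord distance must know
which side of the chord is superior. Tying it to the image axes would break
under head rotation, so the superior side is fixed from the annotation
itself — the vertebra's own upper-border landmarks for C3/C4, and for C2
(which has no upper-border landmarks) the side opposite the C3 body
centroid. All five measurements are therefore invariant under rotation and
translation of the whole annotation, which the test suite checks by
property.

Anterior heights below 0.5 px raise an error instead of returning a huge
ratio; coincident chord endpoints are a degenerate-line error.

## The staging decision

Staging counts concave borders (depth at or above a threshold) among
C2/C3/C4:

| concave borders | stage |
|---|---|
| 0 | CS1 |
| 1 | CS2 |
| 2 | CS3 |
| 3 | CS4 / CS5 / CS6 by body shape |

With all three borders concave, the C3/C4 shapes decide: at least one
vertical rectangle gives CS6, else at least one square gives CS5, else CS4
— the most mature shape present wins. Ties at every boundary are inclusive
on the mature side.

Three thresholds parameterise the decision, and none of them is published
numerically by the staging literature this package follows, so they are
explicit configuration with defaults chosen once:

* `concavity_mm = 1.0` — the conventional visibility criterion for a
  lower-border concavity on a cephalogram;
* `square_upper_bar = 1.2` and `vertical_upper_bar = 0.95` — a symmetric
  band around the square shape (BAR near 1), wide enough that ordinary
  annotation noise does not flip a clearly rectangular body.

Two deliberate design choices make the decision total for batch use. First,
staging uses the *number* of concave borders, not their identity: landmark
noise can produce anatomically out-of-order patterns (say, C3 concave while
C2 is flat), and these still receive the count-implied stage but are
flagged `pattern_consistent = FALSE` because concavity normally appears in
superior-to-inferior order. Second, trapezoid and horizontal rectangle are
merged into one `horizontal` class: with only the five measurements above
they are indistinguishable, and the early/late split is carried entirely by
the concavity counts.

## The synthetic generator

The generator exists so that every other module is testable with exact
ground truth. It builds a vertebral column analytically — C3/C4 as
quadrilaterals of base width 10 mm whose height is `width / BAR`, C2 as a
body with a three-point lower border, the concave border drawn as the
unique circular arc through `lp`, `m`, `la` (consistent with `m` being the
deepest point) — places the landmarks at the constructed extremes, and puts
`R1`/`R2` exactly 10 mm apart. Concavity depths and BARs are drawn
uniformly from the stage-consistent region of the *staging module's own
thresholds*, with safety margins (0.15 mm for depths, 0.05 for ratios) so
that a zero-jitter case is never borderline: generator and classifier
cannot drift apart, and with jitter off, measurement recovers the
construction to within 1e-9 mm and staging recovers the stage exactly.

The default frame is 100 × 200 px at 0.25 mm/px, the working scale of the
detector's region-of-interest crop. Rendering fills the body outlines over
a darker background (interiors exactly the foreground constant when blur
and noise are off), stamps bright disks at the calibration markers, then
applies separable Gaussian blur and additive Gaussian noise. Landmark
noise is isotropic Gaussian per anatomic point (displacement magnitudes are
then Rayleigh-distributed — mean `sigma * sqrt(pi/2)` — which the tests use
as a closed-form oracle); `R1`/`R2` are never jittered, so calibration is
exact by construction.

The default dataset composition (242/214/164/108/52/200 cases for
CS1..CS6) mirrors the training split of the clinical study this pipeline
emulates, with its realistic scarcity of CS5 and of the short-lived growth
spurt stage CS3.

What the generator does *not* emulate: soft tissue, neighbouring anatomy,
exposure gradients, occlusion of C2 by the mandible, or inter-patient shape
variation beyond the five measured quantities. Tests passing on synthetic
cases therefore validate the geometry, the decision logic and the learning
machinery — not clinical performance on radiographs.

## The landmark detector

The detector reproduces the reference pipeline's shape — ROI frame in, the
30-vector of 15 (x, y) landmark coordinates out of one fully connected
layer, mean-squared-error objective, Adam with learning rate 1e-4 and
epsilon 1e-8, batch 32 — with a compact backbone: six 3 × 3 convolutions
(channels 8–32, the first four at stride 2) with ReLU, implemented in
matrix algebra via im2col. A large dilated residual backbone would change
the capacity, not the pipeline, and the pipeline is what this package
reproduces; depth, channels and strides are configuration, so a heavier
variant can be plugged in.

Coordinates are normalized to [0, 1] by dividing by `(width − 1)` and
`(height − 1)`; the 30-vector is ordered as (x, y) pairs in the fixed
`landmark_names()` order, and that ordering is part of the checkpoint
contract. No augmentation is applied. Everything — initialization (He
Gaussian), batch order, hence the whole loss history — is deterministic in
the configured seed.

Desk-scale defaults are 30 epochs on a few hundred synthetic frames
(minutes on one CPU core), down from the reference schedule of 200 epochs
on 980 radiographs, which remains selectable. The capacity checks used in
the tests are the standard ones for a regression network: a single training
case is memorized to sub-2-pixel accuracy (at a raised learning rate,
3e-3, since 1e-4 is deliberately conservative), training on a 200-case
corpus cuts the loss well below half its starting value, and an untrained
network stages at chance on balanced cases.

## Evaluation statistics

Staging agreement uses the standard one-vs-rest decomposition per stage:
precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, specificity `TN/(TN+FP)`, F1
as the harmonic mean, overall accuracy as trace over total, unweighted
Cohen's kappa, and the intraclass correlation with stages coded 1–6 as
equally spaced integers. Zero-denominator metrics return `NA` — an explicit
undefined marker — never a silent zero. Display rounding is half-up to two
decimals; full precision is kept internally.

The ICC is computed from the two-way ANOVA mean squares (via `stats::aov`)
and defaults to ICC(2,1), the two-way random-effects absolute-agreement
single-rater form: agreement between an algorithm and a gold standard is an
absolute question, and a systematic one-stage offset should count against
it. ICC(3,1) and ICC(2,k) are selectable.

Landmark placement error is the per-landmark Euclidean displacement in mm
under the reference record's calibration. Its `Total` row follows the
per-landmark convention — unweighted mean of the 13 per-landmark means and
the sample SD (n−1) of those means — which is the convention that
reproduces the published totals of the study this package emulates;
image-weighted pooling is available behind a flag.

One erratum is corrected rather than reproduced: the study's methods print
specificity as `TN/(TP+FN)`, but its own specificity column is only
consistent with the standard `TN/(TN+FP)` (e.g. CS5: 74/88 = 0.84 from the
reconstructed counts), which is what this package computes.

`confusion_from_metrics()` closes the loop on published summaries: given
per-stage gold counts and printed precision/recall it reconstructs the
integer one-vs-rest counts and a full 6 × 6 matrix with those margins
(diagonal and margins exact; the placement of individual off-diagonal
confusions is not unique), so the whole metric suite can be re-run against
a published table.

## Numerical choices and degenerate inputs

* Boundary ties: inclusive on the mature side everywhere (depth equal to
  the threshold is concave; BAR equal to a cut point takes the more mature
  shape).
* Generator sampling margins (0.15 mm / 0.05) guarantee that sub-nanometre
  perturbations never change a synthetic case's stage.
* Degenerate geometry errors rather than silent junk: coincident `R1`/`R2`
  (calibration), coincident chord endpoints, anterior height < 0.5 px.
* LabelMe ingestion warns and continues on unknown labels and non-point
  shapes; duplicate labels are a hard error naming the label.
* ROI cropping is an affine map stored with the crop, so coordinates map
  back to the full frame exactly (the suite checks 1e-6 px); resampling is
  bilinear with edge clamping.
* JSON round trips serialize coordinates at 17 significant digits so
  read-after-write is bit-exact.

## Problem sizes

The shipped test suite and the reproduction script run entirely on
generated data at sizes chosen to exercise every claim at desk scale: 200
zero-jitter cases per stage for the recovery check, 600 cases per jitter
level on the sigma grid 0–1 mm, 13 000 displacement samples for the
Rayleigh check, and a 200-case / 30-epoch detector run plus a 250-step
memorization run. These sizes are the package's own reproducibility
settings; the reference clinical schedule (980 training images, 200
epochs) remains available through configuration.

## Known limitations

* The staging cut points are defensible defaults, not the (unpublished)
  values fitted to Baccetti's original data; on real data they should be
  tuned per acquisition protocol.
* Synthetic realism is deliberately limited (see above); detector
  performance on these frames says nothing quantitative about radiographs.
* CS2's definition here does not require the single concavity to be
  specifically C2's — any one concave border counts, with the atypical
  patterns flagged rather than rejected.
* No probabilistic/soft staging, no bootstrap confidence intervals, no
  DICOM ingestion.
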