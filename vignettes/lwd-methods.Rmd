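---
title: "Quantifying lung water density from proton-density-weighted MRI"
author: "lungwater package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lung water density from proton-density-weighted MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lungwater)
```

## The measurement

In a proton-density-weighted acquisition (ultrashort echo time, flip angle
around 1 degree), voxel intensity is proportional to mobile water content.
Lung water density (LWD) expresses each lung voxel's signal as a percent
water content by anchoring it to a reference tissue of known water density:
hepatic tissue, assumed to be 70% water. Two obstacles stand between the
reconstructed magnitude image and that number:

1. **Surface-coil shading.** Phased-array receive coils impose a smooth
   multiplicative intensity bias \(C(x)\). It is removed by dividing the
   image by a normalization map fitted to the signal of the body.
2. **An absolute reference.** After normalization, intensities are still in
   arbitrary units. A circular region of interest (ROI) placed automatically
   in the liver provides the anchor:
   \[\mathrm{LWD}(x) = 70\% \cdot \frac{S_{\mathrm{norm}}(x)}{\bar S_{\mathrm{liver}}}.\]

The pipeline (`runPipeline()`) chains: lung segmentation, liver-ROI
placement on the raw-geometry masks, body-mask extraction, smoothing-
parameter selection, normalization-map fitting and division, LWD mapping
(ROI mean taken on the normalized image), and global/regional summaries. It
is fully deterministic: there is no randomness anywhere in the pipeline
itself.

All volumes use one axis convention: axis 1 indexes coronal slices anterior
to posterior, axis 2 rows superior to inferior, axis 3 columns subject-right
to subject-left; a voxel's physical position is its center, and voxel
index 1 sits at coordinate 0. NIfTI orientation codes are honored on input
(`readVolume()` reorients to this frame).

## Lung segmentation

Two interchangeable segmentation modes produce the left/right lung masks
that drive everything downstream.

**Classical (default, weight-free).** The body is thresholded at the mean
intensity of the whole volume and reduced to its largest connected
component. Low-intensity cavities fully enclosed by the body are candidate
lungs; connected components of the low-intensity set that touch the volume
border (the background, and an airway open to the superior boundary) are
discarded, as are central narrow tubes (airway remnants). The two largest
remaining cavities are the lungs, with right/left assigned by centroid
column against the volume midline (ties toward the right, which is the
low-column side in our convention). A one-voxel morphological closing
smooths each mask. The explicit airway handling is deliberate: a plain
cavity detector tends to annex the lower airways, which in practice is the
dominant failure mode of automated lung masks.

**Residual U-Net (trainable).** The learned alternative follows the
configuration that won the original architecture sweep: 3 downsampling
stages, 1 bridge, and 4 decoder stages, where each stage is a residual
block of two (batch normalization, 3x3 convolution, leaky ReLU) cycles and
a 1x1 convolution produces the output map with no output nonlinearity.
"4 upsampling layers" is read as 3 2x-upsampling stages (restoring full
resolution after 3 poolings) plus one full-resolution decoder block; no
other reading yields shape-consistent tensors. Because the final layer is
linear, the network emits logits; the logistic map converts them to
probabilities inside the Soft-Jaccard loss
\[L = 1 - \frac{\sum p g + \epsilon}{\sum p + \sum g - \sum p g + \epsilon},
\qquad \epsilon = 1,\]
and thresholding probabilities at 0.5 is equivalent to thresholding logits
at 0. Inputs are 2D slices resampled to a working resolution of 1-1.5 mm
(default 1.25 mm) and z-scored per slice; augmentation applies flips,
small rotations and scalings identically to image and mask (mask resampled
nearest-neighbour), and blur and noise to the image only. "Random
permutations" of the original augmentation recipe is interpreted as axis
flips.

The convolution, pooling and upsampling primitives and the batch-norm hot
path are compiled code (`src/`); the training loop (Adam, per-epoch
validation logging) is R. All gradients are verified against numerical
differentiation in the test suite. The training objective adds a
binary-cross-entropy term (weight 0.5) to the batch-aggregated
Soft-Jaccard: the Jaccard gradient reaches the logits through
\(p(1-p)\) and vanishes once they saturate — a freeze we observe
reproducibly on degenerate minima — while the cross-entropy gradient
\(p-g\) has no such trap. Validation loss and every reported metric remain
pure Soft-Jaccard and Dice.

**Desk-scale training choices.** The faithful batch size default is 64; on
a single CPU we train with batch 16 on ~200 synthetic 96x96 slices, cap
epochs at 20, and stop early once validation Dice reaches 0.98 or stops
improving for 5 epochs (the best-validation weights are kept). These are
compute-budget choices, not method changes; on the easy synthetic geometry
the model passes 0.93 validation Dice within a handful of epochs.

## Automated liver ROI

The reference ROI is a disc of area \(A = 12.5\ \mathrm{cm}^2\) (radius
\(r = \sqrt{A/\pi} \approx 19.95\) mm) placed in the coronal slice nearest
the right lung's 3D centroid, centered in the centroid column, with its
center 8.75 mm below the bottom-most right-lung voxel of that column.
Membership is decided by voxel centers falling inside the disc.

Two geometric facts are worth recording. First, a disc of that size
centered 8.75 mm below the lung bottom necessarily grazes the lung above
its center; lung-labelled voxels are therefore excluded from the member
set, keeping the reference purely hepatic. Second, at 3.5 mm isotropic
resolution the 8.75 mm offset is exactly 2.5 voxels, so the disc center
sits mid-way between voxel centers in the row direction; the lattice-point
count inside the disc is then exactly 104 (the next admissible counts are
100 and 108, since 4 boundary voxels enter or leave together), giving a
discretized area of 12.74 cm^2 against the nominal 12.5 cm^2 — a
quantization of just under two voxel areas that no choice of indexing
convention removes.

## Coil-shading normalization

Per coronal slice, the normalization map \(M\) minimizes
\[\sum_{x \in \mathrm{body}} (M(x) - S(x))^2
  + \lambda^2 \lVert \Delta M \rVert^2\]
over the full slice grid, where \(\Delta\) is the 5-point discrete
Laplacian with Neumann boundaries and the body mask is "intensity above the
volume mean, minus segmented lung, largest component". The fit is solved on
a 4x coarser grid (block-averaged data weighted by body-voxel count — the
exact restriction of the full objective to block-constant maps) and
interpolated back bilinearly; for the smooth maps of interest this changes
the solution by well under the fitting error (verified against the
full-resolution solve in the tests, with the lambda rescaling
\(\lambda_{\mathrm{full}} = 4\lambda_{\mathrm{coarse}}\) implied by the
coarser Laplacian stencil). Slices without body voxels copy the nearest
fitted slice. Before division the map is floored at
\(10^{-3} \times \mathrm{median}(M\ \mathrm{over\ body})\) so near-zero
extrapolations outside the fitted support cannot blow up the quotient. Both
terms of the objective are quadratic in the signal, so the entire pipeline
is invariant to a global intensity rescaling of the input — the liver ratio
removes the remaining scale.

**Choosing the smoothing parameter.** `selectLambdaLcurve()` sweeps a fixed
grid of 30 log-spaced values over six decades (\(10^{-2}\) to \(10^4\);
dimensionless, and scale-invariant for the reason above) and records the
L-curve: log residual norm over body voxels against log Laplacian seminorm.
Finite-difference curvature along the curve is exposed for diagnostics, but
the corner is located by a chord rule on range-normalized axes: the point
of maximum distance from the straight line joining the curve's endpoints.
Raw curvature is numerically treacherous here — where consecutive grid
points nearly coincide the finite-difference curvature is pure noise
amplification — while the chord rule depends only on the curve's
macroscopic geometry. Two regimes occur. When the body signal is a clean
multiplicative field (the homogeneous phantom), the curve has a classic
convex corner at the noise-fitting scale, on the origin side of the chord,
and that corner is selected. When genuine anatomy (the 70% liver against
85% soft tissue) dominates the residual, the origin-side corner all but
vanishes and the curve is globally concave; the selector then takes the
strongest far-side bend, which sits in the heavy-smoothing regime. That is
the regime the anchor needs: the map must smooth *over* the liver's darker
signal, because a map that follows it re-normalizes the liver toward the
soft-tissue level and biases every LWD value downward. The selected corner
is stable across noise realizations (same grid index), consistent with the
view that the smoothing parameter need not be re-optimized per image on a
fixed protocol; a fixed-lambda mode (`lambda = <value>`) is provided for
exactly that use.

On phantoms, the selected lambda recovers the generator's coil field over
body voxels with \(r^2 > 0.99\) (homogeneous body) and reproduces regional
lung water within 1.5 percentage points at 2% noise (heterogeneous body,
default supine gradient); the residual ~1 point underestimate is the
fingerprint of the trend fit absorbing a little of the liver dip and of
interpolating the map across the lung cavity.

## LWD map and regional summaries

\(\mathrm{LWD}(x) = 70 \cdot S_{\mathrm{norm}}(x)/\bar S_{\mathrm{liver}}\)
for lung voxels; non-lung voxels are NA (a sentinel, -1 by default, in
written overlays). No clipping is applied — values above 100% are reported
as computed, since clipping would bias means. A voxel whose normalized
signal equals the ROI mean maps to exactly 70% by construction; this anchor
is asserted in the acceptance tests.

For regional analysis the lung-containing coronal slices, ordered anterior
to posterior, are split into three contiguous segments with equal slice
counts. When the count is not divisible by 3 the extra slice goes to the
mid segment first, then posterior, keeping the anterior/posterior extremes
— the reported contrast — maximally balanced. Per-segment, per-lung and
global means and the segmented lung volume (voxel count times voxel
volume) are reported. `resliceSagittal()` provides the sagittal view of the
isotropic volumes for visual assessment of the anterior-posterior
gradient.

## The digital phantoms

Both generators share the signal model
\(S(x) = C(x)\, \mathrm{WD}(x)/100 \cdot S_0 + \varepsilon\), with
\(\varepsilon \sim N(0, (\sigma S_0)^2)\) clipped at zero as a magnitude-
image surrogate. The noise is Gaussian rather than Rician: at the
signal-to-noise levels simulated the difference is negligible, and the
Gaussian keeps every oracle analytic. The shading surrogate is a constant
offset plus anisotropic Gaussians, dynamic range capped at 3.

**Vial phantom.** Ten vials (water/D2O dilutions, 10-100% in 10% steps,
the 100% vial as reference) in a water-filled container, imaged as
cylinders along the slice axis; analysis mirrors the physical experiment:
disc ROIs shrunk to 80% of the vial radius in a central slice (avoiding
partial-volume edges), relative densities against the reference vial,
ordinary least squares, Bland-Altman, and ICC. The default simulation uses
uniform coil sensitivity, so it isolates noise-driven error; the measured
bias is correspondingly far below the physical experiment's, which bundles
shading and sequence effects.

**Thorax phantom.** An ellipsoidal body (soft tissue 85% — any value
comfortably above lung water works; 85% makes the mean-threshold body mask
behave as in vivo), two ellipsoidal lungs kept two voxels clear of the body
surface, a liver block (70%) whose top face conforms to the right lung's
bottom surface (required by the ROI-placement oracle), and a central
low-density airway tube open to the superior boundary. Lung water varies
along the slice axis as a piecewise-linear profile through the three
regional targets — the minimal profile consistent with reporting only three
regional means; the generator also records the *achieved* regional means of
the realized field, and recovery is always scored against those. Supine
places the higher densities posteriorly; the prone flag reverses the
profile. The default grid is 64 x 96 x 96 at 3.5 mm isotropic (a
desk-scale stand-in for the 72-80 slice acquisitions); the posterior-
weighted default shading emulates a spine array.

What the phantoms deliberately do not model: vasculature, lobar fissures,
cardiac structures, partial-volume blur at tissue boundaries, respiratory
motion, Rician noise, or k-space effects. Passing tests on them therefore
demonstrates the correctness of the pipeline's geometry, algebra and
selection logic under known truth — not segmentation robustness on real
anatomy, which the original study established with a large annotated
corpus that is out of scope here.

**Segmentation training slices** are a separate, intentionally easy 2D
caricature (random body/lung ellipses at 1.25 mm, random shading and
noise, ~15% lung-free slices) generated directly at the network's working
resolution. They exercise the training recipe end to end; a model trained
on them is not expected to segment real thoraces.

## Agreement statistics

The vial analysis reports the OLS fit of measured on known concentration
(slope, intercept, Pearson \(r^2\)), Bland-Altman bias and limits of
agreement, and the intraclass correlation coefficient. The ICC variant is
fixed to two-way mixed effects, absolute agreement, single measures —
ICC(A,1) — the defensible choice for known-versus-measured comparison,
computed from the two-way mean squares
\[(MS_R - MS_E)\ /\ \bigl(MS_R + (k-1) MS_E + k (MS_C - MS_E)/n\bigr)\]
and cross-checked in the tests against a variance-components computation
from `aov()` mean squares. Both pooled-across-repeats and per-repeat ICCs
are reported, since either pooling convention is defensible for a repeated
phantom experiment.

## Numerical choices and degenerate inputs

* Tie-breaks: right/left assignment ties go to the right lung; the ROI
  centroid column falls back to the nearest lung-bearing column (flagged on
  the ROI object) if the rounded centroid column holds no lung voxel in the
  centroid slice.
* Degenerate inputs fail loudly with stage-tagged errors: uniform volumes
  (no cavities), empty body masks after thresholding, non-positive liver
  means, ROIs exceeding the volume bounds, lambda grids shorter than 3,
  fewer than 3 lung-containing slices.
* The Soft-Jaccard epsilon defaults to 1, which also stabilizes training on
  lung-free slices.
* Batch-norm uses momentum 0.1 running statistics; inference uses the
  stored statistics, so prediction is deterministic.
* Problem sizes in the shipped tests: thorax phantoms at 48x72x72 (property
  tests) and 64x96x96 (acceptance), ~200 training slices at 96x96, vial
  phantoms at 16x80x80 — sizes chosen so the full suite, including one
  complete U-Net training run, executes in minutes on one CPU while every
  oracle stays nontrivial.

## Known limitations

* The classical segmentation assumes the body is brighter than the lungs
  and the lungs are enclosed cavities; strong shading that lifts posterior
  lung signal above the volume mean will erode it. The U-Net mode exists
  for exactly that regime (given training data).
* The 70% hepatic anchor inherits its physiological caveats: hepatic fat
  or iron change liver water density and bias every LWD value
  proportionally.
* The L-curve selector assumes the six-decade default grid brackets the
  corner; `lambdaInterior` in the report flags a corner at the grid edge.
* LWD conflates intravascular and extravascular water; the package
  quantifies, it does not interpret.
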