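---
title: "Automated lung segmentation and densitometry for murine micro-CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated lung segmentation and densitometry for murine micro-CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Longitudinal micro-CT of bleomycin-induced pulmonary fibrosis in mice lets a
laboratory follow disease on the whole lung instead of the <1 % of tissue a
histological section samples.  The quantitative readout is densitometry: the
linear relationship between X-ray attenuation and tissue density means the
Hounsfield-unit (HU) histogram of the lung partitions into aeration
compartments, and fibrosis shows up as a shift of volume from the
normo-aerated compartment toward the hypo- and non-aerated ones.  Two
obstacles stand between a raw scan and that readout: bench-top micro-CT
scanners deliver detector grey levels, not HU, and fibrotic lungs are so
dense that intensity-based segmentation fails exactly where the disease is.

`muridens` implements a fully automated pipeline that addresses both:

1. **Coarse localization** — a multi-class model segments joint lungs, heart
   and airways on axial slices down-sampled in-plane by 4 (512² slices become
   128²).
2. **Automatic HU calibration** — the mean grey level of the airway lumen is
   pinned to −1000 HU (air) and the mean grey level of the heart to +50 HU
   (blood), and the unique line through those two points converts the full
   volume: `HU = slope · GL + intercept`.
3. **ROI cropping** — a fixed cuboid (default 384 × 320 × 384 voxels) centred
   on the coarse lung centroid crops the converted volume.
4. **2.5-D fine segmentation** — three single-view models, one per
   orthogonal plane (axial/sagittal/coronal), segment the 2×-down-sampled
   crop slice-wise; left/right models are obtained from joint-lung models by
   retraining only the decoder with the encoder frozen.
5. **Majority-vote fusion** — each voxel takes the label at least two views
   agree on; three-way disagreement is arbitrated by the highest mean class
   probability, else background.
6. **Cleaning and densitometry** — lung-labelled voxels with HU outside
   [−1040, +121] are dropped; the rest are binned into hyper-inflated
   [−1040, −860), normo-aerated [−860, −435), hypo-aerated [−435, −121) and
   non-aerated [−121, +121] compartments, and volumes/percentages are
   reported per side and for the whole lung.

## Segmentation backends

The pipeline is written against a backend contract: anything that maps a 2-D
slice to per-class probability maps.  Three implementations ship.

The **trainable backend** is a deliberately small encoder/decoder network
over per-pixel features: raw intensity, Gaussian-smoothed intensity at
σ = 1 and σ = 3 pixels, gradient magnitude, normalised in-slice coordinates,
normalised stack position, and radial distance from the slice centre.  A
single tanh hidden layer (default width 16) is the *encoder*; the softmax
output layer is the *decoder*.  Transfer learning from joint-lung to
left/right replaces and retrains the decoder for the three-class problem
while the encoder weights and the feature normalisation are frozen —
the package asserts bit-identity of the encoder before and after.  Training
uses Adam on mini-batches of whole slices, class-balanced pixel sampling,
and early stopping on validation cross-entropy.  The two-class joint stage
optimises a softmax cross-entropy that coincides with binary cross-entropy
on the lung probability; the coarse and left/right stages use categorical
cross-entropy.

The **oracle backend** passes stored ground truth through as indicator
probabilities, optionally after boundary corruption (erosion plus random
boundary flips); it isolates downstream stages in tests.  The **classical
backend** is a non-learned grey-level-band baseline (air band + connected
components for airways, mid-band for lungs) useful as a sanity reference.

### Reference training recipe and the scaled-down recipe

The package defaults mirror the reference recipe: Adam with learning rate
10⁻⁴, mini-batches of 24 slices (coarse) and 4 slices (fine), early-stopping
patience 10 epochs, augmentation ranges ±5° rotation, ±5 % shift, ±15 % zoom.
Those values are sized for runs seeing on the order of 10⁵ training slices
and 10⁶ gradient steps.

The test-suite and acceptance experiments run at desk scale: 64³ phantoms,
16 training scans, a few hundred slices, and a few thousand gradient steps —
two orders of magnitude fewer steps.  At that budget a 10⁻⁴ step size leaves
the model far from convergence, so the scaled-down recipe uses learning rate
3 × 10⁻³ with at most 300 epochs, and a coarse down-sampling factor of 2
(64² slices become 32²; factor 4 would leave 16² slices that cannot carry
the anatomy).  These are optimisation-budget choices for the small problem,
not changes to the synthetic study conditions.

## The phantom generator

Because no public dataset exists for this task, the package ships a
synthetic murine-thorax generator that every stage is tested against.  A
phantom is: a superellipsoid thorax of soft tissue with a thin high-density
(rib-like) shell; two ellipsoidal lungs separated from an ellipsoidal
midline heart by a guaranteed mediastinal gap; and a three-generation
cylindrical airway tree entering at the cranial face.  Intensities are raw
grey levels: airway lumen mean 801.8, heart mean 2250.19 (the calibration
anchors), soft tissue 2200, plus additive Gaussian noise (default sd 20
grey levels, a realistic noise floor for gated bench-top reconstructions).
The ground-truth grey-level→HU relation is the exact line through
(801.8, −1000) and (2250.19, +50), so automatic calibration has an exact
oracle.

Lung texture is generated from the aeration mixture: compartment quotas are
drawn multinomially from the mixture weights (default hyper 0.20, normo
0.70, hypo 0.08, non 0.02 — a healthy profile), HU values are drawn
uniformly within each compartment's bin, and quotas are *placed* by ranking
lung voxels on a lesion field of Gaussian blobs seeded subpleurally.  Denser
compartments therefore form spatially coherent lesions while the marginal
fractions recover the mixture (to within multinomial error, ±2 percentage
points at 128³).  The `fibrosis_severity` parameter interpolates the
mixture toward a fibrotic profile (hyper 0.02, normo 0.28, hypo 0.35, non
0.35), so lesions nest monotonically with severity.  Cohorts give each
synthetic mouse one anatomy seed shared across timepoints of increasing
severity (spanning severity 0–0.6 by default, a mild-to-moderate disease
course) and an independent noise seed per scan.

One scale choice deserves a note: the airway radii (trachea 0.055 of the
grid, bronchi 0.036, third generation 0.022) are proportionally wider than
murine anatomy.  At 64³ an anatomically scaled trachea would be ~2 voxels
wide — narrower than the 5×5×5 median pre-filter, which would erase it.  No
real scan has that property (at 512³ the trachea spans ~30 voxels), so the
phantom keeps the lumen resolvable relative to the filter rather than
proportional to the body.

What the phantom does *not* model: beam hardening, scatter, gating
artefacts, lobar anatomy, anatomical variation beyond the seeds, or the
texture statistics of real parenchyma.  Passing the phantom suite shows the
pipeline's machinery is correct and trainable, not that the shipped tiny
backend would match a U-Net on real scans.

## Numerical choices

* **Axis convention**: grids are (z, y, x); axial slices fix z, sagittal fix
  x, coronal fix y.  Voxel indices are 0-based; bounding boxes are half-open
  `[origin, origin + extent)`.
* **Median filter borders**: reflect padding, which keeps the output shape
  and avoids edge darkening.
* **Non-divisible down-sampling**: pad with the volume minimum (raw
  background is dark) or background labels to the next multiple.
* **Out-of-grid crops**: filled with −1040 HU (the air floor of the
  densitometric range) for HU volumes, the grid minimum for raw volumes.
* **Binarization conflicts**: the highest-probability class above its
  threshold wins; exact ties go to the lowest class code.
* **Threshold optimisation**: per class independently, maximising mean
  per-volume Dice over a 0.05…0.95 grid; ties break toward 0.5, then toward
  the larger threshold.  The shipped operating points are 0.45 per coarse
  class, and 0.45/0.45 (axial), 0.40/0.40 (sagittal, coronal) for the
  left/right stage.
* **Vote ties**: with three-way disagreement the mean class probability
  across views arbitrates; without probabilities the voxel falls to
  background.
* **Compartment bin edges**: the published ranges share endpoints, so the
  package uses half-open bins closed on the left with the top bin closed on
  both ends — an exact partition with no double counting.  The bin test at
  −860 HU therefore assigns the voxel to normo-aerated, and −121 HU to
  non-aerated.
* **Dice of two empty masks** is defined as 1 (perfect agreement on
  absence).
* **Calibration masks**: region means are taken on the median-filtered
  volume under the coarse masks, eroded by 1 voxel (boundary partial-volume
  bias), and — beyond the erosion — restricted to voxels with class
  probability above 0.9.  The high-confidence cut exists because the
  binarized airway mask can carry low-confidence false positives near the
  carina whose soft-tissue grey levels bias the airway mean by hundreds of
  grey levels; the confident core is a representative air sample.  Both
  knobs are configurable (`calibration_erode`, `calibration_confidence`).
* **Densitometry grid**: fine predictions are up-sampled (nearest) from the
  2×-down-sampled grid back to the crop resolution before cleaning and
  binning, so volumes are counted at the resolution the calibration was
  applied at.
* **Left/right percentages**: reports carry both denominators (percent of
  the structure and percent of total lung volume).

## Design questions that were genuinely open

* Whether the median filter runs before or after coarse down-sampling is
  unstated upstream; the package filters at full resolution first, matching
  the pre-processing description of the source protocol.
* Coarse thresholds are optimised per class independently, and the two
  left/right thresholds likewise; joint optimisation over the threshold
  pair was not worth the quadratic grid at the observed insensitivity.
* Per-view slice counts in the reference tables imply partial stacks with
  in-plane sizes that conflict with the stated crop (192 × 120 vs the
  384 × 320 × 384 crop halved); the package uses full stacks at the sizes
  the crop implies (axial 160 × 192, sagittal 192 × 160, coronal 192 × 192
  under its axis convention).
* Augmentation is applied as additional randomly transformed copies of the
  training slices rather than on the fly per mini-batch; with the pixel-MLP
  backend the pool-level augmentation reaches the same invariances at lower
  cost.
* Only end-expiration (P02) phantoms train the models; end-inspiration
  (P01) variants exist to probe generalisation, mirroring how densitometry
  is acquired in practice.

## Problem sizes used by the shipped experiments

The test-suite and acceptance script train on 16 phantoms of 64³ voxels
(8 synthetic mice × 2 timepoints, severity 0–0.6, noise sd 20), validate on
4 and evaluate on 6 held-out phantoms, with bounding-box extent 48 × 40 × 48
and the scaled-down recipe above; the mixture-recovery check runs at 128³.
These sizes keep the full suite in the tens of minutes on one CPU while
leaving each accuracy bar a comfortable margin.

## Limitations

The shipped backend is a pixel-feature network chosen for CPU-scale
training and testability; real deployments would slot a convolutional
encoder/decoder behind the same backend contract and train it at full
resolution.  The phantom's geometric simplicity means phantom Dice values
should not be read as expected real-data performance.  HU calibration
assumes the coarse model finds a usable airway and heart core; scans in
which it cannot raise a tagged calibration error rather than producing a
silently wrong conversion.
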