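# muridens

Automated lung segmentation and compartmental densitometry for thoracic
micro-CT scans of murine pulmonary-fibrosis models.

## The problem

Bleomycin-induced pulmonary fibrosis in mice is routinely monitored with
respiratory-gated micro-CT, because the linear relation between X-ray
attenuation and tissue density turns the whole lung volume into a
quantitative readout.  Two things stand in the way of automation: bench-top
scanners produce raw detector grey levels rather than Hounsfield units (HU),
and fibrotic parenchyma becomes dense enough that lungs are hard to separate
from surrounding soft tissue — the historical reason these scans were
segmented by hand.

`muridens` implements a fully automated coarse-to-fine pipeline:

1. **Coarse localization** — multi-class segmentation of joint lungs, heart
   and airways on axial slices down-sampled in-plane by 4.
2. **Automatic HU calibration** — the unique line through
   (mean airway grey level, −1000 HU) and (mean heart grey level, +50 HU):
   `HU = slope · GL + intercept`.
3. **ROI cropping** — a fixed cuboid (default 384 × 320 × 384 voxels)
   centred on the coarse lung centroid.
4. **2.5-D fine segmentation** — three single-view models (axial, sagittal,
   coronal) on the 2×-down-sampled HU crop; left/right models are derived
   from joint-lung models by encoder-frozen transfer learning.
5. **Majority-vote fusion** — per voxel, the label at least two views agree
   on; three-way ties are arbitrated by mean class probability.
6. **Cleaning + densitometry** — lung voxels with HU outside [−1040, +121]
   are discarded; the rest are binned into aeration compartments

   | compartment     | HU range        |
   |-----------------|-----------------|
   | hyper-inflated  | [−1040, −860)   |
   | normo-aerated   | [−860, −435)    |
   | hypo-aerated    | [−435, −121)    |
   | non-aerated     | [−121, +121]    |

   and reported as volumes (mm³) and percentages per left lung, right lung
   and total lung.

Evaluation utilities cover the Dice coefficient, absolute percent volume
error, per-compartment percentage-point errors, Bland–Altman limits of
agreement, trend-line R², and mouse-grouped k-fold splitting for
longitudinal cohorts.

Because no public dataset of this kind exists, the package ships a synthetic
murine-thorax phantom generator (ground-truth labels, exact grey-level→HU
line, graded fibrotic involvement, paired end-inspiration/end-expiration
variants) against which every stage is trained and tested.

## Worked example

Generate a fibrotic phantom, run the ground-truth densitometry, and inspect
the report:

```r
library(muridens)

spec  <- phantom_spec(fibrosis_severity = 0.5, seed = 7)
s     <- generate_phantom(spec)
truth <- relabel(s$truth_labels, c(left_lung = 1L, right_lung = 2L))
clean <- clean_segmentation(truth, s$truth_hu)
comp  <- compartmentalize(clean, s$truth_hu)
densitometry_report(comp, clean)
```

```
<densitometry_report> voxel volume 0.000125 mm^3
  left       1.090 mm^3 : hyper 12.1% normo 43.0% hypo 24.7% non 20.1%
  right      1.370 mm^3 : hyper 11.4% normo 52.7% hypo 20.1% non 15.8%
  total      2.460 mm^3 : hyper 11.7% normo 48.4% hypo 22.1% non 17.8%
```

At severity 0.5 the generator has moved roughly a third of the healthy
normo-aerated volume (70 %) into the hypo- and non-aerated compartments —
the densitometric signature of fibrosis.  The full pipeline (train on a
phantom cohort, segment held-out scans, calibrate HU automatically) is
exercised end to end by `scripts/acceptance.R` and by the test suite; a
command-line front end lives at `inst/cli/muridens.R`:

```sh
Rscript inst/cli/muridens.R phantom --n 4 --seed 1 --out-dir phantoms/
Rscript inst/cli/muridens.R train-demo --out models.rds --seed 1
Rscript inst/cli/muridens.R run --in phantoms/M001_T2.nii.gz --models models.rds --out-dir out/
```

## Package layout

* `R/` — volume containers and I/O (NIfTI/TIFF), 3-D median filtering and
  resampling, the phantom generator, segmentation backends and training,
  coarse localization and bounding boxes, HU calibration, fine single-view
  models and transfer learning, vote fusion and densitometry, evaluation
  metrics, and the pipeline orchestrator.
* `src/` — Rcpp kernels for the 3-D median filter and 6-connected
  component labelling.
* `vignettes/muridens-methods.Rmd` — the model, its assumptions, numerical
  choices and limitations.
* `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
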