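---
title: "Corruption simulation and DSC-ranked auto-curation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corruption simulation and DSC-ranked auto-curation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Clinical reference segmentations of organs-at-risk — the parotid gland is
the paradigm here — carry annotation noise: systematic biases such as
lateral over-segmentation that sweeps in skin, bone and air, and random
deviations near structure boundaries. Models trained on such labels learn
the noise, and the damage is invisible when validation labels come from the
same noisy distribution ("apparent" performance) rather than from verified
clean references ("true" performance).

`segcurate` implements, end to end and at desk scale, the machinery needed
to study this: a corruption simulator for binary organ masks, an
auto-curation training procedure that removes the worst-fitting training
cases early, the surface-distance metric suite, ensembling, the associated
statistics, and a synthetic CT-like phantom cohort generator so that every
experiment is reproducible from a seed with no clinical data.

## The corruption model

Two operators act on a reference mask, both realized as directional
morphology with a line structuring element (a ball element would not be
directional, and the corruption modes being emulated are axis-aligned):

* **Systematic lateral corruption** dilates the mask along the sagittal
  axis, away from the mid-sagittal plane (`+axis1` for a right-sided organ).
  The default magnitude is 10 voxels = 1.0 cm at the default 1 mm isotropic
  spacing.
* **Random corruption** samples dilate/erode with probability 1/2 each and
  one of the six signed Cartesian directions with probability 1/6 each.
  Erosions are 20% smaller than dilations (`round(0.8 * m)`, 8 voxels for
  `m = 10`) to compensate for the size sensitivity of overlap agreement.

Design points the operators fix explicitly, because the underlying idea
leaves them open:

* Erosion acts on the single face in the sampled direction, not
  symmetrically; the applied operator, direction and magnitude are recorded
  per case in a `corruption_record` so every corruption is reproducible.
* An erosion that would empty a mask triggers a direction resample (up to
  six attempts) rather than silently producing an empty reference.
* Cohort corruption at fraction *i* selects exactly `round(i * N)` cases
  (round half away from zero) uniformly without replacement under a derived
  seed, and returns the ground-truth corrupted id set.
* `calibrate_magnitude()` picks the integer magnitude whose median
  agreement DSC under 100% corruption is closest to a target (ties to the
  smaller magnitude). The standard target used in the package's experiments
  is a median agreement of 0.778, the level at which fully perturbed labels
  match the poorest-agreement quartile of a clinically contoured cohort.

## The curation procedure

Curation is sample selection, exploiting the observation that networks fit
dominant consensus structure before they fit minority corruptions:

1. **Prompt training**: train for `ceiling(0.25 * E)` of the full `E`
   epochs.
2. **Ranking**: score every *training* case by the DSC between the prompt
   model's prediction and that case's own (possibly corrupted) reference
   label. Ranking against the training labels — not against any clean
   reference — is what makes the procedure applicable in practice, where no
   clean reference exists.
3. **Removal**: drop the `floor(R * N)` lowest-DSC cases. Ties break by
   case id so the procedure is deterministic. Validation and test cases are
   never candidates.
4. **Retraining**: reinitialize the weights with a fresh derived seed and
   train the full `E` epochs on the kept cases only.

Scoring against known ground truth uses the definitions: sensitivity is the
fraction of truly corrupted cases removed; specificity is the fraction of
removed cases that genuinely warranted removal; agreement across repeated
runs is the mean pairwise `|A_i ∩ A_j| / k`. The pairwise-overlap form was
chosen over alternatives because its expectation under uniform random
removal equals the curation rate `k / N`, which gives the natural
chance-level anchor (removal of 20% at random yields agreement 0.20).

Ensembles average per-voxel *pre-sigmoid* scores across models and
threshold the mean at zero; for a single binary output this equals
thresholding the sigmoid of the mean logit at 0.5.

## Metrics

* DSC `= 2|A∩B| / (|A|+|B|)`; two empty masks score 1 by convention,
  empty-vs-nonempty scores 0.
* Surfaces are foreground voxels with at least one of six face-neighbours
  background, with the grid boundary counting as background. Distances are
  measured between surface-voxel centres scaled by spacing — no sub-voxel
  mesh — which is consistent with the voxel-based corruption model. MSD is
  the symmetric average of the two directed mean nearest-surface distances;
  HD is the maximum (not a percentile variant). MSD/HD are an error for
  empty inputs.

## The phantom generator

Each case is a deformed ellipsoid organ (radius drawn from 5.5–6.5 mm,
per-axis eccentricity 0.9–1.08, low-frequency radial perturbation of 1 mm
built from random first- and second-order directional harmonics) placed
3 voxels lateral of the mid-sagittal plane with ±1 voxel jitter, on a 48³
grid at 1 mm isotropic spacing. The intensity model is soft tissue (mean
30) with the organ at 80, plus a high-intensity bone/skin slab (700) and a
low-intensity air pocket (−800) placed laterally adjacent to the organ —
so that lateral over-segmentation sweeps through tissue the organ never
contains, the same signature seen in clinically biased contours. The model
is smoothed at 1 mm and Gaussian noise (sd 15) is added.

Defaults were chosen once, to satisfy two constraints: the organ must look
parotid-like relative to the grid (a compact lateral structure occupying a
few percent of the volume), and every generated mask must keep at least
`max_corruption + 1 = 11` voxels of margin to the grid boundary so that
magnitude-10 dilation in any direction stays on the grid. The parameter
validator enforces the margin for the worst case at construction time.

Clean reference labels are exact phantom boundaries; an observer-jitter
knob (±1 voxel random boundary perturbation) exists but is off by default
so the clean/corrupt distinction stays sharp. Cohorts are pure functions of
`(params, n, proportions, seed)`: per-case seeds derive deterministically
from the master seed. The out-of-distribution cohort is produced by
`shift_distribution()`, which offsets named parameters and revalidates.

What the phantom does *not* emulate: real CT texture and artifacts,
multi-organ context, anatomical shape statistics of actual parotids, and
inter-observer delineation style. Passing tests on phantoms therefore show
that the pipeline's logic and its corruption/curation mechanics are
correct, not that any particular clinical DSC will be achieved.

## The trainable backend

The curation machinery is backend-agnostic: anything supporting
`init_segmenter()` / `train_segmenter()` / `predict_logits()` can be
curated. The configuration also carries the classical 3D U-Net filter plan
(depth layers, input-layer filters, filters doubling per depth, batch-norm
after the nonlinear activation), exposed as pure arithmetic via
`stage_filters()` and `unet_parameter_count()`.

The built-in desk-scale backend is a shallow convolutional scorer chosen to
be trainable in seconds on one CPU while still exhibiting the phenomena
under study:

* intensities are robust-normalized (median / IQR-based sd of the training
  intensities, frozen into the model), smoothed with a fixed 1 mm Gaussian,
  and expanded into a radial-basis bank over the z-score (centres −6..6,
  width 1.5) — a band detector, so bright bone and dark air are separable
  from the mid-intensity organ, which no monotone intensity threshold can
  do;
* a cohort spatial-prior channel (smoothed mean of the training masks,
  rescaled to ±1) plus two copies of that prior shifted laterally by ±3
  voxels. The shifted copies give the scorer the capacity to *represent* a
  systematic lateral displacement, so biased training labels can actually
  be learned and reproduced — the mechanism by which label bias damages a
  segmentation model — rather than being silently averaged away by an
  over-rigid model class;
* a trainable 1×1×1 convolution over these channels produces the per-voxel
  pre-sigmoid score; training is full-batch Adam (default step 0.3) on mean
  per-case soft-Dice loss, which is overlap-based and involves no
  distance-to-boundary information. Training runs on a crop around the
  union of the training masks (margin 14 voxels) for speed; prediction is
  full-grid. Masks are logits thresholded at 0.

Everything about the backend is deterministic given `(config, seed)`:
initialization is seeded, training is full-batch, and the normalization
statistics and prior are frozen at training time.

## Statistics

Paired DSC comparisons use the two-sided Wilcoxon signed-rank test, zero
differences discarded (the classical convention; Pratt's variant was
deliberately not used). The exact null distribution applies for n ≤ 25
without ties, otherwise the normal approximation with tie correction.
Multiplicity is handled by threshold adjustment (`alpha / m`), displayed to
two significant figures — 0.05 over 27 comparisons gives 1.9e-3. Repeated
runs are collapsed to per-case medians (`aggregate_repeats()`) before
testing, so tests consume independent data points rather than pooled
repeats.

## Experiment pipelines and problem sizes

The `run_*` functions orchestrate the standard experiment series: the
corruption-impact grid (by default 21 fractions × 2 modes = 42
configurations over one fixed train/val/test allocation), the
seven-condition curation matrix (clean baseline, random removal, curation
on clean data, and 30% systematic/random corruption with and without 30%
curation, each over seeded folds), the curation-rate sweep against a
random-removal baseline with true/apparent/external evaluation sets,
repeated random sub-sampling, repeated curation at the best rate with
ensembling, and k-fold cross-validation with DSC-quartile assignment
(quartiles on out-of-fold DSC rank, ties by id).

The package's standard scaled experiment (`scaled_curation_study()`) uses
60 training and 20 clean test cases on the 48³ grid, 30% systematic
corruption calibrated to median agreement 0.778, the 40-epoch backend with
a 25% prompt phase, and 30% removal, repeated over 5 master seeds. These
sizes were chosen as the smallest cohort at which the corrupted subgroup
(18 cases) is large enough for a stable sensitivity estimate; unit tests
use a 32³ phantom variant for speed.

## Numerical conventions and degenerate inputs

* Removal counts use `floor(R * N)`; corruption counts use round half away
  from zero on `i * N`. A fraction that rounds to zero warns rather than
  errors.
* Split allocation uses largest-remainder rounding, earlier split on ties;
  `n = 1` therefore lands in the first (training) split.
* All sub-seeds derive from one master seed by a deterministic string hash
  (FNV-style, folded into the positive 31-bit range), so every run is
  reproducible and prompt/retrain phases are independent but seeded.
* Dilation refuses to push foreground across the grid boundary under the
  corruption semantics (`clip = FALSE`); the plain morphological semantics
  with boundary clipping is available via `clip = TRUE`. The
  erosion/dilation complement duality is exact once the grid is embedded in
  a background ring of width `m` (the exterior counts as background for the
  mask but as foreground for its complement), and the test suite checks it
  in that form.

## Known limitations

* The backend is a linear scorer over fixed channels, not a deep network;
  it reproduces the qualitative phenomena (consensus-first fitting, bias
  learning, curation recovery) but its absolute DSC values are not
  comparable to clinical-scale 3D U-Net results, and effects whose
  magnitude depends on network capacity (e.g. memorization dynamics late
  in training) are outside its reach.
* DICOM/DICOM-RT input, resampling between scanners, and dose-based
  evaluation are out of scope; NIfTI is the sole volume format.
* The specialist quality rubric is encoded as a synthetic oracle driven by
  corruption agreement; it stands in for manual review in synthetic runs
  and is labelled as such.
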