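---
title: "Quantifying label-induced instability of SN-conditioned QSM classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying label-induced instability of SN-conditioned QSM classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Automated Parkinson's disease (PD) diagnosis from quantitative
susceptibility mapping (QSM) conditions on a label of the substantia nigra
(SN): either the image is masked to the SN before feature extraction, or
region statistics are pooled over the labeled voxels. SN labels come from
different experts and from segmentation algorithms, and they disagree —
typically at the region boundary, where iron-rich neighbors give the SN a
sharp, bright edge. A clinically usable classifier must not change its
diagnosis because the label shifted by a voxel or two.

`nigrastab` provides the full experimental apparatus for studying this:
controlled label perturbation at prescribed Dice levels, two classifier
families that consume labels in different ways, a segmentation network
that can replace the expert, a jointly trained end-to-end model, and the
statistics (metric panels, the classification consistency index, paired
tests) that summarize the outcome.

## The phantom cohort generator

Because clinical QSM cohorts are not redistributable, every experiment in
the package runs on synthetic phantoms designed to carry the statistical
structure the analyses rely on:

* **Geometry.** Two axis-aligned ellipsoidal nuclei (semi-axes drawn
  uniformly from 3.0–4.2 mm, mild positional jitter) placed bilaterally in
  a 48×48×32 grid at 0.86×0.86×1.0 mm spacing. The reference mask is the
  exact voxelization: a voxel is foreground iff its center satisfies the
  ellipsoid inequality (boundary equality counts as foreground). The
  narrow size range mirrors the fairly consistent adult SN volume; with a
  much wider range, region-size variation would dominate pooled intensity
  features and mask the disease signal.
* **Intensity.** Units are QSM-like ppb. Interior intensity is
  `N(class mean, class sd)` per subject (defaults: HC 90 ± 10, PD
  120 ± 18 — the disease class is both brighter and more heterogeneous,
  so first-order *and* texture features carry signal), plus spatially
  correlated texture noise (white noise smoothed at 2 mm correlation
  length, 8 ppb amplitude). Background sits at 20 ± 10 ppb. A one-voxel
  interior rim gains +25 ppb, sharpening the boundary gradient.
* **Distractors.** Each nucleus has an adjacent bright structure (a red
  nucleus analogue: 150 ± 10 ppb, radius 2–3 mm, offset medially and
  anteriorly) whose intensity is *independent of diagnosis*. This is the
  load-bearing realism ingredient for the stability experiments: labels
  that drift off the SN pick up bright distractor voxels, which is what
  destabilizes intensity features. With a uniformly dark background,
  quantile features would be artificially immune to boundary drift and
  the radiomics baseline would look more stable than it is on real
  anatomy.
* **What is not modeled.** MR acquisition physics and dipole inversion,
  demographic covariates, and SN substructure (nigrosomes): interiors are
  statistically homogeneous. Consequently, passing experiments demonstrate
  the *mechanisms* (edge sensitivity, pooling-level invariance), not
  clinical performance levels.

Everything is deterministic in `(params, seed)`; per-subject seeds derive
from the cohort seed.

## Dice-controlled label perturbation

The perturbed label families are produced by warping each reference mask
through a smooth random displacement field (componentwise Gaussian-smoothed
white noise, default smoothing 4 mm, zero mean, unit-normalized to 1 mm
maximum displacement) scaled by a magnitude α. Masks are interpolated
trilinearly and thresholded at 0.5; samples outside the grid read as
background. Achieved Dice is empirically monotone non-increasing in α, so
`solve_alpha_for_dice()` bisects α until the achieved Dice is within
tolerance (default ±0.005) of the target, with a dense 200-point grid
search as a fallback if monotonicity fails at bisection resolution. All
levels of one subject share one field with increasing α, so the family is
a nested, gradual deviation. Note the normalization is global: the local
field magnitude at the nuclei is usually well below the 1 mm maximum, so
`make_label_series()` allows α up to 15 mm by default.

This replaces a registration-derived deformation between a manual and an
automatic labeling. The two properties that matter — smoothness and
gradual, controllable deviation — are preserved while the achieved Dice
becomes exact and seed-reproducible.

## Classifier arms

**Radiomics + logistic regression.** A documented 29-feature subset (17
first-order statistics, 6 shape descriptors, 6 gray-level co-occurrence
statistics at 1-voxel offsets averaged over the 13 unique 3D directions,
16 fixed bins over the in-mask range) stands in for a full radiomics
configuration; the extractor is pluggable. Features are screened for label
robustness by ICC(2,1) — two-way random effects, absolute agreement,
single rater — between the reference and *every* perturbed label set; a
feature survives only if all pairings exceed 0.8 (strict). Degenerate
(constant) features return `NA` and fail the screen. The classifier is an
L2-regularized logistic model with recursive feature elimination: drop the
smallest absolute standardized weight (lexicographic tie-break), refit,
until `n_final` (default 10) remain. The ridge fit is delegated to
`glmnet` at a fixed penalty.

**CNN classifiers.** The extractor is a stack of stride-1 conv blocks —
the first fixed at 6 channels, 5×5×5 — with desk-scale defaults
6→12→16 channels on a 16×16×12 ROI (cropped from the label bounding box
plus a 4-voxel margin and trilinearly resampled). Inputs are normalized by
the fixed affine map `(x − 70)/70` ppb: QSM is quantitative and the
diagnostic signal *is* the absolute susceptibility level, so per-sample
standardization (z-scoring, or per-sample channel normalization inside the
network) would remove it — the optional normalization toggle is therefore
off by default for classification, while the segmentation network keeps it
on (its signal is spatial contrast). Two conditioning modes:

* *masked*: input is zeroed outside the label, pooled by global averaging.
  The label edge becomes an intensity edge in the input, so label changes
  propagate through every convolution.
* *gated*: the un-zeroed ROI is encoded once; the label enters only as a
  pooling gate. Both normalizations are implemented —
  `sum(g·f)/sum(g)` (gate mass; default for binary gates) and
  `mean(g·f)` (ROI size; the form used with the probability gate) —
  because the two readings describe different models; the mode is recorded
  with each run. Algebraically, perturbations strictly outside the gate
  support cannot change the pooled vector; this is the pooling-level
  stability mechanism, and it is asserted exactly in the tests.

Training is cross-entropy with Adam (default 15 epochs at learning rate
5e-3, single-volume batches, seeded shuffling); the best-validation-epoch
weights are kept, with ties resolved toward the later epoch so a plateaued
validation score does not freeze a half-trained model.

## Segmentation and the joint model

SN² is a pooling-free (stride-1 everywhere; configs with downsampling are
rejected) coarse-to-fine network: two densely connected trunks (depth 3,
growth 6; each layer consumes the concatenation of the input and all
previous outputs) feed an initial 2-class softmax head and a
signed-distance regression head; their outputs are concatenated along
channels and fused by a 3×3×3 convolution with softmax into the fine
segmentation. Distance targets use the package's anisotropic
center-to-center signed Euclidean distance transform, clipped to ±10 mm
and scaled to [−1, 1]. The loss is
`w_seg (soft Dice + voxel cross-entropy) + w_dist L1`, defaults
(1, 0.5); the distance branch penalizes confident predictions far from
the boundary, suppressing isolated false positives. The network operates
on a population ROI box (union of training-mask boxes plus margin) stored
with the model, so segmenting a new volume requires no mask.

The joint model gates the classifier's feature maps by
`δ(p) = 0 / 5p − 2 / 1` of the fine probability map (continuous by
construction; the constructor enforces `δ(0.4) = 0`, `δ(0.6) = 1`) and
pools by the global mean of `δ(p)·f`. Training is end-to-end with the
combined loss `w_seg·seg + w_dist·dist + w_cls·CE`; gradients pass through
δ (piecewise-linear, slope 5 on the middle branch, zero elsewhere). Two
starting points are supported: from scratch with a few segmentation-only
warm-up epochs, or warm-started from an already trained SN² and gated
classifier — in that case the first dense layer of the head is rescaled by
the mean gate mass, compensating the switch from gate-mass to ROI-size
pooling normalization, and fine-tuned end-to-end. The comparison harness
uses the warm start (the models are trained per fold anyway); with it the
joint model trains reliably within the CPU budget, whereas from-scratch
training needs substantially more epochs because the globally pooled
vector is small and confounded by predicted-region size early in
training. If the gate is identically zero (no voxel above probability
0.4) the pooled vector is zero and the prediction is flagged as
degenerate.

## Experiments and their desk-scale conditions

The harness mirrors a sevenfold nested cross-validation with permutations:
stratified, size-balanced test folds (140 subjects reproduce the
100/20/20 train/validation/test split sizes), the validation part used
only for epoch selection. Experiments at the package's desk scale use a
36-subject cohort (18 PD / 18 HC), the full six-level label series, seven
folds, and two permutations for the stability tables (one for the CCI and
joint comparisons); the acceptance checks of the label forge use a
60-subject cohort. These sizes were chosen so the complete suite trains
its ~60 networks in well under half an hour on one CPU; all counts are
arguments, not constants.

Directional findings reproduced on phantoms (and asserted in
`test-acceptance.R` at these conditions):

1. radiomics-LR accuracy declines monotonically as test labels fall from
   Dice 1.0 to 0.872, while being trained on reference labels only;
2. the masked CNN's accuracy spread across levels is smaller than the LR
   spread;
3. gated pooling raises the mean off-diagonal CCI over the masked model;
4. the joint end-to-end model is at least as accurate as the pipeline
   that trains on reference labels and tests on automatic ones.

One plausible direction does **not** reproduce synthetically: training
*and* testing on automatic labels is not worse here than the all-reference
configuration, because the automatic labels are mutually consistent
between training and testing — the phantom study has no analogue of an
expert standard that the automatic labels systematically miss. The
package reports the comparison without asserting its direction.

## Numerical choices and degenerate inputs

* Dice of two empty masks is 1; empty-vs-nonempty is 0 (defensive only).
* AUC uses the rank (Mann–Whitney) formulation with half credit for ties;
  class calls threshold scores at 0.5. Per-split AUCs are averaged,
  matching the mean ± sd presentation of the stability tables.
* The multiple-comparison correction is Bonferroni (configurable), capped
  at 1; zero-variance paired differences return p = 1 on exact ties.
* ICC(2,1) with a zero denominator (constant ratings) returns `NA`,
  treated as a screen failure rather than an error.
* GLCM features of a single-gray-level region take their point-mass
  values (energy 1, contrast 0); correlation, undefined there, is 0.
* Conv weights are He-initialized; all RNG flows through derived seeds so
  every cohort, plan, and training run is bit-reproducible. The
  convolution, distance-transform, and resampling kernels are exact and
  are tested against naive-loop and brute-force oracles, with gradients
  checked by central finite differences.

## Known limitations

Phantom interiors are homogeneous; radiomics texture features carry less
independent signal than on real tissue. Accuracy levels on phantoms are
not comparable to clinical values — only directions and invariances
transfer. At the desk-scale split counts, the spread comparison between
the two classifier arms has limited statistical power: on some cohort
seeds the LR arm happens to select unusually label-stable features and
its spread shrinks below the CNN's. The packaged experiments report
whatever the chosen seed produces; the asserted directional findings use
the package's fixed default conditions. The CNNs are deliberately small; scaling the architecture up is
a configuration change, but CPU training time grows accordingly. The
distance head shares the trunk design of the segmentation head rather
than being tuned separately.
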