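# nigrastab

Stability analysis for Parkinson's disease (PD) classifiers that condition
on substantia nigra (SN) labels in quantitative susceptibility mapping
(QSM) images.

QSM-based PD diagnosis pipelines first delineate the SN — a small,
iron-rich bilateral midbrain nucleus whose susceptibility is elevated in
PD — and then classify the patient from image features of that region. The
labels, however, come from different experts or segmentation algorithms,
and two perfectly reasonable labelings of the same patient can disagree at
the boundary. `nigrastab` quantifies what that disagreement does to a
classifier, and implements the modelling ideas that mitigate it:

* **Phantom cohorts** — synthetic QSM-like volumes (ppb units) with
  bilateral ellipsoidal SN nuclei, class-conditional interior statistics
  (PD brighter and more heterogeneous), correlated texture, a sharp
  boundary rim, and adjacent bright distractor structures (red-nucleus
  analogues), so every experiment runs without any data download.
* **Dice-controlled label perturbation** — smooth random displacement
  fields warp each reference mask, with the field magnitude solved by
  bisection so the perturbed label family `L_1.000, L_0.975, ..., L_0.872`
  achieves prescribed Dice overlaps (default tolerance ±0.005) and deviates
  gradually (one field per subject, increasing magnitude).
* **Radiomics + logistic regression baseline** — masked feature extraction
  (first-order, shape, gray-level co-occurrence), an ICC(2,1) robustness
  screen (`ICC > 0.8` against every perturbed label set), and recursive
  feature elimination over an L2-regularized logistic model.
* **3D CNN classifiers** — a compact convolutional extractor
  (first block fixed to 6@5×5×5, stride 1) with two conditioning modes:
  *masked input* (zero outside the SN label, global average pooling) and
  *gated pooling*, where the un-zeroed ROI is encoded once and the label
  only weights the pooling of feature maps:
  `pool_c = Σ g·f_c / Σ g` (binary gate) or `mean(δ(p)·f_c)` (probability
  gate).
* **SN² segmentation network** — a pooling-free, densely connected
  coarse-to-fine architecture with parallel initial-segmentation and
  signed-distance heads fused by convolution + softmax.
* **Joint end-to-end model** — SN² drives the piecewise-linear gate
  `δ(p) = 0` for `p ≤ 0.4`, `5p − 2` on `(0.4, 0.6]`, `1` for `p > 0.6`,
  fused with the extractor by `feature vector = mean(δ(p) × feature map)`;
  diagnosis needs no external mask at test time.
* **Evaluation harness** — stratified nested cross-validation with
  permutations, per-level metric panels (accuracy, AUC, BAC, sensitivity,
  specificity), the classification consistency index
  (CCI = fraction of test subjects with identical predicted diagnoses
  under two label sources), and matched-samples t-tests with Bonferroni
  correction.

All networks are trained on CPU through the package's own GEMM-based 3D
convolution kernels (RcppArmadillo) with manual backpropagation and Adam.

## Worked example

```r
library(nigrastab)

coh <- generate_cohort(n_pd = 6, n_hc = 6, phantom_params(), seed = 42)
series <- make_label_series(coh, targets = c(0.95, 0.90), tol = 0.005,
                            seed = 7)
print(series)
#> <label_series> 3 levels over 12 subjects
#>   L1.000  target 1.000  achieved 1.0000
#>   L0.950  target 0.950  achieved 0.9510
#>   L0.900  target 0.900  achieved 0.8994

plan <- make_cv_plan(vapply(coh$subjects, `[[`, "", "diagnosis"),
                     folds = 3, n_permutations = 1, seed = 11)
rep <- run_population_stability(coh, series, "radiomics-lr", plan)
subset(rep$summary, metric == "accuracy")
#>    label_source   metric      mean        sd
#> 1        L1.000 accuracy 0.7500000 0.0000000
#> 6        L0.950 accuracy 0.6666667 0.1443376
#> 11       L0.900 accuracy 0.6666667 0.1443376
```

Each level of the series reports its achieved Dice against the reference
labeling; the stability report shows the per-level mean ± sd of test
accuracy over all permutation × fold splits — here the logistic-regression
arm already loses accuracy when tested with labels at Dice 0.90, the
degradation the package is built to measure. (Exact numbers depend on the
RNG stream of your R version; these were produced with R 4.3.)

The CCI of two prediction tables:

```r
cci(preds_under_L1000, preds_under_L0872)   # e.g. 926/1000 -> 0.926
```

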