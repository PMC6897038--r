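---
title: "Hybrid hand-crafted and learned features for nodule patch classification"
author: "noduleFusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid hand-crafted and learned features for nodule patch classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Pulmonary nodules are small, roughly round or oval opacities in lung CT;
distinguishing nodule patches from confusable non-nodule structures
(vessels, flat parenchyma) is the core binary decision of a CAD
second-reader. `noduleFusion` implements a hybrid feature-extraction
pipeline for this decision: three hand-crafted descriptors capture low-level
shape and texture, a small trainable convolutional network contributes a
learned representation, and the four blocks are fused by concatenation
before classification.

* **HOG** (1296 values): on a 28 x 28 patch, 4 x 4-pixel cells each hold a
  9-bin histogram of *unsigned* gradient orientation (0--180 degrees,
  opposite directions share a bin), with magnitude-weighted votes linearly
  interpolated between the two nearest bin centers. Blocks of 2 x 2 cells at
  a 4-pixel stride (6 x 6 block positions) are L2-normalized and
  concatenated: 36 x 4 x 9 = 1296.
* **ExHOG** (648 values): per cell of a 6 x 6 grid, an 18-bin *signed*
  histogram over 0--360 degrees is folded: opposite bins i and i + 9 produce
  nine sum bins (the unsigned histogram) and nine absolute-difference bins.
  The difference bins discriminate bright-on-dark from dark-on-bright edges,
  which plain HOG confounds; a cell with balanced opposite edges (typical
  for thin vessels) folds to near-zero difference bins. Each 18-value cell
  vector is L2-normalized, clipped and re-normalized: 36 x 18 = 648.
* **LBP** (256 values): each interior pixel is encoded by thresholding its
  eight neighbours against the center (ties count as 1), clockwise from the
  top-left with the top-left as least-significant bit; the descriptor is the
  normalized 256-bin code histogram. It is exactly invariant to monotone
  affine intensity maps with positive slope.
* **CNN** (40 values): a nine-layer network -- conv(20, 5x5) -> pool(2x2,
  stride 2) -> conv(32, 5x5) -> pool(2x2, stride 2) -> conv(32, 5x5) -> ReLU
  -> pool(2x2, stride 1) -> conv(40, 4x4) -> linear projection to 2 classes
  with softmax. All convolutions are valid (unpadded), so a 50 x 50 x 1
  input traces 50 -> 46 -> 23 -> 19 -> 9 -> 5 -> 5 -> 4 -> 1 and ends at
  1 x 1 x 2. The feature vector is the 40 activations entering the
  projection, not the 2 softmax scores: a 2-dim output would add nothing to
  fusion.

Fusion is plain concatenation in the fixed order HOG, ExHOG, CNN, LBP,
restricted to the requested subset. The canonical experiment grid crosses
nine feature sets (four singletons, HOG+CNN, ExHOG+CNN, CNN+LBP,
ExHOG+CNN+LBP, HOG+CNN+LBP) with four classifiers (RBF-kernel SVM, 1-NN,
CART decision tree, 100-tree random forest): 36 combinations.

## Evaluation protocol and metric conventions

Validation uses five independent stratified train/test partitions at train
fractions 10, 20, 30, 40 and 50 percent. The held-out predictions of the
five splits are pooled into a single confusion matrix per combination; this
pooled-prediction counting is a documented design choice (per-split matrices
would each be a different size). All combinations share the same five
splits, so a hybrid and its constituent singletons are compared on identical
partitions. Features are z-scored with statistics computed on the train
split only -- the harness asserts the absence of test leakage in its tests.

Confusion matrices follow the layout of the published tables this package
reconciles against: row one holds the true nodules (recovered, missed), row
two the true non-nodules (missed, rejected), and the four cells are named
TP, FP, FN, TN *in that order*. Under this convention, the arithmetic that
reproduces every reproducible published value is:
accuracy = (TP+TN)/n, sensitivity = recall = PPV = TP/(TP+FP),
precision = TP/(TP+FN), NPV = TN/(TN+FN), specificity = TN/(FP+TN),
F = 2PR/(P+R), and Cohen's kappa with chance agreement from the marginals.
`metricsPanel()` also reports standard-convention aliases
(`sensitivityStd`, `specificityStd`, `ppvStd`, `npvStd`) for readers used to
the textbook definitions. Four published values do not follow from their own
printed matrices under any of these formulas (both specificity claims, one
F-score, one kappa); `verifyPrintedMetrics()` reports them as mismatches
rather than hiding them, and one printed matrix (KNN with HOG+CNN) sums to
457 rather than 467 true nodules and is preserved verbatim. Published
percentages are often truncated rather than rounded, so reconciliation
accepts one unit in the last printed digit plus 0.02 percentage points.

## The synthetic data generator

The generator emulates the structure of LIDC-style nodule patch data so the
pipeline is testable end to end without the CT archive: 467 nodule and 131
non-nodule samples by default, each a stack of five consecutive 50 x 50
slices (p2, p1, n, n1, n2) with manifest fields patientid, noduleid,
slicenumber, zposition, diameter and label.

* Nodules: an anisotropic Gaussian blob, amplitude U(0.5, 0.9) over a 0.2
  background, radius U(3, 8) pixels, aspect U(0.75, 1.3) with random
  rotation (the "round or oval" morphology), center jittered up to 10% of
  the patch. The blob is scaled by (1, 0.7, 0.4) at slice offsets 0, 1, 2 --
  a 3-D structure sampled by five planes.
* Non-nodules: half are vessel-like bright ridges (Gaussian cross-profile,
  width U(1.5, 3) px, amplitude shared with the nodule range so intensity
  alone cannot separate the classes), half are flat background -- two
  confusable negative modes. Ridges persist unchanged across the five
  slices, as vessels do.
* Per-slice additive Gaussian noise (sd 0.05 by default) and clipping to
  [0, 1].

What this emulates is geometry and topology, not CT physics: there is no
Hounsfield calibration, no partial-volume effect, no lung anatomy, and the
negative class is far cleaner than real candidate sets. Passing the
end-to-end checks therefore demonstrates that the pipeline is wired
correctly and that fusion behaves sensibly on data with the assumed
structure -- it says nothing about accuracy on real CT, which the package
addresses only through the published confusion matrices.

By default each stack contributes its center slice to the feature table, so
the evaluated sample count equals the stack count (598 under the default
conditions); `extractFeatures(slices = "all")` expands every stack to five
samples carrying the stack's label.

## Numerical and design choices

* **Gradients**: centered (-1 0 1) kernels with edge replication; the
  orientation of zero-magnitude pixels is defined as 0. Unsigned orientation
  (HOG) is the signed angle modulo pi -- this reconciles the full-circle
  gradient definition with the half-circle histogram.
* **ExHOG cell grid**: 648 = 36 x 18 forces a 6 x 6 grid of 18-bin cells on
  a 28-pixel patch, which is not an integer cell size; pixels are assigned
  to cell floor(6 x / 28). Exact bin-count agreement takes precedence over
  integer cells.
* **Normalization guards**: every L2 normalization uses an epsilon of 1e-12
  and maps all-zero vectors (constant patches) to zero vectors. The ExHOG
  clipping threshold is 0.2 of the cell norm, the usual re-normalized
  clipping level.
* **LBP bit order** is a documented constant; any fixed order is a pure
  relabeling of histogram bins and cannot change any downstream classifier.
* **Resizing** is bilinear (each descriptor declares its own working size:
  28 for the hand-crafted descriptors, 50 for the network); constants are
  preserved exactly and outputs stay within the input range.
* **Pooling strides**: the printed layer list composes to a 1 x 1 x 2
  output only with pool strides (2, 2, 1), which is the sequence
  implemented; the stated pool of stride 1 is the third one. The final
  softmax needs a 40 -> 2 linear projection, treated as part of the softmax
  layer.
* **CNN training**: plain SGD, learning rate 0.01, mini-batch 32, He
  initialization, seeded end to end. The training problem sizes used by the
  test suite and worked examples are 300 SGD iterations on the synthetic
  task (it converges in well under the 1770-iteration cap that applies to
  the harder real-data setting).
* **Classifier defaults**: SVM with RBF kernel, cost 1 and
  gamma = 1/(p * var(x)); 1-NN with Euclidean distance; CART with Gini
  impurity and the library's standard pruning; random forest with 100 trees.
  All stochastic learners draw from one recorded run seed.
* **Split arithmetic**: the five train fractions are applied per class with
  `round()`; a fraction that would empty either class's train or test side
  is an error.

## Known limitations

* The ExHOG construction implemented is the dense folded-histogram reading;
  the corner-point phrasing sometimes attached to this descriptor does not
  produce a fixed 648-length vector and is not implementable as stated.
* DICOM input is not supported in this build; PNG and TIFF patches (8- or
  16-bit) are. The manifest-driven I/O layer is format-agnostic beyond the
  reader.
* The decision tree is the weakest learner on the synthetic task --
  axis-aligned splits on highly correlated orientation histograms generalize
  poorly from the smallest (10%) train split, and its pooled accuracy on
  some singleton descriptors sits near the 85% sanity threshold. This is a
  property of the generator's difficulty, not of the harness.
* Timing columns report wall-clock seconds on the current machine and are
  not comparable across hardware.
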