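---
title: "Late fusion of multi-omic classifier probabilities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Late fusion of multi-omic classifier probabilities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model behind `latefuse`, the
parameters that matter and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical design decisions a
maintainer would want to know about.

## The fusion model

Let a sample have up to $M$ modalities, each with a trained classifier
emitting a probability vector over $C$ classes. The fusion layer is a
single parameter matrix $W \in \mathbb{R}^{C \times M}$; the fused score
of class $i$ is

$$ s_i \;=\; \sum_{j=1}^{M} w_{i,j}\, P_j(c_i), $$

with each row of $W$ constrained to the probability simplex by a row-wise
softmax of an unconstrained raw matrix. The prediction is
$\arg\max_i s_i$. Three properties follow:

- **Per-class weighting.** A modality strong at recognizing only one
  class can dominate that class's row while staying small elsewhere.
  Global accuracy-based weighting schemes cannot express this.
- **Missing modalities.** A modality absent for a sample is encoded as an
  exact all-zero probability row. Its term contributes $w_{i,j}\cdot 0 = 0$,
  so fused scores are bit-identical to a sum that omits the term. No
  imputation is performed and nothing is refit at prediction time. The
  price is that fused scores of incomplete samples are systematically
  smaller; since prediction is a per-sample argmax and weights within a
  class row are comparable across samples only through the argmax, this
  does not affect the decision, and fused scores are deliberately *not*
  renormalized (see below).
- **Row-stochastic weights.** The softmax keeps every row summing to 1
  with entries in $(0,1)$, so fused scores of fully observed samples stay
  in $[0,1]$ and per-row weights are interpretable as modality shares.

### Optimization

The raw matrix is initialized from a standard normal (its softmax rows
therefore sum to one from the start) and trained by minibatch Adam
($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$) on the
cross-entropy $-\log \max(s_{y}, 10^{-12})$ of the fused score of the true
class. A stratified 10% validation split is carved from the training
samples and fused accuracy on it is recorded after every epoch; the
weights returned are those of the best-validation epoch (disable with
`best_epoch = FALSE`).

Design choices that were genuinely open:

- **Softmax placement.** The projection can be read either as part of the
  differentiable forward pass or as a hard projection applied to the raw
  weights after each optimizer step. The default is the differentiable
  reading (`softmax_mode = "forward"`): a hard projection that overwrites
  the raw parameters after every Adam step changes the meaning of Adam's
  moment estimates, whereas the forward-pass softmax leaves the optimizer
  semantics intact. The projection reading is available via
  `softmax_mode = "projection"`; both keep the stored projected matrix
  row-stochastic after every step. The analytic gradient (including the
  softmax Jacobian) is verified against central finite differences in the
  test suite to $10^{-5}$.
- **Learning rate.** Default `lr = 0.1`. The fusion layer has only
  $C \times M$ parameters (15 in the five-modality case) and trains for 5
  epochs over at most a few hundred samples, i.e. on the order of $10^2$
  optimizer steps. Adam's updates are scale-normalized (each step moves a
  parameter by roughly `lr`), so a learning rate of $10^{-3}$ — a common
  default for deep networks trained for $10^4$–$10^6$ steps — would move
  the raw weights by less than 0.1 over an entire run and could never
  overcome the standard-normal initialization. At 0.1 the optimizer
  converges comfortably within the 5-epoch budget on all the package's
  test problems.
- **Best-epoch ties.** Validation accuracy on a 10% split is a coarse,
  frequently saturating metric; when several epochs tie, the weights with
  the lower training loss (the better-trained ones) are kept. Keeping the
  first tied epoch instead returns near-initialization weights whenever
  epoch 1 already validates perfectly.
- **No renormalization of fused scores.** The weighted sum is used as-is
  for both the argmax and the loss (after clamping at $10^{-12}$ inside
  the log). Renormalizing would change nothing for the argmax of fully
  observed samples but would silently rescale the loss of incomplete
  samples; leaving the sum raw keeps the missing-modality term-dropping
  equivalence exact.
- **Degenerate inputs.** A modality missing for *all* training samples
  leaves its raw column untouched by gradients; a warning is emitted and
  the returned weights for that column are arbitrary (their softmax share
  of an untrained column). Samples with every modality missing raise an
  explicit no-information error at prediction; ties in fused scores are
  broken by class order with a warning.

## Per-modality classifiers

Molecular modalities use an RBF-kernel SVM. Features are min-max scaled
to $[-1, 1]$ with parameters estimated on the training split only; test
values outside the training range map outside $[-1, 1]$ and are left
unclipped (clipping would discard the information that a value is
extreme). $(C, \gamma)$ are selected over the grid
$\{2^{-7}, 2^{-5}, 2^{-2}, 2, 2^{4}, 2^{7}\}$ (both axes) by 5-fold
stratified inner cross-validation on the training split, scored by
accuracy. One subtlety: the deployed output is the pairwise-coupling
probability vector (Wu–Lin–Weng coupling as implemented in libsvm via
`e1071`), and at very small `C` the Platt sigmoid calibration can
collapse to near-uniform probabilities while hard-label accuracy stays
top-tied. Accuracy near-ties (within 1 percentage point, at most 8
candidates) are therefore re-scored by inner-CV probability log-loss and
the best-calibrated pair wins. Constant features are scaled to zero with
a warning.

The slide pipeline cuts a slide into non-overlapping 512-pixel tiles
(row-major; partial edge tiles dropped — the grid convention must simply
be fixed, and dropping partial tiles avoids feeding the tile classifier
truncated inputs), discards tiles whose three channel means all exceed
220, and aggregates per-tile predictions into the tile-fraction
probability vector; the slide-level label is the majority vote, which
always equals the argmax of the tile fractions. The tile classifier
itself is a pluggable contract (`fit` on tiles and labels, `predict_tiles`
to classes). The default is a multinomial logistic regression on the
three per-tile channel means: deliberately lightweight, so the
tile-to-slide mathematics is exercised end-to-end in seconds. A
convolutional backend can be substituted behind the same contract without
touching the aggregation; results on real histology will obviously depend
on that backend, and nothing in this package's tests speaks to
convolutional performance.

## Feature screening

Three selection procedures cover the molecular preprocessing:

- `drop_missing_features()` removes every feature with at least one
  missing value, keeping all samples.
- `ttest_screen()` runs Welch's two-tailed two-sample t-test for each of
  the three pairwise class comparisons. Welch rather than Student because
  real per-modality class sizes are strongly unbalanced and
  equal-variance assumptions buy nothing. A feature is selected iff at
  least `required_comparisons` of the three comparisons are significant
  at `alpha` (default 0.001) *and* clear the mean-difference threshold in
  those same comparisons (3-of-3 and threshold 0.1 for copy-number-style
  screening; 2-of-3 and 0.4 for methylation-style). Bonferroni control
  (default on) uses the most conservative family: features × 3
  comparisons. Requiring the mean-difference condition on the
  significant comparisons themselves (rather than on any comparison) is
  the stricter of the two readings of "significant and with a large mean
  difference", and is the implemented one.
- `deg_filter()` is the classical differential-expression screen:
  maximum pairwise |log2 fold change| of class means ≥ 2, one-way
  (Welch) ANOVA p ≤ 0.05, coefficient of variation over all samples ≤ 2.
  The omnibus ANOVA is used because the screen is defined by a single
  p-value across three classes. Values must be positive; the error
  message suggests a pseudocount.
- `mrmr_rank()` implements greedy mRMR with the MID (difference)
  criterion — relevance is mutual information with the label, redundancy
  the mean mutual information with already-picked features — after
  equal-width 3-bin discretization. MID with coarse discretization is
  the canonical default; ties are broken by input feature order and the
  ranking is checked against a brute-force oracle in the tests.

## Cross-validation and metrics

`stratified_patientwise_kfold()` deals *patients* (never samples) into
folds round-robin within each class, so per-fold class counts deviate by
at most one patient and all of a patient's samples — a second slide, an
RNA aliquot — stay on one side of every split. All training-side
computation (scaling, grid search, probability fitting, feature
selection, fusion-weight optimization) happens inside each fold's
training split; the suite property-tests that permuting test labels
changes nothing trained.

Metrics: accuracy; per-class precision/recall/F1 with support-weighted F1
as the headline (it tracks accuracy closely on near-balanced problems)
and macro F1 alongside; one-vs-rest ROC AUC per class (via pROC) and
average precision (AUPRC, step-wise estimator), macro-averaged. A class
absent from the truth has undefined AUC: reported `NA`, excluded from the
macro average, warned about. Across-fold dispersion uses the sample
standard deviation ($n-1$).

Two evaluation regimes are first-class: `"common"` restricts a modality
subset to the samples all its members share (the regime for comparing
subsets on equal footing); `"all"` evaluates on every sample with at
least one member modality, zero-filling the missing rows (the regime that
exercises missing-data handling). `error_rate_reduction()` reports
$100\,(\mathrm{wrong}_{\mathrm{single}} - \mathrm{wrong}_{\mathrm{fusion}})/n$
rounded to one decimal.

## The synthetic cohort generator

`generate_cohort()` draws independent Gaussian features (within-class SD
1). A configurable fraction of features per modality (default 10%) is
informative; each informative feature shifts the mean of exactly one
class — assigned round-robin — by `effect_size` SDs. Missingness is
missing-completely-at-random per (patient, modality). The generator
records which features were planted, so selection procedures are scored
against ground truth. `generate_slide()` composes a tile grid with a
configured fraction of near-white background tiles (channel means
guaranteed above the 220 filter) and tissue tiles coloured around a
per-class RGB mean with Gaussian pixel noise.

What this emulates: class-conditional signal of controllable strength,
per-modality availability gaps, and the background/tissue composition of
tiled slides. What it does not: RNA-Seq count distributions, CNV segment
structure, beta-value bimodality, feature correlation, informative
missingness, histology texture. Tests passing on these cohorts therefore
validate the *machinery* — selection recovers planted signal, classifiers
reach the separability the geometry allows, fusion is never materially
worse than its best input and exploits complementary modalities — not
clinical performance on TCGA-like data.

Benchmark conditions used by the test suite and the acceptance script,
chosen once: five modalities with effect sizes 0.8, 1.1, 1.4, 1.7, 2.0
(a spread from weak to strong, mirroring the real-world spread between
modalities), 200 patients per class, 10% missingness per modality, 12
features per modality of which 25% are informative (three markers, one
per class, so every class has signal in every modality), 10-fold CV. The
worked examples in the README use a scaled-down three-modality version of
the same design.

## Known limitations

- The fusion layer is linear in the per-modality probabilities; it
  cannot model interactions between modalities' probability vectors.
- Weight identifiability: two modalities with identical probability
  tables make the weight split between them arbitrary (only their sum is
  identified); the optimizer's answer depends on initialization. Fused
  *predictions* are unaffected.
- The default tile classifier sees only mean colour; it is a stand-in
  for the contract, not a histology model.
- mRMR's 3-bin discretization is coarse for heavily skewed features;
  rank stability under alternative binnings is not asserted.
- Probability calibration quality is inherited from libsvm's Platt
  scaling; the grid-search tie-break mitigates but does not eliminate
  calibration pathologies at extreme hyperparameters.
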