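# latefuse

Gradient-optimized late fusion of multi-omic and histology classifiers for
cancer-subtype diagnosis.

## The problem

Distinguishing the subtypes of non-small-cell lung cancer (lung
adenocarcinoma, LUAD, vs. lung squamous cell carcinoma, LUSC, vs. healthy
control) matters clinically because the two subtypes are treated
differently. Several data modalities each support a usable classifier on
their own — RNA-Seq and miRNA-Seq expression, per-gene copy-number values
(CNV), CpG methylation beta values (metDNA), and tiled whole-slide
histology images (WSI) — but they carry complementary information, and no
patient has all screenings performed. `latefuse` trains an independent
probabilistic classifier per modality and learns how to combine their
class probabilities, so that predictions improve when modalities are added
and degrade gracefully when they are missing.

## The model

Each modality *j* emits a class-probability vector for a sample. For
molecular modalities this comes from an RBF-kernel SVM (grid-searched `C`
and `γ` over `{2⁻⁷, 2⁻⁵, 2⁻², 2, 2⁴, 2⁷}`, features min-max scaled to
[-1, 1] on the training split, pairwise-coupling probability estimates).
For a slide, tiles of 512 × 512 are extracted, near-white tiles (all three
channel means > 220) are discarded, a tile-level classifier labels each
tile, and the slide's probability for class *cᵢ* is the tile fraction

    P_WSI(x, cᵢ) = #TilesPredicted(x, cᵢ) / #SlideTiles(x).

The fusion layer is a single `classes × modalities` weight matrix
`W = (w_{i,j})`, kept row-stochastic by a row-wise softmax. The fused
score of class *cᵢ* is the weighted sum

    P_Fusion(cᵢ) = Σⱼ w_{i,j} · P_j(cᵢ),

and the prediction is its argmax. The weights are learned by minibatch
Adam on the cross-entropy of the fused scores, with a 10% validation split
monitored across 5 epochs. A modality missing for a sample enters as an
exact all-zero probability row, contributing nothing to the sum — no
imputation, no refitting.

Because each class row has its own weights, a modality that is good at
recognizing only one class can receive a large weight in that row and
small weights elsewhere — the advantage over global accuracy-based
weighting schemes.

The package also implements the surrounding pipeline: missing-value
removal, log2-fold-change/COV differential-expression filtering, pairwise
Welch t-test screening with Bonferroni control and mean-difference
thresholds, mRMR feature ranking, stratified patient-wise k-fold
cross-validation, modality-subset sweeps, and a synthetic multi-modal
cohort generator with planted ground truth for end-to-end testing.

## Worked example

A synthetic three-modality cohort (60 patients per class, modality effect
sizes 1.0 / 1.4 / 1.8 SD, 10% of patients missing each modality), with
5-fold stratified patient-wise cross-validation; the fusion is evaluated
on every sample with at least one modality:

```r
library(latefuse)

spec <- cohort_spec(
  60,
  modalities = c("RNA", "CNV", "metDNA"),
  n_features = 12,
  effect_size = c(1.0, 1.4, 1.8),
  missing_rate = 0.1,
  informative_fraction = 0.25,
  seed = 42
)
cohort <- generate_cohort(spec)
print(cohort)
#> <cohort> 180 patients (control=60, LUAD=60, LUSC=60); modalities: RNA[160 x 12], CNV[162 x 12], metDNA[161 x 12]

res <- run_fusion_cv(cohort, k = 5, seed = 42, regime = "all")
print(res$single, digits = 3)
#>   modality accuracy accuracy_sd f1_weighted f1_weighted_sd auc_macro auprc_macro
#> 1      RNA    0.622      0.0955       0.617         0.0957     0.780       0.676
#> 2      CNV    0.711      0.0677       0.706         0.0707     0.874       0.809
#> 3   metDNA    0.814      0.0820       0.809         0.0844     0.948       0.919
print(res$fusion, digits = 3)
#>           subset n_modalities accuracy accuracy_sd f1_weighted f1_weighted_sd auc_macro auprc_macro
#> 1 RNA+CNV+metDNA            3    0.839      0.0887       0.838         0.0896     0.924       0.903
```

The three modalities alone reach weighted F1 scores of 0.62–0.81 (their
planted effect sizes differ); fusing them lifts F1 to 0.84, above the best
single modality, while classifying *all* 180 patients — including those
missing the strongest modality. `subset_sweep()` produces the same table
for every modality subset, and `error_rate_reduction()` converts a pair of
misclassification counts into the percentage-point reduction a fusion
model achieves over a single-modality model.

A thin command-line wrapper with `synth`, `tile`, `fuse` and `evaluate`
subcommands is installed at `inst/cli/latefuse`.

## Package layout

- `R/synthetic-data.R` — cohort and slide generators with planted ground truth
- `R/omics-features.R` — missing-value removal, t-test screen, DEG filter, mRMR
- `R/wsi-pipeline.R` — tiling, background filter, tile-fraction aggregation
- `R/modality-models.R` — RBF-SVM per modality with grid search and scaling
- `R/late-fusion.R` — probability tables, softmax-projected weights, Adam optimizer
- `R/evaluation.R` — patient-wise CV, metrics, subset sweeps, error accounting
- `vignettes/late-fusion-methods.Rmd` — the methods account of the model,
  its parameters and its limitations
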