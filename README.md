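# cmms — cross-modality metabolic stability prediction

`cmms` predicts whether a small molecule is **metabolically stable** in
liver-microsome assays (binary label, 1 = stable) directly from its SMILES
string, and explains which functional groups drive the prediction. It is
aimed at computational chemists triaging compound series and at modellers
who want an interpretable, fully reproducible baseline for
structure–stability modelling in R.

## The model

Each molecule is encoded through two views that are fused before
classification:

* **Sequence view** — SMILES tokens → skip-gram embeddings
  (d₁ = 100) → bidirectional GRU (d₂ = 200) → multihead additive attention
  pooling → sequence representation *sᵢ* ∈ ℝ²⁵⁶. The attention weights per
  head are a softmax over positions (nonnegative, summing to 1), which later
  doubles as an explanation device.
* **Structure view** — heavy-atom graph with 84 binary atom features →
  two GIN layers, *h*ᵥ⁽ᵏ⁾ = MLP((1+ε⁽ᵏ⁾)·*h*ᵥ⁽ᵏ⁻¹⁾ + Σᵤ∈N(v) *h*ᵤ⁽ᵏ⁻¹⁾) →
  global max ⊕ mean pooling → structure representation *zᵢ* ∈ ℝ⁵¹².

The concatenation [*zᵢ*; *sᵢ*] ∈ ℝ⁷⁶⁸ feeds a fully connected predictor
(768 → 256 → 1, sigmoid score). Training minimizes

L = L_C + λ·L_CL,  λ = 0.1,

where L_C is the summed binary cross-entropy and L_CL a temperature-scaled
inter-view contrastive loss (τ = 0.2) that pulls each molecule's graph
representation toward that of a random-walk **substructure** of itself
(40% of its atoms) and away from the other 2Q−2 representations in the
minibatch. Optimization is Adam (lr 5·10⁻⁴); everything — initialization,
shuffling, augmentation, embedding pretraining — derives from one seed.

Two interpretability procedures are built in: attention-derived atom/bond
weights (a bond's weight is the mean of its atoms' weights), and
Monte-Carlo **edge Shapley values** (each bond's average marginal
contribution to the predicted score), aggregated into a frequency report of
high-impact substructures (Shapley threshold 0.2, top 10 per class).

All encoders, the contrastive loss and Adam are implemented in base R
matrix algebra with hand-derived backpropagation, verified against finite
differences in the test suite. SMILES canonicalization and ECFP
fingerprints go through ChemmineR/ChemmineOB (OpenBabel).

## Worked example

```r
library(cmms)
library(dplyr)

# a synthetic benchmark with planted functional groups (64/36 balance,
# 5% label noise); real data loads with read_molecules("file.csv")
d  <- synth_molecules(2000, noise = 0.05, seed = 1)
te <- withr::with_seed(1, sample.int(nrow(d), 400))

model <- cmms_fit(d[-te, ], cmms_config(epochs = 30, batch_size = 64,
                                        seed = 1))
preds <- predict(model, d[te, ])
evaluate_predictions(mutate(preds, label = d$label[te]))
#> # A tibble: 1 × 5
#>     auc accuracy    f1   mcc     n
#>   <dbl>    <dbl> <dbl> <dbl> <int>
#> 1 0.921    0.925 0.942 0.837   400
```

AUC/Accuracy/F1 close to their noise ceiling (5% of labels are flipped)
mean the model has recovered the planted structure–activity rule from
held-out molecules. Explanations point back at the planted groups:

```r
ex <- attention_explanation(model, "C1CCCCC1c1ccc(Cl)cc1")
ex
#> <cmms_explanation> C1CCCCC1c1ccc(Cl)cc1 (score 0.914)
#>   top atoms: Cl11 (0.21), C13 (0.10), C12 (0.10)

sh <- edge_shapley(model, "C1CCCCC1c1ccc(Cl)cc1", n_samples = 1000, seed = 1)
head(sh, 3)
#> # A tibble: 3 × 5
#>       u     v     phi       se n_samples
#>   <int> <int>   <dbl>    <dbl>     <int>
#> 1     1     2 0.00790 0.000502      1000
#> 2     2     3 0.0155  0.000427      1000
#> 3     3     4 0.0160  0.000424      1000
```

The attention mass concentrates on the chlorophenyl substituent (the
planted stabilizing group), and the per-bond Shapley values carry standard
errors from the permutation sampling. `group_frequency_report()` aggregates
such explanations over a whole evaluation set; `cmms_crossval()` and
`cmms_cluster_eval()` run stratified 10-fold and leave-one-structural-
cluster-out validation; `autoplot()` / `tidy()` / `glance()` work on fitted
models. A thin command-line wrapper lives at `inst/cli/cmms`
(`cmms synth | train | predict | crossval | cluster-eval | sweep-lambda |
explain`).

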