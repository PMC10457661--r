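---
title: "Cross-modality metabolic stability prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality metabolic stability prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Metabolic stability — how quickly a compound is degraded by liver enzymes —
is a central filter in early drug discovery. In the liver-microsome assays
that define the labels used here, a compound is *stable* (label 1) when its
half-life criterion is met, *unstable* (label 0) otherwise, and collections
derived from such assays are typically imbalanced at roughly 64% stable to
36% unstable. `cmms` predicts this binary outcome from the SMILES string
alone and, just as importantly, explains *which functional groups* drive the
prediction.

## The model

A molecule enters the model through two views that are fused before
classification.

**Sequence view.** The SMILES string is tokenized into atoms and structural
symbols (`tokenize_smiles()`); each token receives a pretrained embedding of
width $d_1 = 100$ from a skip-gram model with negative sampling trained on
tokenized SMILES (`train_atom_embeddings()`), so tokens appearing in similar
chemical contexts receive nearby vectors. Tokens missing from the vocabulary
receive a deterministic seeded fallback vector. A bidirectional GRU maps the
embedding sequence to hidden states $h_t \in \mathbb{R}^{d_2}$, $d_2 = 200$
(100 per direction): position $t$ concatenates the forward recurrence state
at $t$ with the backward recurrence state at $t$. Multihead additive
attention then scores every position,

$$\alpha = \mathrm{softmax}\big(w_2^\top \tanh(W_1 h_t + b_1)\big),$$

normalized over positions so each head's weights are nonnegative and sum
to 1; head contexts $\sum_t \alpha_t h_t$ are averaged and passed through a
fully connected layer with ReLU to give the sequence representation
$s_i \in \mathbb{R}^{256}$.

**Structure view.** The heavy-atom graph carries an 84-dimensional binary
feature per atom: element one-hot (50 slots, last = unknown), heavy degree
(0–10), attached hydrogens (0–10), implicit valence (0–10), and an
aromaticity flag. Two GIN layers update each atom as

$$h_v^{(k)} = \mathrm{MLP}\Big((1 + \epsilon^{(k)})\,h_v^{(k-1)} +
  \textstyle\sum_{u \in N(v)} h_u^{(k-1)}\Big),$$

with a linear → batch-norm → ReLU → linear MLP of width $d_g = 256$ and a
learnable $\epsilon^{(k)}$ initialized at 0. The molecule representation
$z_i \in \mathbb{R}^{512}$ concatenates global max-pooling and global
mean-pooling of the final node states.

**Contrastive regularizer.** During training, each molecule is paired with a
random-walk substructure covering $\lceil 0.4\,N \rceil$ atoms. Both views
pass through the *same* GIN, and a temperature-scaled contrastive loss
(NT-Xent, $\tau = 0.2$) over the $2Q$ stacked representations pulls each
molecule toward its subgraph and away from the other $2Q - 2$ batch rows:

$$\ell_i = -\log \frac{\exp(\mathrm{cos}(z_i, \hat z_i)/\tau)}
  {\sum_{k \neq i} \exp(\mathrm{cos}(z_i, z_k)/\tau)}, \qquad
  L_{CL} = \tfrac{1}{2Q}\sum_i \big[\ell(z_i, \hat z_i) +
  \ell(\hat z_i, z_i)\big].$$

Three comparison augmentations are available (`node_dropping` at ratio 0.2,
`edge_perturbation` and `attribute_masking` at 0.4).

**Predictor and loss.** $[z_i; s_i] \in \mathbb{R}^{768}$ feeds a fully
connected head (768 → 256 → 1); the score is the sigmoid of the logit. The
training objective is

$$L = L_C + \lambda\, L_{CL}, \qquad
  L_C = -\textstyle\sum_i y_i \log \sigma(\mathrm{logit}_i) +
  (1 - y_i)\log(1 - \sigma(\mathrm{logit}_i)),$$

a *sum* (not mean) over the minibatch, with $\lambda = 0.1$ by default.
Optimization is Adam at learning rate $5 \times 10^{-4}$; the reference
protocol is 200 epochs, and every piece of randomness (initialization,
shuffling, augmentation, embedding pretraining) derives from a single seed,
so a run is exactly reproducible.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `d1` | 100 | token-embedding width |
| `d2` | 200 | BiGRU output width (100 per direction) |
| `d_s`, `d_g` | 256, 256 | sequence / GIN widths; make the fused input 512 + 256 = 768 |
| `K` | 2 | GIN layers = receptive field in bonds |
| `heads` | 4 | attention heads, mean-aggregated |
| `d_att` | 64 | attention scoring width |
| `tau` | 0.2 | contrastive temperature |
| `ratio` | 0.4 | substructure size as a fraction of atoms |
| `lambda` | 0.1 | contrastive weight; `sweep_lambda()` covers the conventional grid 0.01–2 |
| `epochs`, `lr` | 200, 5e-4 | reference optimization protocol (Adam) |
| `batch_size` | 128 | also the number of in-batch negatives, so contrastive quality depends on it |

The number of attention heads, their aggregation (mean), the attention
scoring width, and the presence of a ReLU after the FCs layer are design
choices of this package — the architecture family fixes only the components,
not these details. The same holds for the exact composition of the 84
features (the five property families and the total are fixed; the block
sizes are ours) and for the ECFP setting used in similarity work (radius 2
as provided by the chemistry toolkit backend, 4096 bits).

## The synthetic benchmark

`synth_molecules()` generates molecules as *scaffold + planted motif* string
templates: scaffolds are alkane chains (2–6 carbons), cyclohexane, benzene
and pyridine; stabilizing motifs are acetylene, trifluoromethyl and
chlorophenyl; destabilizing motifs are ester, amide, methoxy and hydroxyl —
groups whose association with microsomal stability or lability is chemical
common knowledge. The clean label is 1 iff the motif is stabilizing; the
emitted label is flipped with probability `noise`; the motif's atom indices
are recorded as ground truth. Defaults mirror the shape of real
liver-microsome collections: 64% positives, a few thousand molecules.

What the generator does *not* emulate: real chemical diversity (it uses 4
scaffolds and 7 motifs), confounded or context-dependent structure–activity
relationships, multiple interacting groups per molecule, stereochemistry,
or assay noise structure beyond independent label flips. A passing recovery
test therefore shows that the pipeline can learn and explain a planted
structure–activity rule through realistic SMILES — not that it reaches any
particular accuracy on real assay data.

Study sizes used by the test suite and the acceptance script: the recovery
study trains on 1600 molecules (80% of n = 2000, 5% label noise) for 30
epochs at batch 64 and evaluates on the held-out 400; explanation recovery
uses up to 50 correctly classified held-out positives per seed; Shapley
checks use 500–1000 permutations. These sizes were chosen to exercise the
full pipeline at desk scale while keeping a complete run in minutes.

## Numerical and design choices

* **Recurrences.** The two GRU directions are independent parameter sets;
  one runs the sequence forward, one backward (the printed formulation is
  ambiguous about the arrows; this is the standard reading). Padded batch
  positions carry the hidden state through unchanged and are excluded from
  attention softmax by masking; batches are length-bucketed.
* **Logit vs score.** The predictor returns a logit; the sigmoid is applied
  inside the loss (`log1pexp` form), which keeps the loss finite for
  extreme logits. Scores reported to users are sigmoids, strictly inside
  (0, 1).
* **Batch norm.** Training mode uses batch statistics (and updates running
  means/variances with momentum 0.1, eps 1e-5); evaluation always uses
  running statistics, so single-molecule prediction is well defined. The
  first GIN linear has no bias (batch norm absorbs it). Originals and their
  augmented views are encoded in one block-diagonal batch, so both views
  are normalized with the same statistics.
* **Contrastive denominators** run over the other $2Q - 1$ rows exactly as
  the index set $k \neq i$ states, the positive included. The cosine is
  computed on unnormalized pooled vectors ($z_i$ doubles as the predictor
  input; no projection head by default). Zero-norm rows are an error.
* **Substructure sampler** is a seeded random walk (restarting inside the
  start component at dead ends, frontier-completed if the walk stalls), so
  the subgraph is connected, exactly $\lceil k N \rceil$ atoms whenever the
  component allows, with features copied unchanged.
* **Optimizer.** Adam with bias correction, β = (0.9, 0.999), eps 1e-8.
  All gradients are hand-derived and verified against central finite
  differences (relative error ≤ 1e-4 at every checked coordinate, typically
  ≤ 1e-7) in the test suite.
* **Attention-to-atom mapping.** Attention lives on tokens; non-atom tokens
  (ring digits, bonds, branches) get zero atom mass and the remaining
  weights are renormalized over atom tokens. Bond weight = mean of its two
  atom weights.
* **Edge Shapley.** Permutation sampling with the incremental-coalition
  trick: one random edge ordering yields a marginal for every edge from
  |E| + 1 nested coalition evaluations, batched into a single GIN pass.
  The per-permutation telescoping sum makes the efficiency identity
  $\sum_e \phi_e = f(G) - f(\emptyset)$ hold exactly for the estimates.
  Edges outside the coalition are deleted from the adjacency; node features
  and the sequence branch are untouched. The value function is the sigmoid
  score, not the logit.
* **Frequency report.** A critical bond (φ > 0.2) plus its neighbor bonds
  defines a substructure instance. Instances are keyed by a deterministic
  sorted multiset of typed bonds rather than a canonical fragment SMILES:
  bond-induced fragments of aromatic systems are not valid molecules, so a
  canonical SMILES writer cannot key them reliably. A small built-in
  matcher names fragments (trifluoromethyl, amide, hydroxyl, …) for
  reporting only.
* **Ties and degenerate inputs.** Max-pooling breaks ties by first index;
  AUC uses the rank statistic with half credit for ties; MCC is defined as
  0 when a confusion-matrix margin is empty; single-class training sets and
  evaluation sets are errors, as is clustering-fold evaluation on a
  single-class cluster (skipped with a warning).
* **Dedupe.** Canonical SMILES (OpenBabel) decide duplication; the first
  occurrence wins; unparseable rows are dropped and counted, and the counts
  travel with the data as a report.

## Limitations

* The synthetic benchmark is deliberately simple; performance numbers on it
  do not transfer to real assay collections.
* The SMILES parser covers the organic subset, bracket atoms, charges, ring
  closures (including `%nn`) and branches, but not reactions, wildcard
  atoms, or polymer notation; stereo markers are accepted and ignored.
* Embeddings are pretrained and then frozen during supervised training;
  fine-tuning them is not implemented.
* Training is CPU-bound R matrix algebra: fine for thousands of molecules,
  not for hundred-thousand-molecule corpora.
* The functional-group namer is heuristic and used only to label report
  rows; the signature key, not the name, defines the counting.
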