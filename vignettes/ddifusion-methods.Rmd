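---
title: "Multimodal DDI type classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal DDI type classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Co-administered drugs can change each other's pharmacokinetics or
pharmacodynamics.  Interaction knowledge bases describe these events with
directional sentence templates ("the serum concentration of drug B can be
increased when combined with drug A"), which turns interaction prediction
into multiclass classification over *ordered* drug pairs: the pair (A, B)
and the pair (B, A) are different records that may carry different
labels.  `ddifusion` implements a classifier for this task that fuses
three per-drug views:

* **SSP — structural similarity profile.**  Each drug's SMILES is
  canonicalized and hashed into an extended-connectivity fingerprint
  (ECFP4 by default, i.e. circular substructures of radius 2 folded into
  a 2048-bit binary space).  A drug's raw profile is the vector of its
  Tanimoto similarities $|A \cap B| / |A \cup B|$ to every drug in the
  collection; the drug-by-drug similarity matrix is then compressed by
  PCA (200 components by default).
* **PSP — protein similarity profile.**  Drugs act through their carrier,
  transporter, enzyme and target (CTET) proteins.  Starting from a
  uniform seed distribution over a drug's CTET proteins, a random walk
  with restart (RWR) on a weighted protein–protein interaction network,
  $p \leftarrow (1-r)\,W p + r\,p_0$, yields a stationary diffusion
  profile over all network proteins that captures indirect pathway
  proximity: two drugs whose protein sets never overlap can still diffuse
  into the same network neighborhood.  The drug-by-drug cosine-similarity
  matrix of these diffusion profiles is PCA-compressed (300 components by
  default).
* **Text embedding.**  Each drug's name and free-text description are
  turned into one fixed 768-dimensional vector through a pluggable
  provider.  The preparation rule is deliberate: if the name already
  occurs in the description, the description is used as provided,
  otherwise the name is prepended — so the name is always in the encoded
  text.  Inputs longer than the provider's 512-token limit are truncated
  and flagged rather than dropped.

For an ordered pair, the selected per-drug vectors are concatenated (all
of drug A's modalities, then all of drug B's) and classified by a
multilayer perceptron.  Its first, optional block is a **projection
layer**: a learnable square linear map with the same input and output
width as the concatenated feature.  Heterogeneous modalities arrive on
very different scales and correlation structures; the projection re-weights
and mixes dimensions into a joint space *before* the compressing hidden
layer.  ReLU and dropout follow the projection and the hidden layer.  No
input standardization is applied by default — scale alignment is exactly
what the projection is for (a z-scoring option exists for comparison).

## Embedding backends

The package ships a deterministic **mock provider** as its embedding
backend.  It embeds a text as $(1-\eta)\,e_k + \eta\,u$, where $e_k$ is
the basis direction assigned to the first matched keyword and $u$ is
unit-norm pseudo-random noise derived from a stable hash of the text (no
global RNG state is disturbed).  At the default $\eta = 0.1$, texts
sharing a keyword have cosine similarity above 0.9, and texts with
different keywords are nearly orthogonal — the geometry a real text
encoder produces for strongly clustered corpora, in idealized form.  A
pretrained transformer backend is *not* bundled; any object of class
`ddi_embedding_provider` producing finite length-768 vectors can be
plugged into `embed_texts()` and the rest of the pipeline is unchanged.
Results obtained with the mock therefore validate the pipeline's
mechanics and the fusion model's behavior, not the linguistic quality of
any particular encoder.

## Training schedule

Training follows a two-stage schedule.  Stage 1 trains from scratch with
minibatch Adam (batch 256, learning rate 1e-3) and cross-entropy loss for
up to 300 epochs; early stopping watches validation accuracy with
patience 20 but is only allowed to trigger from epoch 200 on, and the
best-validation checkpoint is kept.  Stage 2 resumes from that checkpoint
for up to 100 epochs with plateau decay: whenever validation accuracy
fails to improve for 5 consecutive epochs the learning rate is multiplied
by 0.1, floored at 1e-6.  The plateau scheduler's baseline is the
checkpoint's validation accuracy — a stage that never improves on its
checkpoint therefore decays at epochs 5, 10, ... exactly.  Test metrics
are reported from the fine-tuning stage's best validation checkpoint.

Splits are stratified per class at 0.64/0.16/0.20 using largest-remainder
apportionment, so every class's test fraction is within 1/class-size of
20%; the within-class shuffle is seeded and bit-reproducible.  Classes
with fewer than `min_count = 5` pairs are removed beforehand (5 is the
smallest count that can populate all three partitions) and survivors are
re-indexed contiguously, retaining the original ids.

Determinism: given one seed, weight initialization, batch order, dropout
masks, splits and the synthetic generator are all reproducible
bit-for-bit on a single machine.  Across different BLAS builds or
hardware, reproducibility is statistical rather than bitwise.

## Evaluation

`compute_metrics()` reports accuracy, macro-averaged precision/recall/F1,
and one-vs-rest AUROC and AUPR macro-averaged over classes with at least
one test positive.  AUROC uses the Mann–Whitney formulation with ties
counted 1/2; AUPR is step-wise precision–recall integration (average
precision) without interpolation.  Classes absent from the test set are
excluded from macro averages with a warning rather than imputed — their
one-vs-rest curves are undefined.  Argmax ties resolve to the lowest
class id for determinism.  `misclassification_table()` reproduces the
error-analysis view: per class, its test share and its share of *all*
misclassified samples (summing to 100% whenever errors exist), ranked;
`error_heatmap()` normalizes the top-k block of the confusion matrix by
the total error count with the diagonal masked.

## The synthetic benchmark

Real interaction corpora are licensed and large; the generator creates
datasets with the statistical structure the pipeline assumes, at desk
scale.  Drugs belong to latent clusters.  Each cluster is tied to a
hard-coded scaffold family (substituted benzenes, alkanes, naphthalenes,
pyridines, ...) — enumerated decorations of a valid base scaffold, so
every SMILES parses and within-cluster Tanimoto similarity clearly
exceeds between-cluster.  The PPI network is modular (one dense,
internally ringed module per cluster, high-confidence scores, plus a few
bridges and sub-threshold cross edges), and a drug's CTET set is drawn
from its cluster's module.  Descriptions are templated sentences carrying
the drug's name and its cluster keyword, which the mock provider maps to
a basis direction.  Ordered pair labels are an injective map from ordered
cluster pairs to class ids, after which a `label_noise` fraction (5% by
default) is flipped uniformly — so 1 − noise is, up to rare coincidental
flips, the accuracy ceiling.

Per modality, an informativeness parameter $q$ controls how faithfully
the modality reflects a drug's cluster: with probability $1-q$ the
modality "sees" a *confusable partner* cluster instead, and each modality
pairs up different clusters (structure confuses (1,2) and (3,4); text
confuses (1,3) and (2,4); proteins confuse (1,4) and (2,3)).  This was a
deliberate design choice over independent uniform corruption: modalities
err in *different* directions, the way chemically similar drugs can have
dissimilar descriptions and vice versa.  Consequently each modality alone
leaves a residual ambiguity of order $1-q$ per drug, while two modalities
together disambiguate almost perfectly — giving ablation experiments a
real, mechanistically interpretable fusion gain to detect rather than a
statistical artifact.

What the generator does *not* emulate: realistic pharmacology, imbalanced
long-tailed class distributions, shared substructures across families,
correlated label noise, or the lexical variety of curated descriptions.
Passing tests demonstrate that the pipeline's machinery (featurization,
diffusion, fusion, training, evaluation) behaves as specified, not that
any particular accuracy will transfer to licensed interaction corpora.

## Problem sizes and numerical choices

The reference benchmark is the generator default: 60 drugs, 4 clusters,
120 proteins, 8 classes, up to 400 ordered pairs per class (about 1,770
pairs), 5% label noise, informativeness 0.9 per modality.  At this scale
the package's tests and scripts use a desk-scale schedule — 40 stage-1
and 10 stage-2 epochs — which plateaus well before its end on this easy,
well-separated problem; the paper-scale defaults (300/100, early stopping
from 200) remain the configuration defaults.  Ablation experiments use a
smaller harness (60 pairs per class, informativeness 0.7 on the two
modalities under test, hidden width 256, 30/5 epochs, 3 seeds), sized so
a full modality-combination sweep runs in minutes on one core.

Other numerical choices:

* RWR: restart 0.5, L1 tolerance 1e-6, at most 1000 iterations —
  standard network-propagation settings; the iterate matches the dense
  closed-form solve to well below the tolerance.  Mass reaching dangling
  (isolated) nodes restarts at the seed, so scores always sum to 1.
* PPI loading: STRING-style scores kept as weights (evidence should
  weight the walk), minimum confidence 700, duplicate pairs collapsed to
  their maximum score, self-loops removed.
* Fingerprints: 2048-bit folding of the backend's native 4096-bit ECFP
  space; radius 2 by default (radius 3 available; resolution differences
  are minor for profile construction).  A 0/0 Tanimoto (two empty
  fingerprints) is defined as 0 with a warning: empty fingerprints carry
  no evidence of similarity.
* PCA: fit on the full drug collection by default, matching the
  transductive way similarity profiles are defined over all drugs;
  `fit_rows` provides the leakage-safe train-only fit.  Reductions
  retaining less than 95% variance are flagged, not rejected.  Embeddings
  are used at native width by default — compressing them has been
  observed to cost accuracy — though `emb_pca_k` exists.
* PSP definition: cosine-similarity-profile-then-PCA was chosen over
  using raw diffusion vectors, mirroring the SSP construction; the raw
  variant is available via `build_psp(..., method = "raw")`.

## Known limitations

* The fingerprint backend folds to at most 4096 bits; wider bit spaces
  are not supported.
* Pure-R training is practical up to a few thousand pairs and input
  widths in the low thousands; the projection layer's cost is quadratic
  in the concatenated width.
* No cold-drug (drug-disjoint) split is provided; the split stratifies
  by pair, so drugs recur across partitions.  Accuracy under a
  drug-disjoint protocol would be substantially lower.
* Blanket symmetrization of pairs (`augment_symmetric()`) is off by
  default and only sound for classes known to be symmetric.
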