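# ddifusion

Multimodal classification of drug–drug interaction (DDI) types in R.

Co-administered drugs can alter each other's pharmacokinetics or
pharmacodynamics, and interaction knowledge bases describe such events
with directional sentence templates ("the serum concentration of drug B
can be increased when combined with drug A").  `ddifusion` treats this as
multiclass classification over **ordered** drug pairs and fuses three
per-drug modalities:

* **SSP** — structural similarity profile: canonicalized SMILES →
  extended-connectivity fingerprints (ECFP4/ECFP6) → pairwise Tanimoto
  matrix `|A∩B|/|A∪B|` → PCA-reduced per-drug profile (200 components by
  default);
* **PSP** — protein similarity profile: a weighted protein–protein
  interaction network, random walk with restart
  `p ← (1−r)·W·p + r·p₀` seeded at each drug's carrier / transporter /
  enzyme / target (CTET) proteins, cosine similarity between diffusion
  profiles, PCA-reduced (300 components by default);
* **text embeddings** — fixed 768-dimensional vectors from drug names and
  descriptions through a pluggable provider (a deterministic mock backend
  ships with the package; any encoder producing 768-vectors plugs in).

Per ordered pair, drug A's and drug B's features are concatenated and
classified by a multilayer perceptron whose first (optional) block is a
**projection layer** — a learnable square linear map that re-weights and
aligns the heterogeneous modalities before compression.  Training runs in
two stages: minibatch Adam from scratch with late-activating early
stopping, then fine-tuning with plateau learning-rate decay
(factor 0.1, patience 5, floor 1e-6) from the best validation checkpoint.
Evaluation reports accuracy, macro precision/recall/F1, one-vs-rest macro
AUROC/AUPR, and misclassification analyses (ranked per-class error shares
and a normalized error heatmap).

A synthetic benchmark generator makes the whole pipeline runnable and
testable without downloads: clustered scaffold-family SMILES, a modular
PPI network, cluster-linked protein associations, keyword-bearing
templated descriptions, and pair labels that are a deterministic function
of the two drugs' latent clusters plus label noise.  See the methods
vignette (`vignettes/ddifusion-methods.Rmd`) for the models, parameters
and design decisions.

## Worked example

```r
library(ddifusion)

# a small synthetic benchmark: 30 drugs in 3 clusters, 4 pair classes
cfg <- synthetic_config(n_drugs = 30, n_proteins = 60, n_clusters = 3,
                        n_classes = 4, pairs_per_class = 30,
                        label_noise = 0, seed = 7)
ds <- generate_synthetic(cfg)

# featurize, split 0.64/0.16/0.20, train both stages, evaluate
ex <- run_experiment(ds, modalities = c("ssp", "emb"), seed = 1,
                     config_overrides = list(max_epochs_stage1 = 15,
                                             max_epochs_stage2 = 5,
                                             hidden_dim = 64))
print(ex)
#> fusion experiment [ssp+emb, projection]:
#>   accuracy 1.0000 | macro P 1.0000 R 1.0000 F1 1.0000 | macro AUROC 1.0000 AUPR 1.0000  (n = 24, 4 classes)
```

The printed line is the test-partition performance of the fine-tuning
stage's best validation checkpoint: overall accuracy, unweighted
(macro) per-class precision/recall/F1, and one-vs-rest AUROC/AUPR
averaged over the classes present in the 24 held-out pairs.  On this
noise-free, well-separated toy problem the planted cluster-pair labels
are recovered perfectly; with the default 5% label noise the accuracy
ceiling drops to ≈ 0.95 accordingly.

Ablation and projection comparisons follow the same pattern:

```r
run_ablation(ds, combos = list("ssp", "emb", c("ssp", "emb")), seeds = 1:3)
compare_projection(degrade(ds, "text", "scale", factor = 100))
```

A thin command-line front end wraps the same functions
(`inst/cli/ddifusion.R`): `simulate`, `featurize-ssp`, `featurize-psp`,
`embed`, `split`, `train`.

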