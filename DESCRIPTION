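Package: ddifusion
Title: Multimodal Drug-Drug Interaction Type Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Classifies ordered drug pairs into directional drug-drug
    interaction (DDI) types by fusing three per-drug modalities: structural
    similarity profiles (SSP) built from extended-connectivity fingerprints
    and Tanimoto similarity, protein similarity profiles (PSP) built by
    random walk with restart over a protein-protein interaction network
    seeded at each drug's carrier/transporter/enzyme/target proteins, and
    fixed-length text embeddings of drug descriptions.  Per-drug features
    are concatenated per ordered pair and classified with a multilayer
    perceptron that optionally applies a learnable square projection layer
    before compression.  Includes class filtering, stratified splitting, a
    two-stage training schedule with plateau learning-rate decay,
    macro-averaged multiclass evaluation with misclassification analysis,
    an ablation harness over modality combinations, and a synthetic data
    generator so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ChemmineOB,
    data.table,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    optparse,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
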