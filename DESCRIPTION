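Package: synergraph
Title: Sub-Hypergraph Attention Networks for Dose-Level Drug-Combination
    Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts dose-level drug-combination synergy from gene-set
    hypergraphs, k-mer SMILES hypergraphs and dose-injected subject
    features using an attention-based sub-hypergraph neural network with
    a feed-forward synergy head. Includes readers for GMT gene sets,
    expression matrices and dose-level combination-response tables, the
    sample-curation rules that turn raw dose-level records into binary
    synergy labels, single-sample gene-set enrichment (ssGSEA)
    featurization, grouped cross-validation with per-triplet and IC50
    dose-quadrant evaluation, attention-weight interpretation via
    Mann-Whitney tests with Benjamini-Hochberg correction, and a
    synthetic-data generator with a planted dose-dependent synergy
    signal for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
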