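# synergraph

Dose-level drug-combination synergy prediction with sub-hypergraph
attention networks, in R.

Combination screens in oncology test drug pairs on cancer cell lines
across a grid of concentrations and score each well for synergy
(BLISS, HSA/I, LOEWE, ZIP). Most predictive models average those scores
over the grid and predict one label per (drug A, drug B, cell line)
triplet — useless for the clinical question of *which doses* act
synergistically. `synergraph` is for computational pharmacologists who
want per-dose-combination predictions plus an interpretable readout of
which gene sets drive them.

## The model

Biological structure enters as two incidence hypergraphs
H ∈ {0,1}^|V|×|E|: a gene-set hypergraph (nodes = TF-target or pathway
gene sets, hyperedges = genes) and a heterogeneous drug hypergraph
(hyperedges = drugs; nodes = k-mer SMILES substrings and overlapping
gene sets). Node and hyperedge states evolve by dual attention: for an
incident pair (g, p),

    s(p,g) = tanh(W [h_V(g); h_E(p)]),     z(p,g) = cᵀ s(p,g)
    a_E(p,g) = softmax_{g∈p} z(p,g)        h_E(p) ← ReLU(Σ_g a_E h_V(g))
    a_V(g,p) = softmax_{p∋g} z(p,g)        h_V(g) ← ReLU(Σ_p a_V h_E(p))

A subject — one (drug A, drug B, cell, dose A, dose B) measurement —
carries feature rows F: dose-scaled ssGSEA enrichment over gene-set
nodes, and per-drug dose injection over drug nodes. Subgraph attention
scores node i as F_ji · (bᵀ h_V(i)), softmaxes over the subject's
support, and pools a subject embedding. Cell embedding, drug-pair
embedding and one-hot covariates (doses, tissue, gender, age) feed a
batch-normalised two-layer ELU network trained with
binary cross-entropy on labels binarized from LOEWE (> 10 synergistic,
< −10 antagonistic), under triplet-grouped 10-fold cross-validation.

The forward and analytic backward passes are implemented directly in
vectorised R and verified against finite differences and brute-force
oracles in the test suite.

## Worked example

```r
library(synergraph)

## curation: the five-record worked fixture exercises every rule
fx <- workedPipelineFixture()
res <- curateSamples(fx$records, fx$drugs)
res$report
#> Curation report
#>   stage counts:
#>     input                        5
#>     after_drug_unification       5
#>     after_replicate_averaging    5
#>     after_noncancer_filter       5
#>     after_additive_filter        4
#>     after_noninhibitory_filter   3
#>     after_label_binarization     2
#>   exclusions by rule:
#>     replicate_collapsed          0
#>     non_cancer                   0
#>     additive                     1
#>     non_inhibitory               1
#>     loewe_indeterminate          1
```

Five raw records become two labelled samples: one removed as additive
(all four scores inside [−10, 10]), one as non-inhibitory (full synergy
agreement but negative inhibition), one as LOEWE-indeterminate.

```r
## end-to-end on a synthetic screen with a planted dose-dependent signal
bm <- syntheticBenchmark(spec = syntheticSpec(seed = 1))
#> held-out AUROC 1.000, AUPRC 1.000 (n = 321)
#> per-triplet AUROC 1.000 over 27 triplets (constant baseline 0.5)

bm$data$truth$causalSets
#> [1] "SET05" "SET06" "SET07"
head(bm$report[, c("node", "U", "p_adj", "direction")], 4)
#>    node     U        p_adj direction
#> 1 SET17 10679 1.248325e-07   synergy
#> 2 SET06 10326 2.371362e-06   synergy
#> 3 SET23 10251 3.255041e-06   synergy
#> 4 SET07  9973 3.043035e-05   synergy
```

The benchmark generates a 12-drug × 10-cell-line screen on a 4×4 dose
grid, curates it, builds enrichment and hypergraph features, trains the
attention model on triplet-grouped folds and evaluates held out. The
differential attention-weight report ranks two of the three planted
causal gene sets (`SET06`, `SET07`) among its top four nodes at FDR
well below 0.05.

A command-line wrapper with `synth` / `curate` / `featurize` / `train`
/ `evaluate` / `explain` subcommands ships in
`inst/scripts/synergraph-cli.R`.

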