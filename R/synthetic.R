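#' Specification for synthetic toy datasets
#'
#' Describes the shape and signal of a generated dataset: counts of
#' genes, gene sets, cell lines and drugs, the per-drug dose grid, the
#' k-mer size the drug hypergraph will use, the designated causal gene
#' sets, and the planted-signal parameters. The defaults emulate a
#' small dose-level combination screen (every drug pair, a handful of
#' cell lines each, a 4x4 dose grid) with a dose-dependent synergy
#' signal carried by the causal sets.
#'
#' The planted synergy logit for a record is
#' `effectSize * meanNES(causal, cell) * (doseA + doseB - dosePivot)`
#' plus Gaussian noise, so low-dose corners of a dose-response matrix
#' lean antagonistic and high-dose corners synergistic (or vice versa in
#' cell lines where the causal enrichment is negative), giving each
#' triplet a mix of labels. LOEWE is emitted as `10 * logit`, so the
#' +/-10 label thresholds correspond to `|logit| = 1`; the other three
#' scores are correlated copies. Configurable fractions of records are
#' overwritten as additive or non-inhibitory to exercise the curation
#' filters.
#'
#' @param nGenes,nSets,nCells,nDrugs dataset dimensions.
#' @param doseGrid tested concentrations per drug (raw scale).
#' @param kmer k-mer size for drug-structure tokens.
#' @param nCausal number of causal gene sets.
#' @param effectSize logit shift per unit of dose-weighted causal NES.
#' @param noiseSd standard deviation of the logit noise.
#' @param dosePivot centre of the dose effect on the dose-sum scale;
#'   `NULL` uses the midpoint of the tested range.
#' @param additiveFrac,noninhibFrac fractions of records overwritten as
#'   additive / non-inhibitory artefacts.
#' @param cellsPerPair cell lines screened per drug pair.
#' @param seed seed fixing all draws.
#' @return a `syntheticSpec` list.
#' @export
syntheticSpec <- function(nGenes = 120, nSets = 30, nCells = 10, nDrugs = 12,
                          doseGrid = c(0.25, 0.5, 1, 2), kmer = 3,
                          nCausal = 3, effectSize = 25, noiseSd = 0.3,
                          dosePivot = NULL, additiveFrac = 0.08,
                          noninhibFrac = 0.04, cellsPerPair = 4, seed = 1) {
  stopifnot(nGenes > 10, nSets >= 6, nCells >= 2, nDrugs >= 3,
            all(doseGrid > 0), nCausal >= 1, nCausal <= nSets,
            additiveFrac >= 0, noninhibFrac >= 0,
            additiveFrac + noninhibFrac < 1)
  structure(list(nGenes = nGenes, nSets = nSets, nCells = nCells,
                 nDrugs = nDrugs, doseGrid = sort(doseGrid), kmer = kmer,
                 nCausal = nCausal, effectSize = effectSize,
                 noiseSd = noiseSd, dosePivot = dosePivot,
                 additiveFrac = additiveFrac, noninhibFrac = noninhibFrac,
                 cellsPerPair = cellsPerPair, seed = seed),
            class = "syntheticSpec")
}

#' Generate a synthetic dose-level combination screen
#'
#' Draws gene sets whose sizes span the size-filter boundary, log-normal
#' expression with causal-set enrichment varying by cell line, random
#' SMILES-like strings over a fixed alphabet, an IC50 table, cell-line
#' phenotypes, and dose-level synergy records carrying the planted
#' signal described in [syntheticSpec()]. All outputs pass the package's
#' format validators, and identical seeds give identical outputs.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `geneSets` ([GeneSetCollection-class]),
#'   `expression`, `drugs`, `records`, `ic50`, `cellMeta`, and `truth`
#'   (causal sets, per-record noise-free logits, planted artefact rows,
#'   per-cell mean causal NES).
#' @export
generateSynthetic <- function(spec) {
  stopifnot(inherits(spec, "syntheticSpec"))
  withSeed(spec$seed, {
    genes <- sprintf("GENE%03d", seq_len(spec$nGenes))
    cells <- sprintf("CL%02d", seq_len(spec$nCells))
    setNms <- sprintf("SET%02d", seq_len(spec$nSets))

    ## sizes: mid-sized bulk plus planted outliers on both sides of the
    ## one-SD retention interval
    sizes <- sample(8:16, spec$nSets, replace = TRUE)
    sizes[1:2] <- 3
    sizes[3:4] <- max(20, floor(spec$nGenes / 2))
    mid <- which(sizes >= 8 & sizes <= 16)
    causalIdx <- mid[seq_len(spec$nCausal)]
    ## causal sets draw from a reserved gene block so the planted signal
    ## is attributable to them and not diluted across overlapping sets
    nPool <- min(3 * max(sizes[causalIdx]), floor(spec$nGenes / 3))
    causalPool <- genes[seq_len(nPool)]
    otherPool <- genes[-seq_len(nPool)]
    sets <- lapply(seq_len(spec$nSets), function(k)
      if (k %in% causalIdx) sample(causalPool, sizes[k])
      else sample(otherPool, sizes[k]))
    names(sets) <- setNms
    gsc <- GeneSetCollection(sets)
    causal <- setNms[causalIdx]

    ## expression: log2(TPM+1)-like, with causal-set genes shifted per
    ## cell line so causal enrichment varies in sign across cells
    expr <- matrix(log2(stats::rlnorm(spec$nGenes * spec$nCells, 2, 1) + 1),
                   spec$nGenes, spec$nCells,
                   dimnames = list(genes, cells))
    delta <- rnorm(spec$nCells, 0, 2)
    causalGenes <- unique(unlist(geneSets(gsc)[causal], use.names = FALSE))
    expr[causalGenes, ] <- expr[causalGenes, ] +
      matrix(delta, length(causalGenes), spec$nCells, byrow = TRUE)

    drugNms <- sprintf("DRUG%02d", seq_len(spec$nDrugs))
    alphabet <- c("C", "c", "O", "N", "1", "(", ")")
    smiles <- vapply(drugNms, function(d)
      paste(sample(alphabet, sample(12:40, 1), replace = TRUE),
            collapse = ""), character(1))
    drugs <- data.frame(name = drugNms, smiles = unname(smiles),
                        stringsAsFactors = FALSE)
    drugs$genes <- lapply(drugNms, function(d)
      sample(genes, sample(0:5, 1)))

    ic50 <- expand.grid(drug = drugNms, cell = cells,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ic50$ic50 <- runif(nrow(ic50), min(spec$doseGrid) * 1.5,
                       max(spec$doseGrid) * 0.9)

    cellMeta <- data.frame(cell = cells,
                           tissue = sample(c("lung", "breast", "colon",
                                             "skin"), spec$nCells, TRUE),
                           gender = sample(c("F", "M"), spec$nCells, TRUE),
                           age = sample(30:79, spec$nCells, TRUE),
                           stringsAsFactors = FALSE)

    ## planted signal driven by the post-filter enrichment landscape
    gscF <- filterGeneSets(gsc)
    nes <- suppressWarnings(ssgsea(expr, gscF))
    meanCausal <- rowMeans(nes[, causal, drop = FALSE])

    pairs <- utils::combn(drugNms, 2)
    grid <- expand.grid(dose_a = spec$doseGrid, dose_b = spec$doseGrid,
                        KEEP.OUT.ATTRS = FALSE)
    pivot <- spec$dosePivot %||% mean(range(grid$dose_a + grid$dose_b))

    rows <- list()
    for (k in seq_len(ncol(pairs))) {
      cl <- sample(cells, min(spec$cellsPerPair, length(cells)))
      for (cc in cl) {
        r <- grid
        r$drug_a <- pairs[1, k]; r$drug_b <- pairs[2, k]; r$cell <- cc
        rows[[length(rows) + 1L]] <- r
      }
    }
    rec <- do.call(rbind, rows)
    total <- rec$dose_a + rec$dose_b
    trueLogit <- spec$effectSize * meanCausal[rec$cell] * (total - pivot)
    logit <- trueLogit + rnorm(nrow(rec), 0, spec$noiseSd)
    rec$loewe <- 10 * logit
    rec$bliss <- rec$loewe + rnorm(nrow(rec), 0, 2)
    rec$hsa <- rec$loewe + rnorm(nrow(rec), 0, 2)
    rec$zip <- rec$loewe + rnorm(nrow(rec), 0, 2)
    rec$inhibition <- 25 * total / max(total) + rnorm(nrow(rec), 0, 5)
    rec$study <- "synthetic"

    nArt <- floor(nrow(rec) * c(spec$additiveFrac, spec$noninhibFrac))
    art <- sample(nrow(rec), sum(nArt))
    addIdx <- art[seq_len(nArt[1])]
    ninIdx <- setdiff(art, addIdx)
    for (col in scoreColumns())
      rec[[col]][addIdx] <- runif(length(addIdx), -8, 8)
    for (col in scoreColumns())
      rec[[col]][ninIdx] <- runif(length(ninIdx), 12, 25)
    rec$inhibition[ninIdx] <- runif(length(ninIdx), -10, -1)

    rec <- rec[, c("drug_a", "drug_b", "cell", "dose_a", "dose_b",
                   "inhibition", scoreColumns(), "study")]
    rownames(rec) <- NULL

    list(geneSets = gsc, expression = expr, drugs = drugs, records = rec,
         ic50 = ic50, cellMeta = cellMeta,
         truth = list(causalSets = causal, trueLogit = unname(trueLogit),
                      plantedAdditive = addIdx, plantedNonInhibitory = ninIdx,
                      meanCausalNES = meanCausal, dosePivot = pivot))
  })
}

#' Fixed five-record curation worked example
#'
#' A deterministic five-record table for one drug pair in one cell line
#' exercising every curation rule exactly once: one clean synergist, one
#' clean antagonist, one additive record (all scores within \[-10, 10\]),
#' one non-inhibitory record (all scores above 10, negative inhibition),
#' and one LOEWE-indeterminate record rescued from the additive filter
#' by its BLISS score. Curation yields exactly two labelled samples.
#'
#' @return list with `records` and the matching `drugs` table (which
#'   includes a SMILES alias to exercise drug unification).
#' @export
workedPipelineFixture <- function() {
  records <- data.frame(
    drug_a = "DRA", drug_b = "DRB", cell = "CL1",
    dose_a = c(1, 1, 2, 2, 4), dose_b = c(1, 2, 1, 2, 4),
    inhibition = c(30, 20, 10, -5, 15),
    bliss = c(12, -12, 5, 12, 20),
    hsa = c(14, -11, 3, 14, 9),
    loewe = c(15, -15, -2, 11, 9),
    zip = c(13, -13, 8, 13, 9),
    study = "toy", stringsAsFactors = FALSE)
  drugs <- data.frame(name = c("DRA", "DRB", "DRA-ALIAS"),
                      smiles = c("CCO", "CCN", "CCO"),
                      stringsAsFactors = FALSE)
  drugs$genes <- list("EGFR", c("ERBB2", "MYC"), "EGFR")
  list(records = records, drugs = drugs)
}

#' End-to-end benchmark on a synthetic screen
#'
#' Generates a synthetic dataset, runs the full pipeline — curation,
#' gene-set size filtering, ssGSEA, hypergraph construction, grouped
#' 10-fold split (one test fold, one validation fold), model training —
#' and evaluates held-out predictions overall, per triplet and per dose
#' quadrant, plus the attention-weight differential analysis over the
#' top-performing test triplets.
#'
#' @param spec a [syntheticSpec()].
#' @param config a [synergyConfig()]; the default is scaled to the toy
#'   problem (16-dimensional embeddings, hidden width 64, 40 epochs)
#'   so the whole benchmark runs in well under a minute on one CPU.
#'   The k-mer size and the seed are taken from `spec`.
#' @param nFolds,testFold,valFold grouped-fold layout.
#' @param topN number of top test triplets pooled for the attention
#'   analysis.
#' @return list with `metrics`, `baseline` (constant-predictor scores),
#'   `report` (differential-weight table), `causalRank` (best rank of a
#'   causal set, 1 = most significant), `nNodesTested`, `model`,
#'   `samples`, `preds`, `testIdx` and the generated `data`.
#' @export
syntheticBenchmark <- function(spec = syntheticSpec(),
                               config = synergyConfig(embedDim = 16,
                                                      hidden = 64,
                                                      epochs = 40,
                                                      batchSize = 256,
                                                      lr = 3e-3),
                               nFolds = 10, testFold = 1, valFold = 2,
                               topN = 20) {
  config$kmer <- spec$kmer
  config$seed <- spec$seed
  data <- generateSynthetic(spec)
  cur <- curateSamples(data$records, data$drugs)
  samples <- cur$samples

  gscF <- filterGeneSets(data$geneSets)
  nes <- suppressWarnings(ssgsea(data$expression, gscF))
  cellHg <- buildGenesetHypergraph(gscF)
  drugHg <- buildDrugHypergraph(data$drugs, gscF, k = spec$kmer)

  folds <- groupKFold(samples$triplet, nFolds, seed = config$seed)
  testIdx <- which(folds == testFold)
  valIdx <- which(folds == valFold)
  trainIdx <- which(folds != testFold & folds != valFold)

  vocab <- buildCovariateVocab(samples[trainIdx, ], data$cellMeta)
  features <- buildSampleFeatures(samples, nes, cellHg, drugHg, vocab,
                                  data$cellMeta)
  model <- trainSynergyModel(features, cellHg, drugHg, config,
                             trainIdx = trainIdx, valIdx = valIdx,
                             vocab = vocab)
  preds <- predictSynergy(model, features)

  metrics <- evaluatePredictions(preds[testIdx], samples$label[testIdx],
                                 samples$triplet[testIdx],
                                 samples[testIdx, ], data$ic50)
  base <- baselineMostPrevalent(samples$label[trainIdx])
  baseScores <- base$predict(length(testIdx))
  baseline <- list(
    auprc = auprc(baseScores, samples$label[testIdx]),
    auroc = auroc(baseScores, samples$label[testIdx]),
    per_triplet = perTripletMetrics(baseScores, samples$label[testIdx],
                                    samples$triplet[testIdx]))

  top <- topTriplets(preds[testIdx], samples$label[testIdx],
                     samples$triplet[testIdx], n = topN)
  attn <- subjectAttention(model, features, "cell")
  weights <- weightedSubgraph(attn, features$cell)
  report <- pooledAnalysis(weights, samples, pool = "by_dose", triplet = top)
  causalRank <- min(match(data$truth$causalSets, report$node), na.rm = TRUE)

  list(metrics = metrics, baseline = baseline, report = report,
       causalRank = causalRank, nNodesTested = nrow(report),
       model = model, samples = samples, preds = preds, testIdx = testIdx,
       data = data, curation = cur$report)
}

#' False-discovery-rate calibration on pure noise
#'
#' Repeatedly draws label permutations over a pure-noise weighted
#' subgraph matrix, runs the differential-weight analysis, and records
#' the fraction of nodes reported significant at `alpha`. Under the
#' null this empirical rate should not exceed `alpha` beyond Monte
#' Carlo error.
#'
#' @param nSubjects,nNodes pool dimensions.
#' @param nPerms number of label permutations.
#' @param alpha FDR level.
#' @param seed RNG seed.
#' @return list with `rate` (mean fraction of nodes reported), `se`
#'   (Monte Carlo standard error), `perPerm` and `nPerms`.
#' @export
fdrCalibration <- function(nSubjects = 40, nNodes = 30, nPerms = 200,
                           alpha = 0.05, seed = 1) {
  withSeed(seed, {
    weights <- matrix(rnorm(nSubjects * nNodes), nSubjects, nNodes,
                      dimnames = list(NULL, sprintf("N%02d", seq_len(nNodes))))
    labels0 <- rep(c(0, 1), length.out = nSubjects)
    frac <- vapply(seq_len(nPerms), function(i) {
      lab <- sample(labels0)
      rep <- differentialWeights(weights, lab, alpha = alpha,
                                 pool = sprintf("perm%03d", i))
      mean(rep$significant)
    }, numeric(1))
    list(rate = mean(frac), se = stats::sd(frac) / sqrt(nPerms),
         perPerm = frac, nPerms = nPerms)
  })
}
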