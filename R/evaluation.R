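#' Grouped k-fold assignment by triplet
#'
#' Assigns every sample to one of `n_folds` test folds such that all
#' samples of a (drug A, drug B, cell line) triplet land in the same
#' fold — no triplet is shared between training and test data. Triplets
#' are shuffled under `seed` and dealt round-robin, so fold sizes in
#' triplet count differ by at most one.
#'
#' @param triplets character vector of canonical triplet keys, one per
#'   sample.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed for the shuffle.
#' @return integer vector of fold ids (1..n_folds) aligned to samples.
#' @export
groupKFold <- function(triplets, n_folds = 10, seed = 1) {
  uni <- unique(triplets)
  if (length(uni) < n_folds)
    stopf("%d triplet(s) cannot fill %d folds", length(uni), n_folds)
  perm <- withSeed(seed, sample(uni))
  foldOf <- stats::setNames(rep_len(seq_len(n_folds), length(perm)), perm)
  unname(foldOf[triplets])
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision with no interpolation: samples are
#' traversed by descending score, tied scores as a single threshold
#' block, and each block contributes (recall gain) x (precision at the
#' block). Under this definition a constant classifier scores exactly
#' the positive prevalence.
#'
#' @param scores numeric prediction scores (higher = more synergistic).
#' @param labels binary labels (0/1) aligned to scores.
#' @return average precision in (0, 1].
#' @export
#' @examples
#' auprc(c(0.9, 0.8, 0.7), c(1, 0, 1))  # (1 + 2/3) / 2
auprc <- function(scores, labels) {
  checkPredictions(scores, labels)
  P <- sum(labels == 1)
  if (P == 0L) stopf("average precision undefined without positive samples")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  ## block boundaries: last index of each tied-score run
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[last]
  n <- last
  prec <- tp / n
  recall <- tp / P
  dRec <- diff(c(0, recall))
  sum(dRec * prec)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, with tied score pairs contributing 1/2. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @inheritParams auprc
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  checkPredictions(scores, labels)
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0L || N == 0L)
    stopf("AUROC undefined unless both classes are present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

checkPredictions <- function(scores, labels) {
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  if (length(scores) == 0L) stopf("no predictions")
  if (!all(is.finite(scores))) stopf("non-finite scores")
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1")
  invisible(TRUE)
}

#' Per-triplet metrics
#'
#' Computes AUPRC and AUROC within each (drug A, drug B, cell line)
#' triplet — i.e. across its dose combinations — and averages over
#' triplets. Groups where a metric is undefined are skipped for that
#' metric and counted: AUROC needs both classes in the group, AUPRC at
#' least one positive.
#'
#' @param scores,labels predictions as in [auprc()].
#' @param triplets triplet key per sample.
#' @return list with `auprc` and `auroc`, each holding `mean`, `sd`,
#'   `n_groups` (used) and `n_skipped`.
#' @export
perTripletMetrics <- function(scores, labels, triplets) {
  checkPredictions(scores, labels)
  idx <- split(seq_along(scores), triplets)
  aps <- aucs <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    y <- labels[i]
    if (any(y == 1)) aps[k] <- auprc(scores[i], y)
    if (any(y == 1) && any(y == 0)) aucs[k] <- auroc(scores[i], y)
  }
  if (all(is.na(aps)) && all(is.na(aucs)))
    stopf("no triplet group supports either metric")
  summ <- function(v) list(mean = mean(v, na.rm = TRUE),
                           sd = stats::sd(v, na.rm = TRUE),
                           n_groups = sum(!is.na(v)),
                           n_skipped = sum(is.na(v)))
  list(auprc = summ(aps), auroc = summ(aucs))
}

#' Assign dose-quadrant tags from IC50 values
#'
#' A dose strictly above the drug's IC50 in that cell line counts as
#' high, otherwise (including exact equality) low. The quadrants of the
#' dose-response matrix are `low` (low, low), `low_high` (low A, high
#' B), `high` (high, high) and `high_low` (high A, low B). Samples with
#' a missing IC50 for either drug are tagged `NA` and counted.
#'
#' @param samples labelled samples with `drug_a`, `drug_b`, `cell`,
#'   `dose_a`, `dose_b` (raw concentration scale).
#' @param ic50 IC50 table (see [readIc50Table()]).
#' @return factor of quadrant tags with attribute `n_missing`.
#' @export
#' @examples
#' s <- data.frame(drug_a = "d1", drug_b = "d2", cell = "c1",
#'                 dose_a = 5, dose_b = 20)
#' ic <- data.frame(drug = c("d1", "d2"), cell = "c1", ic50 = c(10, 10))
#' assignQuadrant(s, ic)
assignQuadrant <- function(samples, ic50) {
  lut <- ic50Lookup(ic50)
  ia <- unname(lut[paste(samples$drug_a, samples$cell, sep = "||")])
  ib <- unname(lut[paste(samples$drug_b, samples$cell, sep = "||")])
  highA <- samples$dose_a > ia
  highB <- samples$dose_b > ib
  tag <- ifelse(highA & highB, "high",
         ifelse(highA & !highB, "high_low",
         ifelse(!highA & highB, "low_high", "low")))
  out <- factor(tag, levels = c("low", "low_high", "high", "high_low"))
  attr(out, "n_missing") <- sum(is.na(ia) | is.na(ib))
  out
}

#' Most-prevalent-label baseline
#'
#' The baseline classifier predicts the most prevalent training label
#' for every sample; as a score it emits the constant empirical
#' probability of the positive class. With step-wise average precision
#' this scores exactly the positive prevalence, and its AUROC is 0.5 on
#' any two-class label set.
#'
#' @param train_labels binary training labels.
#' @return list with `score` (the constant), `label` (the majority
#'   class) and `predict(n)` returning `n` constant scores.
#' @export
baselineMostPrevalent <- function(train_labels) {
  if (length(train_labels) == 0L) stopf("no training labels")
  stopifnot(all(train_labels %in% c(0, 1)))
  p <- mean(train_labels == 1)
  list(score = p,
       label = as.integer(p >= 0.5),
       predict = function(n) rep(p, n))
}

#' Overall, per-triplet and per-quadrant evaluation
#'
#' @param scores,labels,triplets predictions as in
#'   [perTripletMetrics()].
#' @param samples optional sample table (for quadrant assignment).
#' @param ic50 optional IC50 table; with `samples`, adds a per-quadrant
#'   block.
#' @return nested list: `overall` (auprc, auroc, n), `per_triplet`, and
#'   optionally `per_quadrant` with group counts.
#' @export
evaluatePredictions <- function(scores, labels, triplets,
                                samples = NULL, ic50 = NULL) {
  out <- list(overall = list(auprc = auprc(scores, labels),
                             auroc = auroc(scores, labels),
                             n = length(scores)),
              per_triplet = perTripletMetrics(scores, labels, triplets))
  if (!is.null(samples) && !is.null(ic50)) {
    quad <- assignQuadrant(samples, ic50)
    blocks <- list()
    for (q in levels(quad)) {
      i <- which(!is.na(quad) & quad == q)
      blk <- list(n = length(i))
      if (length(i) && any(labels[i] == 1))
        blk$auprc <- auprc(scores[i], labels[i])
      if (length(i) && any(labels[i] == 1) && any(labels[i] == 0))
        blk$auroc <- auroc(scores[i], labels[i])
      blocks[[q]] <- blk
    }
    blocks$n_missing_ic50 <- attr(quad, "n_missing")
    out$per_quadrant <- blocks
  }
  out
}
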