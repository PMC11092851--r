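#' Mann-Whitney U test with an exact small-sample path
#'
#' Computes \eqn{U = \#\{(x_i, y_j): x_i > y_j\} + \frac{1}{2}\#ties}.
#' For combined sample sizes up to `exact_max` the two-sided p-value is
#' exact, by enumeration of all \eqn{\binom{n+m}{n}} group assignments
#' of the pooled values (ties handled exactly through midranks):
#' \eqn{p = P(|U^* - nm/2| \ge |U - nm/2|)}. Beyond that, a
#' tie-corrected normal approximation without continuity correction is
#' used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_max largest combined size for the enumeration path.
#' @return list with `U`, `p` (two-sided) and `method`.
#' @export
#' @examples
#' mannWhitneyTest(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
mannWhitneyTest <- function(x, y, exact_max = 20) {
  if (length(x) == 0L || length(y) == 0L)
    stopf("both groups must be non-empty")
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mid <- n * m / 2

  if (n + m <= exact_max) {
    combs <- combn(n + m, n)
    Rx <- colSums(matrix(r[combs], nrow = n))
    Uall <- Rx - n * (n + 1) / 2
    p <- mean(abs(Uall - mid) >= abs(U - mid) - 1e-9)
    method <- "exact"
  } else {
    N <- n + m
    ties <- table(pooled)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- n * m / 12 * ((N + 1) - tieCorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mid) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal-tie-corrected"
  }
  list(U = U, p = min(p, 1), method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sort p-values ascending,
#' take \eqn{q_i = \min_{j \ge i} p_j m / j} capped at 1, and restore
#' input order. Adjusted values are componentwise no smaller than the
#' raw ones and invariant to input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "BH")
}

#' Weighted subgraphs
#'
#' Multiplies per-subject attention weights elementwise with the
#' subject feature matrix, yielding the quantity the interpretation
#' analysis tests: how much dose-scaled signal each node actually
#' contributed per subject. Zero support stays zero.
#'
#' @param attention subjects x nodes attention-weight matrix.
#' @param features the matching [SubjectFeatures-class] (or matrix).
#' @return subjects x nodes weighted matrix.
#' @export
weightedSubgraph <- function(attention, features) {
  f <- if (is(features, "SubjectFeatures")) featureValues(features) else features
  if (!identical(dim(attention), dim(f)))
    stopf("attention (%s) and features (%s) shapes differ",
          paste(dim(attention), collapse = "x"), paste(dim(f), collapse = "x"))
  attention * f
}

#' Differential attention-weight analysis within a sample pool
#'
#' For every node carrying non-zero weight in at least one pooled
#' sample, compares weighted-subgraph values between synergistic
#' (label 1) and antagonistic (label 0) samples with the Mann-Whitney U
#' test, adjusts p-values by Benjamini-Hochberg, and reports nodes below
#' `alpha`. Direction is the sign of the location shift
#' (synergy minus antagonism, by median).
#'
#' @param weights subjects x nodes weighted-subgraph matrix (see
#'   [weightedSubgraph()]).
#' @param labels binary labels aligned to rows.
#' @param alpha FDR level for the `significant` flag.
#' @param pool character tag describing the pool (propagated to the
#'   report and error messages).
#' @return data.frame (one row per tested node): `node`, `U`, `p`,
#'   `p_adj`, `direction`, `n_syn`, `n_ant`, `significant`; attribute
#'   `pool`.
#' @export
differentialWeights <- function(weights, labels, alpha = 0.05,
                                pool = "pool") {
  stopifnot(nrow(weights) == length(labels))
  if (!any(labels == 1) || !any(labels == 0))
    stopf("pool '%s' needs both synergistic and antagonistic samples", pool)
  tested <- which(colSums(weights != 0) > 0)
  if (length(tested) == 0L) stopf("pool '%s' has no non-zero node", pool)
  syn <- labels == 1
  res <- lapply(tested, function(j) {
    x <- weights[syn, j]
    y <- weights[!syn, j]
    mw <- mannWhitneyTest(x, y)
    data.frame(node = colnames(weights)[j] %||% as.character(j),
               U = mw$U, p = mw$p,
               direction = ifelse(median(x) >= median(y), "synergy", "antagonism"),
               n_syn = length(x), n_ant = length(y))
  })
  out <- do.call(rbind, res)
  out$p_adj <- bhAdjust(out$p)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_adj, out$p), c("node", "U", "p", "p_adj",
                                        "direction", "n_syn", "n_ant",
                                        "significant")]
  rownames(out) <- NULL
  attr(out, "pool") <- pool
  out
}

#' Pooled attention-weight analysis
#'
#' Builds the sample pool the interpretation analysis runs on and tests
#' each gene-set node for differential weighting between synergistic and
#' antagonistic samples. Two pools are supported: `"by_dose"` — the dose
#' combinations of one (drug A, drug B, cell line) triplet — and
#' `"by_cell_line"` — all samples of one drug pair across cell lines.
#'
#' @param weights subjects x nodes weighted-subgraph matrix for all
#'   samples.
#' @param samples the labelled sample table aligned to `weights` rows.
#' @param pool `"by_dose"` or `"by_cell_line"`.
#' @param triplet for `"by_dose"`: the triplet key to pool.
#' @param pair for `"by_cell_line"`: character vector
#'   `c(drug_a, drug_b)` (canonical order).
#' @param alpha FDR level.
#' @return a [differentialWeights()] report for the pool.
#' @export
pooledAnalysis <- function(weights, samples,
                           pool = c("by_dose", "by_cell_line"),
                           triplet = NULL, pair = NULL, alpha = 0.05) {
  pool <- match.arg(pool)
  if (pool == "by_dose") {
    if (is.null(triplet)) stopf("by_dose pool needs a triplet key")
    sel <- samples$triplet %in% triplet
    tag <- paste0("by_dose:", paste(triplet, collapse = ","))
  } else {
    if (is.null(pair) || length(pair) != 2L)
      stopf("by_cell_line pool needs pair = c(drug_a, drug_b)")
    sel <- samples$drug_a == pair[1] & samples$drug_b == pair[2]
    tag <- paste0("by_cell_line:", pair[1], "+", pair[2])
  }
  if (!any(sel)) stopf("empty pool '%s'", tag)
  differentialWeights(weights[sel, , drop = FALSE], samples$label[sel],
                      alpha = alpha, pool = tag)
}

#' Rank triplets by model performance
#'
#' Orders triplets by per-triplet AUPRC (descending), breaking ties by
#' sample count, and returns the top `n` keys — the pools the
#' interpretation analysis focuses on.
#'
#' @param scores,labels,triplets predictions as in
#'   [perTripletMetrics()].
#' @param n number of triplets to return.
#' @return character vector of triplet keys.
#' @export
topTriplets <- function(scores, labels, triplets, n = 20) {
  idx <- split(seq_along(scores), triplets)
  ap <- vapply(idx, function(i) {
    if (any(labels[i] == 1)) auprc(scores[i], labels[i]) else NA_real_
  }, numeric(1))
  cnt <- lengths(idx)
  keep <- !is.na(ap)
  ord <- order(-ap[keep], -cnt[keep])
  utils::head(names(idx)[keep][ord], n)
}
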