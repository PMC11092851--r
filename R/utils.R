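#' @importFrom stats rnorm runif rbinom plogis sd median pnorm p.adjust
#' @importFrom methods new validObject is slot
#' @importFrom utils read.delim write.table head combn
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number state set from `seed` and
#' restores the previous state afterwards, so callers' RNG streams are
#' not disturbed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## softmax of `z` within integer groups 1..nG; returns a vector aligned to z.
## Numerically stabilised by subtracting the per-group maximum.
groupSoftmax <- function(z, g, nG) {
  mx <- rep(-Inf, nG)
  ## segment max without sorting: loop over groups is fine at these sizes,
  ## but a vectorised two-pass via order() scales better.
  o <- order(g)
  gs <- g[o]; zs <- z[o]
  bounds <- c(which(diff(gs) != 0L), length(gs))
  starts <- c(1L, head(bounds, -1L) + 1L)
  for (k in seq_along(bounds)) {
    idx <- starts[k]:bounds[k]
    mx[gs[idx[1L]]] <- max(zs[idx])
  }
  e <- exp(z - mx[g])
  denom <- rowsumVec(e, g, nG)
  e / denom[g]
}

## rowsum() for a plain vector with integer groups 1..nG; absent groups get 0.
rowsumVec <- function(x, g, nG) {
  out <- numeric(nG)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs[, 1L]
  out
}

## rowsum() for a matrix with integer groups 1..nG; absent groups get 0 rows.
rowsumMat <- function(x, g, nG) {
  out <- matrix(0, nG, ncol(x))
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Dose transform applied before feature injection
#'
#' Screens span several orders of magnitude of concentration, so raw doses
#' are compressed with `log10(dose + 1)` before they are injected into
#' subject features or used to build one-hot dose vocabularies. Zero dose
#' maps to zero signal.
#'
#' @param dose numeric vector of non-negative concentrations.
#' @return numeric vector on the transformed scale.
#' @export
#' @examples
#' transformDose(c(0, 9, 99))
transformDose <- function(dose) {
  stopifnot(is.numeric(dose), all(dose >= 0))
  log10(dose + 1)
}

#' Canonical triplet key
#'
#' Builds the (drug A, drug B, cell line) key used to group dose-level
#' measurements. Drug ids must already be canonically ordered (see
#' [unifyDrugs()]).
#'
#' @param drug_a,drug_b canonical drug identifiers.
#' @param cell cell-line identifier.
#' @return character vector of keys.
#' @export
tripletKey <- function(drug_a, drug_b, cell) {
  paste(drug_a, drug_b, cell, sep = "||")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## required record columns for a dose-level synergy table
synergyColumns <- function() {
  c("drug_a", "drug_b", "cell", "dose_a", "dose_b",
    "inhibition", "bliss", "hsa", "loewe", "zip", "study")
}

scoreColumns <- function() c("bliss", "hsa", "loewe", "zip")
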