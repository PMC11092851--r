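#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Computes, per cell line, a weighted Kolmogorov-Smirnov-style
#' enrichment score for each gene set and min-max normalises across the
#' whole score matrix to give normalised enrichment scores (NES).
#'
#' Per sample, genes are ranked by expression (average ranks on ties,
#' descending traversal with stable tie order). Walking down the ranked
#' list, the in-set empirical CDF steps by \eqn{r^w / \sum_{hit} r^w}
#' (rank value `r`, exponent `w`) at set members and the out-of-set CDF
#' by \eqn{1/(N - N_{hit})} elsewhere; the enrichment score is the sum
#' over all positions of the CDF difference. NES divides every score by
#' the range (max - min) of the full ES matrix.
#'
#' Sets with no gene in the expression matrix (or covering every gene,
#' which leaves the out-of-set CDF undefined) are dropped with a
#' warning.
#'
#' @param expr genes x cells numeric matrix (log2(TPM+1) scale).
#' @param sets a [GeneSetCollection-class].
#' @param weight rank-weighting exponent; 0.25 is the conventional
#'   single-sample default.
#' @return cells x sets NES matrix.
#' @export
ssgsea <- function(expr, sets, weight = 0.25) {
  stopifnot(is.matrix(expr), is.numeric(expr), all(is.finite(expr)))
  gsc <- geneSets(sets)
  genes <- rownames(expr)
  n <- length(genes)
  overlap <- lapply(gsc, function(s) which(genes %in% s))
  usable <- vapply(overlap, function(i)
    length(i) > 0L && length(i) < n, logical(1))
  if (!any(usable)) stopf("no gene set overlaps the expression matrix")
  if (any(!usable))
    warnf("dropping %d gene set(s) with no usable overlap: %s",
          sum(!usable), paste(names(gsc)[!usable], collapse = ", "))
  overlap <- overlap[usable]

  es <- matrix(NA_real_, ncol(expr), length(overlap),
               dimnames = list(colnames(expr), names(overlap)))
  for (s in seq_len(ncol(expr))) {
    vals <- expr[, s]
    r <- rank(vals, ties.method = "average")
    ord <- order(vals, decreasing = TRUE)
    rw <- r[ord]^weight
    for (j in seq_along(overlap)) {
      hit <- logical(n)
      hit[overlap[[j]]] <- TRUE
      hit <- hit[ord]
      nh <- sum(hit)
      pin <- cumsum(rw * hit) / sum(rw[hit])
      pout <- cumsum(!hit) / (n - nh)
      es[s, j] <- sum(pin - pout)
    }
  }
  rng <- max(es) - min(es)
  if (rng == 0) {
    warnf("all enrichment scores identical; NES set to zero")
    return(es * 0)
  }
  es / rng
}

#' Build the gene-set hypergraph
#'
#' Nodes are the gene sets (TFs or pathways); hyperedges are genes. A
#' set-node is incident to a gene-hyperedge exactly when the gene
#' belongs to the set, so genes shared between sets tie their nodes
#' together while singleton genes form singleton hyperedges. Node and
#' edge axes are sorted for determinism.
#'
#' @param sets a [GeneSetCollection-class] (typically after
#'   [filterGeneSets()]).
#' @param transpose if `TRUE`, build the conventional orientation
#'   instead (genes as nodes, sets as hyperedges).
#' @return an [IncidenceHypergraph-class].
#' @export
buildGenesetHypergraph <- function(sets, transpose = FALSE) {
  gsc <- geneSets(sets)
  setNms <- sort(names(gsc))
  genes <- sort(unique(unlist(gsc, use.names = FALSE)))
  i <- unlist(lapply(setNms, function(nm)
    rep(match(nm, setNms), length(gsc[[nm]]))), use.names = FALSE)
  j <- unlist(lapply(setNms, function(nm)
    match(gsc[[nm]], genes)), use.names = FALSE)
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(setNms), length(genes)),
                            dimnames = list(setNms, genes))
  if (transpose) m <- Matrix::t(m)
  IncidenceHypergraph(m)
}

#' Tokenize a SMILES string into k-mers
#'
#' Splits a SMILES string into the set of unique sliding-window
#' substrings of length `k` (stride 1). A string shorter than `k`
#' becomes a single whole-string token.
#'
#' @param smiles non-empty character string.
#' @param k window length (>= 1); 9 gave the best synergy-prediction
#'   performance in the ablation this package follows.
#' @return character vector of unique tokens.
#' @export
#' @examples
#' kmerTokenize("ABCD", 3)
kmerTokenize <- function(smiles, k) {
  stopifnot(length(smiles) == 1L, is.character(smiles))
  if (!nzchar(smiles)) stopf("empty SMILES string")
  stopifnot(k >= 1)
  nc <- nchar(smiles)
  if (nc < k) return(smiles)
  starts <- seq_len(nc - k + 1L)
  unique(substring(smiles, starts, starts + k - 1L))
}

#' Build the heterogeneous drug hypergraph
#'
#' Hyperedges are drugs. Nodes are of two kinds: k-mer SMILES tokens
#' (sub-structures, prefixed `kmer:`) and gene-set names whose members
#' overlap at least one drug's associated genes (prefixed `set:`). A
#' drug is incident to the token nodes of its SMILES and to every
#' gene-set node sharing at least one gene with its associated genes.
#'
#' @param drugs drug table (see [readDrugTable()]).
#' @param sets a [GeneSetCollection-class].
#' @param k k-mer window length.
#' @return an [IncidenceHypergraph-class].
#' @export
buildDrugHypergraph <- function(drugs, sets, k = 9) {
  stopifnot(nrow(drugs) > 0L)
  if (any(!nzchar(drugs$smiles))) stopf("drug with empty SMILES")
  gsc <- geneSets(sets)
  tokens <- lapply(drugs$smiles, kmerTokenize, k = k)
  setHits <- lapply(drugs$genes, function(g)
    names(gsc)[vapply(gsc, function(s) any(s %in% g), logical(1))])

  tokNodes <- paste0("kmer:", sort(unique(unlist(tokens, use.names = FALSE))))
  setNodes <- paste0("set:", sort(unique(unlist(setHits, use.names = FALSE))))
  nodes <- c(tokNodes, setNodes)
  edges <- sort(drugs$name)

  ii <- integer(0); jj <- integer(0)
  for (d in seq_along(edges)) {
    row <- match(edges[d], drugs$name)
    inc <- c(paste0("kmer:", tokens[[row]], recycle0 = TRUE),
             paste0("set:", setHits[[row]], recycle0 = TRUE))
    ii <- c(ii, match(inc, nodes))
    jj <- c(jj, rep(d, length(inc)))
  }
  m <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(nodes), length(edges)),
                            dimnames = list(nodes, edges))
  IncidenceHypergraph(m)
}

#' Dose injection into cell-line features
#'
#' Scales a cell line's per-set NES row by the total dose of the
#' combination: `F[i] = (dose_a + dose_b) * NES[i]`. Doses are expected
#' on the transformed scale (see [transformDose()]). Injection is linear
#' in each dose and a zero-dose combination contributes zero signal.
#'
#' @param nes_row named numeric vector of NES values for one cell line.
#' @param dose_a,dose_b non-negative doses (transformed scale).
#' @return numeric feature row aligned to `nes_row`.
#' @export
doseInjectCell <- function(nes_row, dose_a, dose_b) {
  stopifnot(dose_a >= 0, dose_b >= 0)
  if (dose_a + dose_b == 0)
    warnf("both doses zero: feature row is all zero")
  (dose_a + dose_b) * nes_row
}

#' Dose injection into drug-pair features
#'
#' Each drug's dose is injected into the nodes it is incident to
#' (sub-structure tokens and overlapping gene sets):
#' `F[i] = dose_a * H[i, drug_a] + dose_b * H[i, drug_b]`. Nodes shared
#' by both drugs receive the sum of the two doses.
#'
#' @param hg the drug [IncidenceHypergraph-class].
#' @param drug_a,drug_b hyperedge (drug) names.
#' @param dose_a,dose_b non-negative doses (transformed scale).
#' @return numeric feature row over the hypergraph's nodes.
#' @export
doseInjectDrugPair <- function(hg, drug_a, drug_b, dose_a, dose_b) {
  m <- incidence(hg)
  if (!drug_a %in% colnames(m)) stopf("unknown drug '%s'", drug_a)
  if (!drug_b %in% colnames(m)) stopf("unknown drug '%s'", drug_b)
  stopifnot(dose_a >= 0, dose_b >= 0)
  as.numeric(dose_a * m[, drug_a] + dose_b * m[, drug_b])
}

ageBin <- function(age) {
  lo <- floor(age / 10) * 10
  sprintf("%d-%d", lo, lo + 9)
}

#' One-hot covariate vocabulary and encoding
#'
#' `buildCovariateVocab()` collects, from training samples only, the
#' category dictionaries used for one-hot dose and phenotype encoding:
#' distinct tested concentrations (raw scale, pooled over both dose
#' axes), tissue of origin, gender, and age binned into decades.
#' `encodeCovariates()` concatenates one-hot blocks for dose A, dose B,
#' tissue, gender and age bin; a category unseen in the vocabulary
#' encodes as an all-zero block.
#'
#' @param samples labelled samples (needs `dose_a`, `dose_b`, `cell`).
#' @param cellMeta optional data.frame with columns `cell`, `tissue`,
#'   `gender`, `age`; when `NULL` only the dose blocks are encoded.
#' @param vocab a vocabulary from `buildCovariateVocab()`.
#' @return `buildCovariateVocab()` a list of category vectors;
#'   `encodeCovariates()` a samples x sum-of-vocabulary-sizes binary
#'   matrix.
#' @export
buildCovariateVocab <- function(samples, cellMeta = NULL) {
  vocab <- list(dose = sort(unique(c(samples$dose_a, samples$dose_b))))
  if (!is.null(cellMeta)) {
    meta <- cellMeta[match(samples$cell, cellMeta$cell), , drop = FALSE]
    vocab$tissue <- sort(unique(stats::na.omit(meta$tissue)))
    vocab$gender <- sort(unique(stats::na.omit(meta$gender)))
    vocab$age <- sort(unique(ageBin(stats::na.omit(meta$age))))
  }
  vocab
}

oneHotBlock <- function(values, categories) {
  m <- matrix(0, length(values), length(categories))
  hit <- match(values, categories)
  ok <- !is.na(hit)
  m[cbind(which(ok), hit[ok])] <- 1
  m
}

#' @rdname buildCovariateVocab
#' @export
encodeCovariates <- function(samples, vocab, cellMeta = NULL) {
  blocks <- list(doseA = oneHotBlock(samples$dose_a, vocab$dose),
                 doseB = oneHotBlock(samples$dose_b, vocab$dose))
  if (!is.null(vocab$tissue)) {
    if (is.null(cellMeta)) stopf("vocabulary has phenotype blocks but no cellMeta given")
    meta <- cellMeta[match(samples$cell, cellMeta$cell), , drop = FALSE]
    blocks$tissue <- oneHotBlock(meta$tissue, vocab$tissue)
    blocks$gender <- oneHotBlock(meta$gender, vocab$gender)
    blocks$age <- oneHotBlock(ageBin(meta$age), vocab$age)
  }
  out <- do.call(cbind, blocks)
  rownames(out) <- rownames(samples)
  out
}

#' Assemble the full feature bundle for a set of samples
#'
#' Builds, for every labelled sample, the dose-injected cell feature row
#' (total transformed dose times the cell line's NES over the gene-set
#' hypergraph nodes), the dose-injected drug-pair feature row over the
#' drug hypergraph nodes, and the one-hot covariate vector.
#'
#' @param samples labelled samples (see [curateSamples()]).
#' @param nes cells x sets NES matrix from [ssgsea()].
#' @param cellHg gene-set hypergraph from [buildGenesetHypergraph()].
#' @param drugHg drug hypergraph from [buildDrugHypergraph()].
#' @param vocab covariate vocabulary (built from training folds).
#' @param cellMeta optional cell-line phenotype table.
#' @return list with `cell` and `drug` [SubjectFeatures-class], `cov`
#'   covariate matrix, `labels`, `triplet`, and the transformed doses.
#' @export
buildSampleFeatures <- function(samples, nes, cellHg, drugHg, vocab,
                                cellMeta = NULL) {
  nodesC <- nodeNames(cellHg)
  if (!all(nodesC %in% colnames(nes)))
    stopf("NES matrix lacks columns for some hypergraph nodes")
  if (!all(samples$cell %in% rownames(nes)))
    stopf("NES matrix lacks rows for some sample cell lines")
  da <- transformDose(samples$dose_a)
  db <- transformDose(samples$dose_b)

  fcell <- nes[samples$cell, nodesC, drop = FALSE] * (da + db)
  rownames(fcell) <- rownames(samples)

  m <- incidence(drugHg)
  miss <- setdiff(unique(c(samples$drug_a, samples$drug_b)), colnames(m))
  if (length(miss))
    stopf("drug(s) missing from the drug hypergraph: %s",
          paste(miss, collapse = ", "))
  ma <- Matrix::t(m[, samples$drug_a, drop = FALSE])
  mb <- Matrix::t(m[, samples$drug_b, drop = FALSE])
  fdrug <- as.matrix(ma * da + mb * db)
  dimnames(fdrug) <- list(rownames(samples), rownames(m))

  list(cell = SubjectFeatures(fcell, cellHg),
       drug = SubjectFeatures(fdrug, drugHg),
       cov = encodeCovariates(samples, vocab, cellMeta),
       labels = samples$label,
       triplet = samples$triplet,
       dose_a = samples$dose_a, dose_b = samples$dose_b)
}
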