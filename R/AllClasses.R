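#' Gene-set collections
#'
#' A named list of gene sets (TF-target sets or pathway memberships).
#' Set names are unique, every set is non-empty, and member symbols are
#' non-empty strings. Within a set, each gene appears once (first
#' occurrence wins).
#'
#' @slot sets named list of character vectors of gene symbols.
#'
#' @param sets named list of character vectors.
#' @param x a `GeneSetCollection`.
#'
#' @return `GeneSetCollection()` returns a validated collection;
#'   `geneSets()` the named list; `setSizes()` an integer vector of set
#'   sizes named by set.
#' @export
#' @examples
#' gsc <- GeneSetCollection(list(S1 = c("TP53", "EGFR"), S2 = c("EGFR", "MYC")))
#' setSizes(gsc)
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  sets <- object@sets
  nm <- names(sets)
  if (length(sets) == 0L) return("collection has no gene sets")
  if (is.null(nm) || any(!nzchar(nm))) return("all sets must be named")
  if (anyDuplicated(nm)) return("duplicate set names")
  for (s in sets) {
    if (!is.character(s) || length(s) == 0L) return("empty gene set")
    if (any(!nzchar(s)) || anyNA(s)) return("gene symbols must be non-empty strings")
    if (anyDuplicated(s)) return("duplicate genes within a set")
  }
  TRUE
})

#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets) {
  sets <- lapply(sets, function(s) s[!duplicated(s)])
  new("GeneSetCollection", sets = sets)
}

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("setSizes", "GeneSetCollection", function(x)
  vapply(x@sets, length, integer(1)))

setMethod("show", "GeneSetCollection", function(object) {
  sz <- setSizes(object)
  cat("GeneSetCollection with", length(sz), "sets;",
      "sizes", min(sz), "-", max(sz), "\n")
})

#' Length of a gene-set collection
#' @param x a `GeneSetCollection`.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' Incidence hypergraphs
#'
#' The shared structure for both the gene-set hypergraph (nodes are gene
#' sets, hyperedges are genes) and the drug hypergraph (nodes are k-mer
#' SMILES tokens plus overlapping gene sets, hyperedges are drugs). The
#' incidence matrix is binary with named node rows and edge columns; no
#' hyperedge is empty and every node belongs to at least one hyperedge.
#'
#' @slot incidence a sparse binary [Matrix::sparseMatrix()]
#'   (nodes x hyperedges) with dimnames.
#'
#' @param incidence binary matrix (dense or sparse) with row and column
#'   names.
#' @param x an `IncidenceHypergraph`.
#' @return `IncidenceHypergraph()` a validated object; `nodeNames()` /
#'   `edgeNames()` character vectors; `incidence()` the sparse incidence
#'   matrix.
#' @export
setClass("IncidenceHypergraph", representation(incidence = "Matrix"))

setValidity("IncidenceHypergraph", function(object) {
  m <- object@incidence
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("incidence matrix needs node (row) and edge (column) names")
  if (anyDuplicated(rownames(m))) return("duplicate node names")
  if (anyDuplicated(colnames(m))) return("duplicate edge names")
  v <- m@x
  if (length(v) && !all(v %in% c(0, 1))) return("incidence must be binary")
  if (any(Matrix::colSums(m) == 0)) return("empty hyperedge")
  if (any(Matrix::rowSums(m) == 0)) return("isolated node (in no hyperedge)")
  TRUE
})

#' @rdname IncidenceHypergraph-class
#' @export
IncidenceHypergraph <- function(incidence) {
  m <- Matrix::Matrix(incidence, sparse = TRUE)
  m <- methods::as(m, "generalMatrix")
  m <- Matrix::drop0(m)
  new("IncidenceHypergraph", incidence = m)
}

#' @rdname IncidenceHypergraph-class
#' @export
setMethod("nodeNames", "IncidenceHypergraph", function(x) rownames(x@incidence))

#' @rdname IncidenceHypergraph-class
#' @export
setMethod("edgeNames", "IncidenceHypergraph", function(x) colnames(x@incidence))

#' @rdname IncidenceHypergraph-class
#' @export
setMethod("incidence", "IncidenceHypergraph", function(x) x@incidence)

setMethod("show", "IncidenceHypergraph", function(object) {
  m <- object@incidence
  cat("IncidenceHypergraph:", nrow(m), "nodes,", ncol(m), "hyperedges,",
      length(m@x), "incidences\n")
})

#' Dimensions of an incidence hypergraph
#' @param x an `IncidenceHypergraph`.
#' @export
setMethod("dim", "IncidenceHypergraph", function(x) dim(x@incidence))

#' Subject feature matrices
#'
#' Real-valued subjects x nodes matrices `F` driving subgraph attention:
#' dose-injected enrichment scores for the cell hypergraph, or
#' dose-scaled drug memberships for the drug hypergraph. The node axis
#' must be identical to the paired hypergraph's node axis; a subject's
#' sub-hypergraph is the set of nodes where its row is non-zero.
#'
#' @slot values numeric matrix, subjects in rows, nodes in columns.
#'
#' @param values numeric matrix with subject rownames and node colnames.
#' @param hypergraph optional `IncidenceHypergraph` whose node axis the
#'   columns must match exactly.
#' @param x a `SubjectFeatures`.
#' @export
setClass("SubjectFeatures", representation(values = "matrix"))

setValidity("SubjectFeatures", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("feature values must be numeric")
  if (!all(is.finite(v))) return("feature values must be finite")
  if (is.null(colnames(v))) return("feature columns must carry node names")
  TRUE
})

#' @rdname SubjectFeatures-class
#' @export
SubjectFeatures <- function(values, hypergraph = NULL) {
  if (!is.null(hypergraph)) {
    if (!identical(colnames(values), nodeNames(hypergraph)))
      stopf("feature node axis does not match the hypergraph node axis")
  }
  new("SubjectFeatures", values = values)
}

#' @rdname SubjectFeatures-class
#' @export
setMethod("featureValues", "SubjectFeatures", function(x) x@values)

#' @rdname SubjectFeatures-class
#' @export
setMethod("subjectIds", "SubjectFeatures", function(x) rownames(x@values))

setMethod("show", "SubjectFeatures", function(object) {
  v <- object@values
  cat("SubjectFeatures:", nrow(v), "subjects x", ncol(v), "nodes;",
      sprintf("%.1f%% non-zero\n", 100 * mean(v != 0)))
})

#' @rdname SubjectFeatures-class
#' @export
setMethod("dim", "SubjectFeatures", function(x) dim(x@values))

#' Trained sub-hypergraph attention synergy models
#'
#' Holds the learned parameters of the dual-attention hypergraph encoder
#' (per-hypergraph node-embedding table, attention state transform `W`,
#' context vector `c` and subgraph bias `b`), the batch-norm statistics
#' and feed-forward head, the configuration and one-hot vocabularies used
#' at training time, and the per-epoch training history.
#'
#' @slot params named list of parameter matrices/vectors.
#' @slot buffers named list of non-learned state (batch-norm running
#'   moments).
#' @slot config named list, see [modelConfig()].
#' @slot vocab one-hot covariate vocabularies captured from the training
#'   folds.
#' @slot history data.frame with one row per epoch (loss, validation
#'   metrics, learning rate).
#'
#' @param x a `HypergraphSynergyModel`.
#' @export
setClass("HypergraphSynergyModel",
         representation(params = "list", buffers = "list", config = "list",
                        vocab = "list", history = "data.frame",
                        cellHg = "IncidenceHypergraph",
                        drugHg = "IncidenceHypergraph"))

#' @rdname HypergraphSynergyModel-class
#' @export
setMethod("modelConfig", "HypergraphSynergyModel", function(x) x@config)

#' @rdname HypergraphSynergyModel-class
#' @export
setMethod("trainingHistory", "HypergraphSynergyModel", function(x) x@history)

setMethod("show", "HypergraphSynergyModel", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat("HypergraphSynergyModel:", np, "parameters;",
      nrow(object@history), "training epochs\n")
})
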