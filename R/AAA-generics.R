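#' @rdname IncidenceHypergraph-class
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname IncidenceHypergraph-class
#' @export
setGeneric("edgeNames", function(x) standardGeneric("edgeNames"))

#' @rdname IncidenceHypergraph-class
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("setSizes", function(x) standardGeneric("setSizes"))

#' @rdname SubjectFeatures-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname SubjectFeatures-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname HypergraphSynergyModel-class
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname HypergraphSynergyModel-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
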