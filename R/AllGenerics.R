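#' @rdname NodeGraph-class
#' @param object,x an object of the documented class.
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname NodeGraph-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname NodeGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname NodeGraph-class
#' @param node a node identifier.
#' @export
setGeneric("neighborsOf", function(x, node) standardGeneric("neighborsOf"))

#' @rdname NodeGraph-class
#' @export
setGeneric("degreeOf", function(x, node) standardGeneric("degreeOf"))

#' @rdname LabelTable-class
#' @export
setGeneric("labelsOf", function(x, node) standardGeneric("labelsOf"))

#' @rdname LabelTable-class
#' @export
setGeneric("labelUniverse", function(x) standardGeneric("labelUniverse"))

#' @rdname LabelTable-class
#' @export
setGeneric("isMultilabel", function(x) standardGeneric("isMultilabel"))

#' @rdname LabelTable-class
#' @export
setGeneric("labeledNodes", function(x) standardGeneric("labeledNodes"))

#' @rdname NodeEmbedding-class
#' @export
setGeneric("embMatrix", function(x) standardGeneric("embMatrix"))

#' @rdname NodeEmbedding-class
#' @export
setGeneric("embDim", function(x) standardGeneric("embDim"))

#' @rdname WeightVector-class
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' @rdname WeightVector-class
#' @export
setGeneric("modeTag", function(x) standardGeneric("modeTag"))

#' @rdname EvalResult-class
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname EvalResult-class
#' @export
setGeneric("summaryTable", function(x) standardGeneric("summaryTable"))

# ---- accessors ---------------------------------------------------------

#' @rdname NodeGraph-class
#' @export
setMethod("nodeNames", "NodeGraph", function(x) x@nodes)

#' @rdname NodeGraph-class
#' @export
setMethod("numNodes", "NodeGraph", function(x) length(x@nodes))

#' @rdname NodeGraph-class
#' @export
setMethod("numEdges", "NodeGraph",
          function(x) igraph::ecount(x@graph))

#' @rdname NodeGraph-class
#' @export
setMethod("neighborsOf", "NodeGraph", function(x, node) {
  if (!node %in% x@nodes)
    stop("unknown node: ", node)
  nb <- igraph::neighbors(x@graph, node)
  # report in canonical node order
  sort_by_canon(names(nb), x@nodes)
})

#' @rdname NodeGraph-class
#' @export
setMethod("degreeOf", "NodeGraph", function(x, node) {
  if (!node %in% x@nodes)
    stop("unknown node: ", node)
  unname(igraph::degree(x@graph, node))
})

#' @rdname LabelTable-class
#' @export
setMethod("labelsOf", "LabelTable", function(x, node) {
  if (!node %in% names(x@labels))
    stop("node has no labels: ", node)
  x@labels[[node]]
})

#' @rdname LabelTable-class
#' @export
setMethod("labelUniverse", "LabelTable", function(x) sort(x@universe))

#' @rdname LabelTable-class
#' @export
setMethod("isMultilabel", "LabelTable", function(x) x@multilabel)

#' @rdname LabelTable-class
#' @export
setMethod("labeledNodes", "LabelTable", function(x) names(x@labels))

#' @rdname NodeEmbedding-class
#' @export
setMethod("embMatrix", "NodeEmbedding", function(x) x@matrix)

#' @rdname NodeEmbedding-class
#' @export
setMethod("embDim", "NodeEmbedding", function(x) x@dModel)

#' @rdname WeightVector-class
#' @export
setMethod("weightValues", "WeightVector", function(x) x@weights)

#' @rdname WeightVector-class
#' @export
setMethod("modeTag", "WeightVector", function(x) x@mode)

#' @rdname EvalResult-class
#' @export
setMethod("scoreTable", "EvalResult", function(x) x@scores)

#' @rdname EvalResult-class
#' @export
setMethod("summaryTable", "EvalResult", function(x) x@summary)

# ---- show methods ------------------------------------------------------

setMethod("show", "NodeGraph", function(object) {
  cat("NodeGraph with", numNodes(object), "nodes and",
      numEdges(object), "edges\n")
})

setMethod("show", "LabelTable", function(object) {
  cat("LabelTable:", length(object@labels), "labelled nodes,",
      length(object@universe), "labels",
      if (object@multilabel) "(multi-label)\n" else "(single-label)\n")
})

setMethod("show", "WalkCorpus", function(object) {
  cat("WalkCorpus:", length(object@walks), "walks (",
      object@walksPerNode, "per node, length <=",
      object@walkLength, ")\n")
})

setMethod("show", "NodeEmbedding", function(object) {
  cat(class(object), ":", nrow(object@matrix), "nodes x",
      object@dModel, "dimensions\n")
})

setMethod("show", "NeighborContext", function(object) {
  cat("NeighborContext for", object@center, ":",
      length(object@neighbors), "of", object@fullDegree,
      "neighbors kept\n")
})

setMethod("show", "WeightVector", function(object) {
  cat("WeightVector [", object@mode, "] over",
      length(object@weights), "neighbors\n")
})

setMethod("show", "AttentionModel", function(object) {
  cat("AttentionModel: dModel =", object@dModel, ", heads =",
      object@heads, ", maxNeighbors =", object@maxNeighbors,
      if (object@trained) "(trained)\n" else "(untrained)\n")
})

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult over", nrow(object@scores), "splits\n")
  print(object@summary, row.names = FALSE)
})
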