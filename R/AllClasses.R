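#' @import methods
#' @importFrom stats prcomp rnorm runif sd setNames predict
#' @importFrom utils head write.table read.table
#' @useDynLib walkaggr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setOldClass("igraph")

#' Undirected network with a stable node ordering
#'
#' Thin S4 wrapper around an \pkg{igraph} graph. The wrapper pins down the
#' two properties every downstream matrix computation relies on: the graph is
#' simple and undirected (symmetric adjacency, no self-loops, no multi-edges)
#' and nodes keep the order of their first appearance, which is reused as the
#' row order of every embedding matrix.
#'
#' @slot graph a simple undirected \code{igraph} object whose vertices are
#'   named by the node identifiers.
#' @slot nodes character vector of node identifiers in canonical order.
#'
#' @seealso [readEdgelist()], [sbmGraph()], [multilabelGraph()]
#' @export
setClass("NodeGraph", representation(graph = "igraph", nodes = "character"))

setValidity("NodeGraph", function(object) {
  g <- object@graph
  msgs <- character()
  if (igraph::is_directed(g))
    msgs <- c(msgs, "graph must be undirected")
  if (any(igraph::which_loop(g)))
    msgs <- c(msgs, "graph must have no self-loops")
  if (any(igraph::which_multiple(g)))
    msgs <- c(msgs, "graph must have no multi-edges")
  vn <- igraph::V(g)$name
  if (is.null(vn) || !identical(vn, object@nodes))
    msgs <- c(msgs, "vertex names must match the canonical node order")
  if (anyDuplicated(object@nodes))
    msgs <- c(msgs, "node identifiers must be unique")
  if (length(msgs)) msgs else TRUE
})

#' Node label assignments
#'
#' Maps node identifiers to non-empty sets of label identifiers. The
#' multilabel flag is derived from the data: it is \code{TRUE} iff any node
#' carries two or more labels. Unlabelled graph nodes are permitted (they are
#' skipped by the classification protocol), but every labelled node must
#' exist in the accompanying graph when the two are used together.
#'
#' @slot labels named list; each element a character vector of labels.
#' @slot multilabel logical flag.
#' @slot universe character vector of all distinct labels.
#' @export
setClass("LabelTable", representation(labels = "list", multilabel = "logical",
                                      universe = "character"))

setValidity("LabelTable", function(object) {
  lab <- object@labels
  msgs <- character()
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    msgs <- c(msgs, "labels must be a uniquely named list")
  nl <- lengths(lab)
  if (any(nl == 0))
    msgs <- c(msgs, "every node must have at least one label")
  if (!identical(object@multilabel, any(nl >= 2)))
    msgs <- c(msgs, "multilabel flag inconsistent with the data")
  if (!setequal(object@universe, unique(unlist(lab, use.names = FALSE))))
    msgs <- c(msgs, "label universe inconsistent with the data")
  if (length(msgs)) msgs else TRUE
})

#' Random-walk corpus
#'
#' Node sequences sampled by truncated random walks; the input to the
#' skip-gram trainer. Every consecutive pair in every walk is an edge of the
#' source graph, and every node starts exactly \code{walksPerNode} walks.
#'
#' @slot walks list of character vectors (node identifier sequences).
#' @slot walksPerNode,walkLength the sampling parameters used.
#' @slot nodes canonical node order of the source graph.
#' @export
setClass("WalkCorpus", representation(walks = "list",
                                      walksPerNode = "integer",
                                      walkLength = "integer",
                                      nodes = "character"))

#' Node embedding matrix
#'
#' One d-dimensional real vector per node (the self-representational vectors
#' produced by the skip-gram stage, or the local vectors produced by
#' neighborhood aggregation). Row order equals the graph's canonical node
#' order; all entries are finite.
#'
#' @slot matrix numeric matrix, rownames = node identifiers.
#' @slot dModel embedding dimension (number of columns).
#' @export
setClass("NodeEmbedding", representation(matrix = "matrix",
                                         dModel = "integer"))

setValidity("NodeEmbedding", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    msgs <- c(msgs, "embedding rows must be uniquely named by node")
  if (!all(is.finite(m)))
    msgs <- c(msgs, "embedding entries must all be finite")
  if (ncol(m) != object@dModel)
    msgs <- c(msgs, "dModel must equal the number of columns")
  if (length(msgs)) msgs else TRUE
})

#' Fused node embedding
#'
#' Result of projecting the [self | local] concatenation onto its leading
#' principal components. The fitted projection (component matrix and column
#' means) is retained so the fusion can be audited or applied to new rows.
#'
#' @slot rotation orthonormal component matrix (2d x outDim).
#' @slot centerMeans column means removed before projection.
#' @export
setClass("FusedEmbedding", contains = "NodeEmbedding",
         representation(rotation = "matrix", centerMeans = "numeric"))

#' One-hop neighborhood of a node in embedding space
#'
#' A center node, its (possibly truncated) one-hop neighbors, and the
#' center-neighbor Euclidean distances in the current embedding. When the
#' degree exceeds \code{maxNeighbors} a seeded uniform sample without
#' replacement is kept; \code{fullDegree} records the degree before
#' truncation so hybrid weighting policies can dispatch on it.
#'
#' @slot center node identifier.
#' @slot neighbors character vector of distinct adjacent nodes.
#' @slot distances nonnegative numeric vector aligned with neighbors.
#' @slot maxNeighbors truncation cap.
#' @slot fullDegree degree of center before truncation.
#' @export
setClass("NeighborContext", representation(center = "character",
                                           neighbors = "character",
                                           distances = "numeric",
                                           maxNeighbors = "integer",
                                           fullDegree = "integer"))

setValidity("NeighborContext", function(object) {
  msgs <- character()
  if (length(object@neighbors) != length(object@distances))
    msgs <- c(msgs, "neighbors and distances must be aligned")
  if (anyDuplicated(object@neighbors))
    msgs <- c(msgs, "neighbors must be distinct")
  if (object@center %in% object@neighbors)
    msgs <- c(msgs, "center must not be its own neighbor")
  if (any(object@distances < 0))
    msgs <- c(msgs, "distances must be nonnegative")
  if (length(object@neighbors) !=
      min(object@fullDegree, object@maxNeighbors))
    msgs <- c(msgs, "neighbor count must be min(fullDegree, maxNeighbors)")
  if (length(msgs)) msgs else TRUE
})

#' Per-neighbor aggregation weights
#'
#' Positive weights over the neighbors of one context, summing to one, plus
#' a tag recording the weighting mode actually used: \code{"N"} (softmax over
#' inverse-sigmoid-normalized distances), \code{"F"} (proportional variant),
#' \code{"1H"} / \code{"MH"} (one-/multi-head self-attention), or the hybrid
#' policies \code{"1H+N"} / \code{"MH+N"} before dispatch.
#'
#' @slot weights numeric vector named by neighbor, positive, sums to 1.
#' @slot mode character mode tag.
#' @export
setClass("WeightVector", representation(weights = "numeric",
                                        mode = "character"))

setValidity("WeightVector", function(object) {
  w <- object@weights
  msgs <- character()
  if (length(w) == 0) msgs <- c(msgs, "weight vector must be non-empty")
  if (any(w <= 0)) msgs <- c(msgs, "weights must be strictly positive")
  if (length(w) && abs(sum(w) - 1) > 1e-9)
    msgs <- c(msgs, "weights must sum to 1 within 1e-9")
  if (length(msgs)) msgs else TRUE
})

#' Self-attention distance-regression model
#'
#' Parameters of the scaled dot-product self-attention weighting model: per
#' head, query/key/value projections of size dModel x dModel/h; for h > 1 an
#' output projection; and a three-layer MLP of sizes
#' (n*dModel, n*dModel/2, n-1) with n = maxNeighbors + 1 that regresses the
#' center-neighbor Euclidean distances from the attention output.
#'
#' @slot dModel,heads,dK,dV,maxNeighbors architecture integers
#'   (dK = dV = dModel / heads, exactly).
#' @slot params named list of parameter matrices/vectors.
#' @slot trained logical; has [trainAttention()] been run.
#' @slot seed integer seed used for initialization.
#' @export
setClass("AttentionModel", representation(dModel = "integer",
                                          heads = "integer",
                                          dK = "integer", dV = "integer",
                                          maxNeighbors = "integer",
                                          params = "list",
                                          trained = "logical",
                                          seed = "integer"))

setValidity("AttentionModel", function(object) {
  msgs <- character()
  if (object@dModel %% object@heads != 0)
    msgs <- c(msgs, "dModel must be divisible by heads")
  if (object@dK != object@dModel %/% object@heads ||
      object@dV != object@dModel %/% object@heads)
    msgs <- c(msgs, "dK and dV must equal dModel / heads")
  if (!all(is.finite(unlist(object@params, use.names = FALSE))))
    msgs <- c(msgs, "all parameters must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Padded mini-batch of neighborhood contexts
#'
#' Internal carrier for attention training and inference: per context an
#' input matrix with the center's vector in row 1 and neighbor vectors below,
#' zero-padded to maxNeighbors + 1 rows; a logical mask of real rows; and the
#' target center-neighbor distances (NA where padded).
#'
#' @slot inputs list of (maxNeighbors+1) x dModel matrices.
#' @slot masks list of logical vectors (TRUE = real row).
#' @slot targets list of numeric vectors of length maxNeighbors.
#' @slot contexts the source [NeighborContext-class] objects.
#' @export
setClass("TrainingBatch", representation(inputs = "list", masks = "list",
                                         targets = "list", contexts = "list"))

#' Node-classification evaluation result
#'
#' Micro-F1 of the repeated random-split one-vs-rest protocol: one score per
#' (training proportion, repeat), plus per-proportion means and standard
#' deviations.
#'
#' @slot scores data.frame with columns proportion, repeat_, microF1.
#' @slot summary data.frame with columns proportion, mean, sd.
#' @slot config list of protocol settings (proportions, repeats, seed).
#' @export
setClass("EvalResult", representation(scores = "data.frame",
                                      summary = "data.frame",
                                      config = "list"))

setValidity("EvalResult", function(object) {
  msgs <- character()
  if (!all(c("proportion", "repeat_", "microF1") %in%
           names(object@scores)))
    msgs <- c(msgs, "scores must have proportion, repeat_, microF1 columns")
  else {
    f1 <- object@scores$microF1
    if (any(f1 < 0 | f1 > 1)) msgs <- c(msgs, "Micro-F1 must lie in [0, 1]")
    agg <- tapply(f1, object@scores$proportion, mean)
    m <- object@summary$mean[match(names(agg),
                                   as.character(object@summary$proportion))]
    if (any(abs(agg - m) > 1e-12))
      msgs <- c(msgs, "summary means inconsistent with per-repeat scores")
  }
  if (length(msgs)) msgs else TRUE
})
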