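#' Aggregate a node's one-hop neighborhood into a local vector
#'
#' \code{meanAggregate} is the unweighted baseline: the local
#' representational vector is the arithmetic mean of the neighbors'
#' self-representational vectors. \code{weightedAggregate} generalizes it
#' to \eqn{r'_u = \sum_{v} \alpha_{uv} r_v} with weights from any weighting
#' policy; because the weights are positive and sum to one, the result is a
#' convex combination and lies in the convex hull of the neighbor vectors.
#' With uniform weights the two coincide exactly.
#'
#' @param ctx a [NeighborContext-class] with at least one neighbor.
#' @param weights a [WeightVector-class] aligned with the context's
#'   neighbors.
#' @param emb the [NodeEmbedding-class] holding the self vectors.
#' @return a numeric vector of length \code{embDim(emb)}.
#' @export
meanAggregate <- function(ctx, emb) {
  stopifnot(is(ctx, "NeighborContext"), is(emb, "NodeEmbedding"))
  k <- length(ctx@neighbors)
  if (k == 0)
    stop("degree-0 context: use the identity fallback (localVectors)")
  m <- embMatrix(emb)
  colMeans(m[ctx@neighbors, , drop = FALSE])
}

#' @rdname meanAggregate
#' @export
weightedAggregate <- function(ctx, weights, emb) {
  stopifnot(is(ctx, "NeighborContext"), is(weights, "WeightVector"),
            is(emb, "NodeEmbedding"))
  w <- weightValues(weights)
  if (length(w) != length(ctx@neighbors))
    stop("weight vector length does not match the context's neighbors")
  if (abs(sum(w) - 1) > 1e-6)
    stop("weights must sum to 1")
  m <- embMatrix(emb)
  drop(w %*% m[ctx@neighbors, , drop = FALSE])
}

#' Local representational vectors for every node of a graph
#'
#' Runs the weighting policy and weighted aggregation over all nodes:
#' for each node a one-hop context is built (neighbor cap
#' \code{maxNeighbors}), weights are computed via [selectWeighting()], and
#' the neighbors' self vectors are combined. Degree-0 nodes fall back to
#' their own self vector (identity fallback) with a warning listing how
#' many were affected.
#'
#' @param graph a [NodeGraph-class].
#' @param emb the self-representational [NodeEmbedding-class].
#' @param policy weighting policy (see [selectWeighting()]).
#' @param model optional [AttentionModel-class] for attention policies.
#' @param maxNeighbors neighbor cap (default 10).
#' @param degreeThreshold hybrid dispatch cutoff (default
#'   \code{maxNeighbors}).
#' @param seed integer seed for neighbor truncation sampling.
#' @return a [NodeEmbedding-class] of local vectors, same node order and
#'   dimension as \code{emb}.
#' @export
localVectors <- function(graph, emb, policy = "N", model = NULL,
                         maxNeighbors = 10,
                         degreeThreshold = maxNeighbors, seed = 1) {
  stopifnot(is(graph, "NodeGraph"), is(emb, "NodeEmbedding"))
  nodes <- nodeNames(graph)
  m <- embMatrix(emb)
  out <- matrix(0, length(nodes), embDim(emb),
                dimnames = list(nodes, NULL))
  isolated <- 0L
  for (u in nodes) {
    ctx <- neighborContext(graph, emb, u, maxNeighbors, seed)
    if (length(ctx@neighbors) == 0) {
      out[u, ] <- m[u, ]
      isolated <- isolated + 1L
      next
    }
    w <- selectWeighting(ctx, policy, model = model,
                         degreeThreshold = degreeThreshold, emb = emb)
    out[u, ] <- weightedAggregate(ctx, w, emb)
  }
  if (isolated > 0)
    warning(isolated, " degree-0 node(s) kept their own self vector")
  new("NodeEmbedding", matrix = out, dModel = embDim(emb))
}

#' Concatenate self and local representations
#'
#' Per node, the self-representational vector comes first and the local
#' (aggregated) vector is spliced after it, giving a |V| x 2d matrix. Both
#' inputs must cover exactly the same node set; rows follow the self
#' embedding's order.
#'
#' @param selfEmb,localEmb [NodeEmbedding-class] objects of equal dimension
#'   over the same nodes.
#' @return a [NodeEmbedding-class] of dimension 2d.
#' @export
concatRepresentations <- function(selfEmb, localEmb) {
  stopifnot(is(selfEmb, "NodeEmbedding"), is(localEmb, "NodeEmbedding"))
  a <- embMatrix(selfEmb); b <- embMatrix(localEmb)
  miss <- c(setdiff(rownames(a), rownames(b)),
            setdiff(rownames(b), rownames(a)))
  if (length(miss))
    stop("node sets differ; missing: ", paste(head(miss, 5), collapse = ", "))
  m <- cbind(a, b[rownames(a), , drop = FALSE])
  rownames(m) <- rownames(a)
  new("NodeEmbedding", matrix = m, dModel = ncol(m))
}

#' Fuse concatenated representations by principal component analysis
#'
#' Projects the [self | local] concatenation onto its leading \code{outDim}
#' principal components, returning both views to a single unified embedding
#' space of the original width. Columns are centered but not variance
#' scaled (both halves already live on comparable embedding scales). The
#' sign of each component is fixed so that its largest-absolute loading is
#' positive, making the projection deterministic.
#'
#' @param concat a [NodeEmbedding-class] (typically 2d wide).
#' @param outDim number of components to keep (default 128); must satisfy
#'   \code{outDim <= min(nrow - 1, ncol)}.
#' @return a [FusedEmbedding-class]; the fitted rotation and column means
#'   are retained in the \code{rotation} and \code{centerMeans} slots.
#' @export
pcaFuse <- function(concat, outDim = 128) {
  stopifnot(is(concat, "NodeEmbedding"))
  outDim <- assert_positive_int(outDim, "outDim")
  m <- embMatrix(concat)
  if (outDim > min(nrow(m) - 1L, ncol(m)))
    stop("outDim must be <= min(|V| - 1, input width) = ",
         min(nrow(m) - 1L, ncol(m)))
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = outDim)
  rot <- pc$rotation
  # canonical sign: largest |loading| of each component is positive
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2, flip, `*`)
  scores <- sweep(m, 2, pc$center) %*% rot
  rownames(scores) <- rownames(m)
  colnames(scores) <- NULL
  new("FusedEmbedding", matrix = scores, dModel = as.integer(outDim),
      rotation = rot, centerMeans = pc$center)
}
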