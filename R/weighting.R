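#' Build a node's one-hop neighborhood context in embedding space
#'
#' Collects a center node's one-hop neighbors and the Euclidean distances
#' between the center's and each neighbor's self-representational vectors.
#' When the degree exceeds \code{maxNeighbors}, a uniform sample of
#' \code{maxNeighbors} neighbors without replacement is kept (seeded, fixed
#' for the run); otherwise all neighbors are kept in canonical node order.
#' A degree-0 center yields a context with an empty neighbor list, which
#' aggregation resolves via the identity fallback.
#'
#' @param graph a [NodeGraph-class].
#' @param emb a [NodeEmbedding-class] covering center and neighbors.
#' @param center node identifier.
#' @param maxNeighbors neighbor cap (default 10).
#' @param seed integer seed for truncation sampling.
#' @return a [NeighborContext-class].
#' @export
neighborContext <- function(graph, emb, center, maxNeighbors = 10,
                            seed = 1) {
  stopifnot(is(graph, "NodeGraph"), is(emb, "NodeEmbedding"))
  maxNeighbors <- assert_positive_int(maxNeighbors, "maxNeighbors")
  nb <- neighborsOf(graph, center)
  deg <- length(nb)
  if (deg > maxNeighbors)
    nb <- with_seed(seed, sort_by_canon(sample(nb, maxNeighbors),
                                        nodeNames(graph)))
  m <- embMatrix(emb)
  need <- c(center, nb)
  if (!all(need %in% rownames(m)))
    stop("embedding does not cover: ",
         paste(setdiff(need, rownames(m)), collapse = ", "))
  d <- if (deg == 0) numeric(0) else
    sqrt(colSums((t(m[nb, , drop = FALSE]) - m[center, ])^2))
  new("NeighborContext", center = center, neighbors = nb,
      distances = unname(d), maxNeighbors = maxNeighbors,
      fullDegree = as.integer(deg))
}

#' Sigmoid normalization of embedding-space distances
#'
#' Maps a nonnegative Euclidean distance d into (0, 1) before the softmax
#' weighting. Mode \code{"N"} (the default, inverse relation) uses
#' \eqn{d' = 1 / (1 + e^{d})}, strictly decreasing in d; mode \code{"F"}
#' (proportional relation) uses \eqn{d' = 1 / (1 + e^{-d})}, strictly
#' increasing. The two are complementary: N(d) + F(d) = 1 for every d.
#' Note that on nonnegative distances mode N actually takes values in
#' (0, 0.5] and mode F in [0.5, 1); the formulas are implemented exactly
#' as defined.
#'
#' @param d finite nonnegative distance(s); vectorized.
#' @param mode \code{"N"} or \code{"F"}.
#' @return normalized distance(s) in (0, 1).
#' @examples
#' normalizeDistance(0, "N")  # 0.5
#' normalizeDistance(1, "N")  # 1/(1+e) = 0.26894...
#' @export
normalizeDistance <- function(d, mode = c("N", "F")) {
  mode <- match.arg(mode)
  if (!all(is.finite(d))) stop("distances must be finite")
  if (mode == "N") 1 / (1 + exp(d)) else 1 / (1 + exp(-d))
}

#' Closed-form (non-learning) neighbor weights
#'
#' The fast substitute for attention-based weighting: each center-neighbor
#' distance is sigmoid-normalized ([normalizeDistance()]) and the weights
#' are the softmax of the normalized distances,
#' \eqn{w_{uv} = e^{d'_{uv}} / \sum_j e^{d'_{uj}}}. Under mode \code{"N"}
#' closer neighbors get strictly larger weights; mode \code{"F"} reverses
#' the relation. Weights depend on absolute distances (no internal
#' rescaling).
#'
#' @param ctx a [NeighborContext-class] with at least one neighbor.
#' @param mode \code{"N"} or \code{"F"}.
#' @return a [WeightVector-class] tagged with the mode.
#' @export
nonlearningWeights <- function(ctx, mode = c("N", "F")) {
  mode <- match.arg(mode)
  stopifnot(is(ctx, "NeighborContext"))
  if (length(ctx@neighbors) == 0)
    stop("context has no neighbors; use the degree-0 aggregation fallback")
  dn <- normalizeDistance(ctx@distances, mode)
  e <- exp(dn)
  w <- e / sum(e)
  new("WeightVector", weights = setNames(w, ctx@neighbors), mode = mode)
}

#' Dispatch between attention-based and closed-form weighting
#'
#' Implements the weighting policies: \code{"N"} and \code{"F"} route to
#' [nonlearningWeights()]; \code{"1H"} and \code{"MH"} route to
#' [attentionWeights()] (a trained or initialized model is required); the
#' hybrid policies \code{"1H+N"} and \code{"MH+N"} use attention when the
#' center's full degree is at most \code{degreeThreshold} and fall back to
#' the closed-form mode N weights for high-degree nodes, which is how the
#' attention models stay tractable on hub-heavy networks. The returned
#' weight vector is tagged with the mode actually used.
#'
#' @param ctx a [NeighborContext-class].
#' @param policy one of \code{"N","F","1H","MH","1H+N","MH+N"}.
#' @param model an [AttentionModel-class]; required by attention policies.
#' @param degreeThreshold hybrid cutoff on the full (untruncated) degree;
#'   defaults to the context's \code{maxNeighbors}.
#' @param emb the [NodeEmbedding-class] the distances were computed in;
#'   required by attention policies.
#' @return a [WeightVector-class].
#' @export
selectWeighting <- function(ctx, policy = c("N", "F", "1H", "MH",
                                            "1H+N", "MH+N"),
                            model = NULL, degreeThreshold = NULL,
                            emb = NULL) {
  policy <- match.arg(policy)
  stopifnot(is(ctx, "NeighborContext"))
  if (is.null(degreeThreshold)) degreeThreshold <- ctx@maxNeighbors
  if (policy %in% c("N", "F"))
    return(nonlearningWeights(ctx, policy))
  if (is.null(model) || !is(model, "AttentionModel"))
    stop("policy ", policy, " requires an AttentionModel")
  hybrid <- policy %in% c("1H+N", "MH+N")
  if (hybrid && ctx@fullDegree > degreeThreshold)
    return(nonlearningWeights(ctx, "N"))
  if (is.null(emb))
    stop("attention weighting requires the embedding (emb)")
  attentionWeights(model, ctx, emb)
}
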