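# Shared in-code fixtures: tiny graphs, hand-built embeddings, random
# neighborhood contexts. Everything is generated programmatically.

# NodeGraph from edge pairs, via the text reader (also exercises IO).
graph_from_pairs <- function(pairs) {
  f <- tempfile(fileext = ".edg")
  writeLines(pairs, f)
  suppressMessages(readEdgelist(f))
}

# Hand-built NodeEmbedding from a matrix with rownames.
embedding_from_matrix <- function(m) {
  new("NodeEmbedding", matrix = m, dModel = ncol(m))
}

# Three disjoint 10-cliques with block labels: the extreme community
# structure used for separation checks.
three_cliques <- function(seed = 1) sbmGraph(30, 3, 1, 0, seed = seed)

# A NeighborContext with given distances (neighbors named x1, x2, ...).
context_with_distances <- function(d, maxNeighbors = 10,
                                   fullDegree = length(d)) {
  new("NeighborContext", center = "u",
      neighbors = if (length(d)) paste0("x", seq_along(d))
                  else character(0),
      distances = d,
      maxNeighbors = as.integer(maxNeighbors),
      fullDegree = as.integer(fullDegree))
}

# Random contexts with |N(0,1)| distances, degrees 1..maxDeg.
random_contexts <- function(n, seed, maxDeg = 10) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample.int(maxDeg, 1)
    context_with_distances(abs(rnorm(k)), maxNeighbors = maxDeg)
  })
}

# A small random graph plus a random embedding covering its nodes.
random_graph_embedding <- function(n, p, d, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  g <- igraph::set_vertex_attr(g, "name", value = paste0("v", seq_len(n)))
  ng <- new("NodeGraph", graph = g, nodes = paste0("v", seq_len(n)))
  m <- matrix(rnorm(n * d), n, d, dimnames = list(paste0("v", seq_len(n)),
                                                  NULL))
  list(graph = ng, emb = embedding_from_matrix(m))
}

# Contexts for attention training: every non-isolated node of a graph.
contexts_for_graph <- function(graph, emb, maxNeighbors = 10, seed = 1) {
  ctxs <- lapply(nodeNames(graph), function(u)
    neighborContext(graph, emb, u, maxNeighbors, seed))
  Filter(function(cx) length(cx@neighbors) > 0, ctxs)
}

# Independent oracle for the center-row attention weights of a model on a
# single context: direct evaluation of softmax(Q K^T / sqrt(dk)) per head,
# head-averaged, self/padding columns dropped, renormalized. Kept free of
# the package's forward-pass code on purpose.
oracle_attention_weights <- function(model, ctx, emb) {
  p <- model@params
  m <- embMatrix(emb)
  k <- length(ctx@neighbors)
  n <- model@maxNeighbors + 1L
  I <- matrix(0, n, model@dModel)
  I[seq_len(k + 1), ] <- m[c(ctx@center, ctx@neighbors), , drop = FALSE]
  rows <- numeric(n)
  for (i in seq_len(model@heads)) {
    q1 <- I[1, , drop = FALSE] %*% p$Wq[[i]]
    K <- I %*% p$Wk[[i]]
    s <- drop(q1 %*% t(K)) / sqrt(model@dK)
    s[seq_len(n) > k + 1] <- -Inf
    e <- exp(s - max(s))
    rows <- rows + e / sum(e)
  }
  rows <- rows / model@heads
  w <- rows[2:(k + 1)]
  w / sum(w)
}
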