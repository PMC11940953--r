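#' Simulate truncated random walks over a network
#'
#' The corpus-sampling stage of the random-walk embedding: from every node,
#' \code{walksPerNode} walks of at most \code{walkLength} nodes are started;
#' at each step the next node is chosen uniformly among the current node's
#' neighbors. A walk that reaches a degree-0 node stops there, so isolated
#' nodes yield length-1 walks. The order in which start nodes are visited is
#' reshuffled on every pass with the same seeded generator, and the whole
#' procedure is bit-reproducible for a fixed seed.
#'
#' @param graph a [NodeGraph-class].
#' @param walksPerNode walks started from each node (default 80).
#' @param walkLength maximum walk length in nodes (default 40).
#' @param seed integer seed.
#' @return a [WalkCorpus-class].
#' @export
simulateWalks <- function(graph, walksPerNode = 80, walkLength = 40, seed) {
  stopifnot(is(graph, "NodeGraph"))
  if (numNodes(graph) == 0) stop("graph has no nodes")
  walksPerNode <- assert_positive_int(walksPerNode, "walksPerNode")
  walkLength <- assert_positive_int(walkLength, "walkLength")
  nodes <- nodeNames(graph)
  adj <- adjacency_index(graph)
  raw <- .cppSimulateWalks(adj, walksPerNode, walkLength, as.double(seed))
  walks <- lapply(raw, function(w) nodes[w + 1L])
  new("WalkCorpus", walks = walks, walksPerNode = walksPerNode,
      walkLength = walkLength, nodes = nodes)
}

# 0-based integer adjacency lists in canonical node order.
adjacency_index <- function(graph) {
  al <- igraph::as_adj_list(graph@graph, mode = "all")
  lapply(al, function(v) as.integer(v) - 1L)
}

#' Train skip-gram node embeddings on a walk corpus
#'
#' Learns one \code{dModel}-dimensional self-representational vector per
#' node by skip-gram with negative sampling over the walk corpus, treating
#' walks as sentences and nodes as words (dynamic context window, unigram
#' distribution raised to 3/4 for negatives, linearly decaying learning
#' rate). Training is single-threaded and seeded, so identical
#' configurations give identical embeddings. Every graph node must occur in
#' the corpus; a missing node is an error rather than a silent zero row.
#'
#' @param corpus a [WalkCorpus-class].
#' @param dModel embedding dimension (default 128).
#' @param window one-sided context window in walk positions (default 10).
#' @param epochs passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param alpha initial learning rate (default 0.025).
#' @param seed integer seed.
#' @return a [NodeEmbedding-class] whose row order is the corpus's
#'   canonical node order.
#' @export
trainSkipgram <- function(corpus, dModel = 128, window = 10, epochs = 5,
                          negative = 5, alpha = 0.025, seed) {
  stopifnot(is(corpus, "WalkCorpus"))
  if (length(corpus@walks) == 0) stop("walk corpus is empty")
  dModel <- assert_positive_int(dModel, "dModel")
  window <- assert_positive_int(window, "window")
  epochs <- assert_positive_int(epochs, "epochs")
  nodes <- corpus@nodes
  seen <- unique(unlist(corpus@walks, use.names = FALSE))
  missing <- setdiff(nodes, seen)
  if (length(missing))
    stop("node absent from the walk corpus: ",
         paste(head(missing, 5), collapse = ", "))
  idx_walks <- lapply(corpus@walks,
                      function(w) match(w, nodes) - 1L)
  m <- .cppTrainSgns(idx_walks, length(nodes), dModel, window,
                     as.integer(negative), epochs, alpha, as.double(seed))
  rownames(m) <- nodes
  new("NodeEmbedding", matrix = m, dModel = dModel)
}
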