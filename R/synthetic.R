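#' Synthetic community-labelled graphs
#'
#' Seeded generators for the labelled benchmark graphs the evaluation
#' protocol runs on. \code{sbmGraph} draws a planted-partition
#' (stochastic-block-model) graph: nodes are split into \code{nBlocks}
#' near-equal blocks, within-block pairs are connected with probability
#' \code{pIn} and cross-block pairs with probability \code{pOut}; the block
#' index is each node's single label. \code{multilabelGraph} emulates
#' overlapping community membership: each node draws its number of labels
#' uniformly from \code{labelsPerNode}, then that many distinct labels
#' uniformly from \code{1..nLabels}; a pair is connected with probability
#' \code{pIn} when it shares at least one label and \code{pOut} otherwise.
#' Both are bit-reproducible for a fixed seed and require
#' \code{pOut < pIn} so a community signal exists (\code{pIn == pOut} is
#' allowed only in \code{multilabelGraph}, giving a label-independent
#' Erdos-Renyi graph for null experiments).
#'
#' Node identifiers are \code{"n1" ... "nN"}; labels are \code{"c1"...}
#' (blocks) or \code{"L1"...}.
#'
#' @param nNodes number of nodes.
#' @param nBlocks,nLabels number of blocks / distinct labels (>= 2).
#' @param pIn,pOut edge probabilities (0 <= pOut < pIn <= 1; equality of the
#'   two allowed in \code{multilabelGraph}).
#' @param labelsPerNode integer range (length-2 vector) of labels per node.
#' @param seed integer seed.
#' @return a list with components \code{graph} ([NodeGraph-class]) and
#'   \code{labels} ([LabelTable-class]).
#' @examples
#' fx <- sbmGraph(30, 3, 1, 0, seed = 1)
#' numEdges(fx$graph)  # 3 * choose(10, 2) = 135
#' @export
sbmGraph <- function(nNodes, nBlocks, pIn, pOut, seed) {
  nNodes <- assert_positive_int(nNodes, "nNodes")
  nBlocks <- assert_positive_int(nBlocks, "nBlocks")
  if (nBlocks < 2) stop("nBlocks must be >= 2")
  check_probs(pIn, pOut, allow_equal = FALSE)
  sizes <- block_sizes(nNodes, nBlocks)
  block <- rep(seq_len(nBlocks), sizes)
  labels <- as.list(paste0("c", block))
  names(labels) <- paste0("n", seq_len(nNodes))
  g <- with_seed(seed, {
    pm <- matrix(pOut, nBlocks, nBlocks)
    diag(pm) <- pIn
    igraph::sample_sbm(nNodes, pref.matrix = pm, block.sizes = sizes)
  })
  g <- igraph::set_vertex_attr(g, "name", value = names(labels))
  list(graph = as_node_graph(g), labels = new_label_table(labels))
}

#' @rdname sbmGraph
#' @export
multilabelGraph <- function(nNodes, nLabels, pIn, pOut,
                            labelsPerNode = c(1, 3), seed) {
  nNodes <- assert_positive_int(nNodes, "nNodes")
  nLabels <- assert_positive_int(nLabels, "nLabels")
  if (nLabels < 2) stop("nLabels must be >= 2")
  check_probs(pIn, pOut, allow_equal = TRUE)
  lpn <- as.integer(labelsPerNode)
  if (length(lpn) == 1) lpn <- c(lpn, lpn)
  if (length(lpn) != 2 || any(lpn < 1) || lpn[1] > lpn[2])
    stop("labelsPerNode must be a nondecreasing integer range >= 1")
  if (nLabels < lpn[2])
    stop("nLabels must be >= max(labelsPerNode)")
  nodes <- paste0("n", seq_len(nNodes))
  with_seed(seed, {
    k <- sample(lpn[1]:lpn[2], nNodes, replace = TRUE)
    memb <- matrix(FALSE, nNodes, nLabels)
    for (i in seq_len(nNodes))
      memb[i, sample.int(nLabels, k[i])] <- TRUE
    # force every label to be used at least once
    unused <- which(colSums(memb) == 0)
    for (j in unused) {
      i <- sample.int(nNodes, 1)
      drop <- sample(which(memb[i, ]), 1)
      memb[i, drop] <- FALSE
      memb[i, j] <- TRUE
    }
    share <- (memb %*% t(memb)) > 0
    prob <- ifelse(share, pIn, pOut)
    u <- matrix(0, nNodes, nNodes)
    u[upper.tri(u)] <- runif(nNodes * (nNodes - 1) / 2)
    sel <- which(upper.tri(u) & u < prob, arr.ind = TRUE)
    g <- igraph::graph_from_data_frame(
      data.frame(from = nodes[sel[, 1]], to = nodes[sel[, 2]],
                 stringsAsFactors = FALSE),
      directed = FALSE, vertices = nodes)
    labels <- lapply(seq_len(nNodes),
                     function(i) paste0("L", which(memb[i, ])))
    names(labels) <- nodes
    list(graph = as_node_graph(g), labels = new_label_table(labels))
  })
}

check_probs <- function(pIn, pOut, allow_equal) {
  ok <- is.numeric(pIn) && is.numeric(pOut) && pIn <= 1 && pOut >= 0 &&
    (if (allow_equal) pOut <= pIn else pOut < pIn)
  if (!ok)
    stop("need 0 <= pOut ", if (allow_equal) "<=" else "<",
         " pIn <= 1 (community signal requires pIn > pOut)")
  invisible(TRUE)
}

block_sizes <- function(n, k) {
  base <- n %/% k
  sizes <- rep(base, k)
  extra <- n - base * k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  sizes
}
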