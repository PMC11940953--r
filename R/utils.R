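# Internal helpers shared across modules.

# Evaluate `expr` under a temporary R RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("seed must be a single finite number")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Order `x` by position in the canonical node vector `canon`.
sort_by_canon <- function(x, canon) {
  x[order(match(x, canon))]
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 1 ||
      x != as.integer(x))
    stop(name, " must be a positive integer")
  as.integer(x)
}

# Construct a NodeGraph from an igraph, fixing the canonical node order to
# the current vertex order.
as_node_graph <- function(g) {
  new("NodeGraph", graph = g, nodes = igraph::V(g)$name)
}

new_label_table <- function(labels) {
  new("LabelTable", labels = labels,
      multilabel = any(lengths(labels) >= 2),
      universe = unique(unlist(labels, use.names = FALSE)))
}
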