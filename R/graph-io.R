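#' Read an undirected network from a whitespace-delimited edge list
#'
#' Each non-comment, non-blank line names one edge by its two endpoint node
#' identifiers (additional tokens on a line are ignored). Lines starting
#' with \code{#} are comments. Node identifiers are opaque strings and are
#' never coerced to integers; nodes are ordered by first appearance.
#' Duplicate edges are collapsed and self-loops dropped, with counts
#' reported via \code{message()}, so the result is always a simple
#' symmetric (undirected) graph.
#'
#' @param path path to the edge-list file.
#' @return a [NodeGraph-class] object.
#' @examples
#' f <- tempfile()
#' writeLines(c("a b", "b c", "# comment"), f)
#' g <- readEdgelist(f)
#' neighborsOf(g, "b")
#' @export
readEdgelist <- function(path) {
  if (!file.exists(path))
    stop("edge list file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad))
    stop("edge list parse error: line ", idx[bad[1]],
         " has fewer than 2 tokens")
  from <- vapply(toks, `[`, character(1), 1L)
  to <- vapply(toks, `[`, character(1), 2L)
  # node order = first appearance scanning each line left to right
  nodes <- unique(as.vector(rbind(from, to)))
  nloops <- sum(from == to)
  loop_keep <- from != to
  from <- from[loop_keep]; to <- to[loop_keep]
  # collapse duplicates (either orientation)
  key <- paste(pmin(from, to), pmax(from, to))
  dup <- duplicated(key)
  ndup <- sum(dup)
  from <- from[!dup]; to <- to[!dup]
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  message(sprintf(
    "readEdgelist: %d nodes, %d edges (%d self-loop(s) dropped, %d duplicate edge(s) collapsed)",
    length(nodes), igraph::ecount(g), nloops, ndup))
  as_node_graph(g)
}

#' Read a node-label table
#'
#' Each line holds a node identifier followed by its labels. Labels are
#' separated from the node by whitespace and from each other by
#' \code{delimiter} (default comma), so both \code{"n1 A"} and
#' \code{"n1 A,B"} parse. A line with no label is an error; duplicated node
#' lines have their labels unioned with a warning. The multilabel flag is
#' set from the data.
#'
#' @param path path to the label file.
#' @param delimiter separator between labels of one node.
#' @return a [LabelTable-class] object.
#' @export
readLabelTable <- function(path, delimiter = ",") {
  if (!file.exists(path))
    stop("label file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) < 2)
  if (length(bad))
    stop("label table parse error: line ", idx[bad[1]],
         " has a node but no labels")
  nodes <- vapply(toks, `[`, character(1), 1L)
  labs <- lapply(toks, function(t)
    unique(unlist(strsplit(t[-1], delimiter, fixed = TRUE))))
  if (any(lengths(labs) == 0))
    stop("label table parse error: empty label set")
  if (anyDuplicated(nodes)) {
    warning("duplicate node lines in label table; labels unioned")
    labs <- lapply(split(labs, factor(nodes, levels = unique(nodes))),
                   function(l) unique(unlist(l)))
    nodes <- unique(nodes)
  }
  new_label_table(setNames(labs, nodes))
}

#' Write / read node embeddings in the standard text format
#'
#' The format used by the word2vec family of tools: a header line
#' \code{"N d"}, then one line per node with the identifier followed by d
#' coordinates written at full precision (17 significant digits), so a
#' write/read round trip reproduces the matrix to within 1e-12.
#'
#' @param emb a [NodeEmbedding-class] (or any object with an embedding
#'   matrix accessible through [embMatrix()]).
#' @param path output (or input) file path.
#' @return \code{writeEmbeddings} returns \code{path} invisibly;
#'   \code{readEmbeddings} returns a [NodeEmbedding-class].
#' @export
writeEmbeddings <- function(emb, path) {
  m <- if (is(emb, "NodeEmbedding")) embMatrix(emb) else as.matrix(emb)
  if (nrow(m) == 0 || ncol(m) == 0)
    stop("cannot write an empty embedding matrix")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(nrow(m), ncol(m)), con)
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(rownames(m)[i],
          paste(formatC(m[i, ], format = "g", digits = 17),
                collapse = " ")),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname writeEmbeddings
#' @export
readEmbeddings <- function(path) {
  if (!file.exists(path))
    stop("embedding file not found: ", path)
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 2 || any(is.na(hdr)))
    stop("embedding file parse error: header must be 'N d'")
  n <- hdr[1]; d <- hdr[2]
  if (length(lines) < n + 1)
    stop("embedding file parse error: fewer rows than header declares")
  toks <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  if (any(lengths(toks) != d + 1))
    stop("embedding file parse error: row with wrong number of fields")
  ids <- vapply(toks, `[`, character(1), 1L)
  m <- t(vapply(toks, function(t) as.numeric(t[-1]), numeric(d)))
  if (d == 1) m <- matrix(m, ncol = 1)
  rownames(m) <- ids
  new("NodeEmbedding", matrix = m, dModel = as.integer(d))
}
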