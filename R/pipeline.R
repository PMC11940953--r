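#' Run the full embedding / weighting / aggregation / fusion / evaluation
#' pipeline
#'
#' Orchestrates the stages end to end on a graph with node labels:
#' (1) self-representational vectors by random walks + skip-gram (or an
#' injected pre-computed embedding file, which generalizes swapping in any
#' other base embedder); (2) per-node neighbor weighting under the chosen
#' policy, training the attention model on the distance-regression task
#' when an attention policy is selected; (3) weighted neighborhood
#' aggregation into local vectors; (4) representation assembly per the
#' \code{fusion} mode — \code{"pca"} (concatenate then project back to
#' \code{outDim}), \code{"cnt"} (unfused 2d concatenation), \code{"local"}
#' (local vectors only), \code{"self"} (base-embedding baseline; skips
#' stages 2-3); (5) the repeated-split one-vs-rest Micro-F1 protocol.
#' All artifacts (embeddings, score tables, resolved configuration, log)
#' are written under \code{outdir} when it is given, and every stage is
#' deterministic given \code{seed}.
#'
#' @param graph a [NodeGraph-class], or a path to an edge-list file.
#' @param labels a [LabelTable-class], or a path to a label file.
#' @param outdir output directory for artifacts (created); \code{NULL}
#'   writes nothing.
#' @param embeddingFile optional pre-computed embedding (text format of
#'   [writeEmbeddings()]); replaces the walk + skip-gram stage.
#' @param dim,walksPerNode,walkLength,window,sgEpochs skip-gram stage
#'   settings (defaults 128, 80, 40, 10, 5).
#' @param weighting policy passed to [selectWeighting()] (default
#'   \code{"N"}).
#' @param heads,attnEpochs,learningRate,batchSize attention stage settings
#'   (defaults 4, 100, 1e-3, 32); heads is forced to 1 by the \code{"1H"}
#'   policies.
#' @param maxNeighbors neighbor cap (default 10).
#' @param degreeThreshold hybrid dispatch cutoff (default
#'   \code{maxNeighbors}).
#' @param fusion one of \code{"pca"}, \code{"cnt"}, \code{"local"},
#'   \code{"self"}.
#' @param outDim fused dimensionality for \code{fusion = "pca"} (default
#'   \code{dim}).
#' @param proportions,repeats evaluation grid (defaults 0.2-0.8, 10).
#' @param seed master seed; stage seeds are derived from it.
#' @return (invisibly) a list with the self, local and final embeddings,
#'   the [EvalResult-class], the trained attention model (or NULL), and
#'   the resolved configuration.
#' @export
runPipeline <- function(graph, labels, outdir = NULL,
                        embeddingFile = NULL,
                        dim = 128, walksPerNode = 80, walkLength = 40,
                        window = 10, sgEpochs = 5,
                        weighting = "N", heads = 4, attnEpochs = 100,
                        learningRate = 1e-3, batchSize = 32,
                        maxNeighbors = 10,
                        degreeThreshold = maxNeighbors,
                        fusion = c("pca", "cnt", "local", "self"),
                        outDim = dim,
                        proportions = c(0.2, 0.4, 0.6, 0.8), repeats = 10,
                        seed = 1) {
  fusion <- match.arg(fusion)
  if (is.character(graph)) graph <- readEdgelist(graph)
  if (is.character(labels)) labels <- readLabelTable(labels)
  stopifnot(is(graph, "NodeGraph"), is(labels, "LabelTable"))
  bad <- setdiff(labeledNodes(labels), nodeNames(graph))
  if (length(bad))
    stop("labelled node(s) missing from the graph: ",
         paste(head(bad, 5), collapse = ", "))
  cfg <- list(dim = dim, walksPerNode = walksPerNode,
              walkLength = walkLength, window = window,
              sgEpochs = sgEpochs, weighting = weighting, heads = heads,
              attnEpochs = attnEpochs, learningRate = learningRate,
              batchSize = batchSize, maxNeighbors = maxNeighbors,
              degreeThreshold = degreeThreshold, fusion = fusion,
              outDim = outDim, proportions = proportions,
              repeats = repeats, seed = seed,
              embeddingFile = embeddingFile)
  logLines <- character()
  say <- function(...) {
    line <- paste0(...)
    message(line)
    logLines <<- c(logLines, line)
  }

  # stage 1: self-representational vectors
  if (!is.null(embeddingFile)) {
    say("stage embed: loading pre-computed embedding from ", embeddingFile)
    selfEmb <- readEmbeddings(embeddingFile)
    miss <- setdiff(nodeNames(graph), rownames(embMatrix(selfEmb)))
    if (length(miss))
      stop("pre-computed embedding misses node(s): ",
           paste(head(miss, 5), collapse = ", "))
  } else {
    say("stage embed: ", walksPerNode, " walks/node of length ",
        walkLength, ", skip-gram dim ", dim)
    corpus <- simulateWalks(graph, walksPerNode, walkLength, seed = seed)
    selfEmb <- trainSkipgram(corpus, dModel = dim, window = window,
                             epochs = sgEpochs, seed = seed + 1)
  }

  model <- NULL
  if (fusion == "self") {
    finalEmb <- selfEmb
    localEmb <- NULL
    say("stage aggregate: skipped (fusion = self)")
  } else {
    # stage 2: weighting (train attention if requested)
    if (weighting %in% c("1H", "MH", "1H+N", "MH+N")) {
      h <- if (weighting %in% c("1H", "1H+N")) 1L else as.integer(heads)
      say("stage attention: training ", h, "-head model, ",
          attnEpochs, " epochs")
      model <- buildAttentionModel(dModel = dim, heads = h,
                                   maxNeighbors = maxNeighbors,
                                   seed = seed + 2)
      ctxs <- lapply(nodeNames(graph), function(u)
        neighborContext(graph, selfEmb, u, maxNeighbors, seed = seed + 3))
      ctxs <- Filter(function(cx) length(cx@neighbors) > 0, ctxs)
      if (weighting %in% c("1H+N", "MH+N"))
        ctxs <- Filter(function(cx) cx@fullDegree <= degreeThreshold,
                       ctxs)
      tr <- trainAttention(model, ctxs, selfEmb, epochs = attnEpochs,
                           learningRate = learningRate,
                           batchSize = batchSize, seed = seed + 4)
      model <- tr$model
      say("stage attention: loss ", signif(tr$history[1], 4), " -> ",
          signif(tr$history[length(tr$history)], 4))
    }
    # stage 3: weighted aggregation
    say("stage aggregate: policy ", weighting)
    localEmb <- withCallingHandlers(
      localVectors(graph, selfEmb, policy = weighting, model = model,
                   maxNeighbors = maxNeighbors,
                   degreeThreshold = degreeThreshold, seed = seed + 3),
      warning = function(w) {
        say("stage aggregate: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    # stage 4: representation assembly
    finalEmb <- switch(fusion,
      pca = pcaFuse(concatRepresentations(selfEmb, localEmb), outDim),
      cnt = concatRepresentations(selfEmb, localEmb),
      local = localEmb)
    say("stage fuse: mode ", fusion, ", final width ", embDim(finalEmb))
  }

  # stage 5: evaluation protocol
  say("stage evaluate: ", repeats, " repeats at proportions ",
      paste(proportions, collapse = ", "))
  result <- withCallingHandlers(
    evaluateProtocol(finalEmb, labels, proportions = proportions,
                     repeats = repeats, seed = seed + 10),
    warning = function(w) {
      say("stage evaluate: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeEmbeddings(selfEmb, file.path(outdir, "self_embedding.txt"))
    if (!is.null(localEmb))
      writeEmbeddings(localEmb, file.path(outdir, "local_embedding.txt"))
    writeEmbeddings(finalEmb, file.path(outdir, "final_embedding.txt"))
    if (!is.null(model))
      saveAttentionModel(model, file.path(outdir, "attention_model.rds"))
    write.table(scoreTable(result), file.path(outdir, "scores.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(summaryTable(result), file.path(outdir, "summary.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(cfg, file.path(outdir, "config.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    writeLines(logLines, file.path(outdir, "run.log"))
    say("artifacts written to ", outdir)
  }
  invisible(list(self = selfEmb, local = localEmb, final = finalEmb,
                 result = result, model = model, config = cfg))
}

#' Write a synthetic labelled-graph fixture to disk
#'
#' Generates a community-structured graph ([sbmGraph()] for single-label,
#' [multilabelGraph()] for multi-label) and writes it in the exact formats
#' the readers consume: an edge list (\code{edges.txt}), a label table
#' (\code{labels.txt}, comma-joined labels), and the generator settings as
#' provenance (\code{fixture.json}). Byte-identical for a fixed seed.
#'
#' @param kind \code{"single"} or \code{"multi"}.
#' @param outdir output directory (created).
#' @param nNodes,nBlocks,pIn,pOut,labelsPerNode,seed generator settings;
#'   \code{nBlocks} doubles as the label count for \code{kind = "multi"}.
#' @return (invisibly) list of the written file paths.
#' @export
makeFixture <- function(kind = c("single", "multi"), outdir,
                        nNodes = 300, nBlocks = 3, pIn = 0.05,
                        pOut = 0.005, labelsPerNode = c(1, 3), seed = 1) {
  kind <- match.arg(kind)
  fx <- if (kind == "single")
    sbmGraph(nNodes, nBlocks, pIn, pOut, seed = seed)
  else
    multilabelGraph(nNodes, nBlocks, pIn, pOut,
                    labelsPerNode = labelsPerNode, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  edgeFile <- file.path(outdir, "edges.txt")
  labFile <- file.path(outdir, "labels.txt")
  el <- igraph::as_edgelist(fx$graph@graph)
  writeLines(paste(el[, 1], el[, 2]), edgeFile)
  labs <- fx$labels@labels
  writeLines(paste(names(labs),
                   vapply(labs, paste, character(1), collapse = ",")),
             labFile)
  specFile <- file.path(outdir, "fixture.json")
  jsonlite::write_json(
    list(kind = kind, nNodes = nNodes, nBlocks = nBlocks, pIn = pIn,
         pOut = pOut,
         labelsPerNode = if (kind == "multi") labelsPerNode else NULL,
         seed = seed),
    specFile, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(list(edges = edgeFile, labels = labFile, spec = specFile))
}
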