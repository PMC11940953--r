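#' Random train/test split of the labelled nodes
#'
#' Partitions the labelled nodes into a training set of size
#' \code{round(proportion * N)} and a test set of the remainder, by a
#' seeded uniform draw (no label stratification). A label absent from the
#' training side triggers a warning: the classifier will skip it.
#'
#' @param labels a [LabelTable-class].
#' @param proportion training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with character vectors \code{train} and \code{test}.
#' @export
splitNodes <- function(labels, proportion, seed) {
  stopifnot(is(labels, "LabelTable"))
  if (!is.numeric(proportion) || proportion <= 0 || proportion >= 1)
    stop("proportion must lie strictly in (0, 1)")
  nodes <- labeledNodes(labels)
  n <- length(nodes)
  if (n < 2) stop("need at least 2 labelled nodes to split")
  ntrain <- round(proportion * n)
  if (ntrain < 1 || ntrain >= n)
    stop("proportion ", proportion, " leaves an empty train or test set")
  train <- with_seed(seed, sample(nodes, ntrain))
  test <- setdiff(nodes, train)
  trainLabs <- unique(unlist(labels@labels[train], use.names = FALSE))
  missing <- setdiff(labels@universe, trainLabs)
  if (length(missing))
    warning("label(s) absent from the training set: ",
            paste(missing, collapse = ", "))
  list(train = train, test = test)
}

#' One-vs-rest logistic-regression prediction
#'
#' Fits one L2-regularized binary logistic regression per label on the
#' training nodes' embedding rows (ridge penalty, strength
#' \code{1/|train|} i.e. the common unit-C setting, configurable via
#' \code{lambda}). For single-label data each test node receives the
#' arg-max-score label; for multi-label data each test node receives its
#' top-\eqn{k_i} scored labels, where \eqn{k_i} is that node's true label
#' count — the standard evaluation convention for this task, without which
#' multi-label Micro-F1 values are not comparable. Labels with no positive
#' (or no negative) training example are skipped with a warning.
#'
#' @param emb a [NodeEmbedding-class] (fused or baseline) covering
#'   \code{train} and \code{test}.
#' @param labels a [LabelTable-class].
#' @param train,test character vectors of node identifiers.
#' @param lambda ridge penalty passed to \pkg{glmnet}; default
#'   \code{1/length(train)}.
#' @return named list: per test node, the predicted label set.
#' @export
fitPredictOvr <- function(emb, labels, train, test, lambda = NULL) {
  stopifnot(is(emb, "NodeEmbedding"), is(labels, "LabelTable"))
  m <- embMatrix(emb)
  need <- c(train, test)
  if (!all(need %in% rownames(m)))
    stop("embedding does not cover: ",
         paste(head(setdiff(need, rownames(m)), 5), collapse = ", "))
  if (is.null(lambda)) lambda <- 1 / length(train)
  xtr <- m[train, , drop = FALSE]
  xte <- m[test, , drop = FALSE]
  universe <- labelUniverse(labels)
  scores <- matrix(-Inf, length(test), length(universe),
                   dimnames = list(test, universe))
  skipped <- character()
  lamPath <- lambda * 10^seq(3, 0, length.out = 15)
  for (lab in universe) {
    y <- vapply(train, function(u) lab %in% labels@labels[[u]], logical(1))
    if (sum(y) == 0 || sum(y) == length(y)) {
      skipped <- c(skipped, lab)
      next
    }
    # glmnet warns about very small classes; expected with tiny splits
    fit <- withCallingHandlers(
      glmnet::glmnet(xtr, factor(y, levels = c(FALSE, TRUE)),
                     family = "binomial", alpha = 0,
                     lambda = lamPath, standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    scores[, lab] <- drop(predict(fit, xte, s = lambda,
                                  type = "link", exact = FALSE))
  }
  if (length(skipped))
    warning("label(s) skipped (no positive/negative training example): ",
            paste(skipped, collapse = ", "))
  if (length(skipped) == length(universe))
    stop("no label could be fitted")
  multilabel <- isMultilabel(labels)
  pred <- lapply(test, function(u) {
    s <- scores[u, ]
    k <- if (multilabel) length(labels@labels[[u]]) else 1L
    names(sort(s, decreasing = TRUE))[seq_len(k)]
  })
  setNames(pred, test)
}

#' Micro-averaged F1 over label decisions
#'
#' Pools true positives, false positives and false negatives over all
#' (node, label) decisions and returns \eqn{2TP / (2TP + FP + FN)}. In the
#' single-label top-1 regime every wrong prediction is simultaneously one
#' FP and one FN, so Micro-F1 reduces to plain accuracy.
#'
#' @param predicted,truth named lists of label sets over the same nodes.
#' @return Micro-F1 in [0, 1].
#' @examples
#' microF1(list(a = "X", b = "X"), list(a = "X", b = "Y"))  # 0.5
#' @export
microF1 <- function(predicted, truth) {
  if (length(truth) == 0) stop("empty test set")
  if (!setequal(names(predicted), names(truth)))
    stop("predicted and truth must cover the same nodes")
  tp <- fp <- fn <- 0
  for (u in names(truth)) {
    p <- predicted[[u]]; t <- truth[[u]]
    tp <- tp + length(intersect(p, t))
    fp <- fp + length(setdiff(p, t))
    fn <- fn + length(setdiff(t, p))
  }
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Repeated random-split node-classification protocol
#'
#' For every training proportion and repeat r, splits the labelled nodes
#' with seed \code{seed + r}, fits the one-vs-rest classifier, predicts the
#' held-out nodes, and scores Micro-F1; then reports per-proportion means
#' and standard deviations. The whole grid is deterministic given the base
#' seed.
#'
#' @param emb a [NodeEmbedding-class] to evaluate.
#' @param labels a [LabelTable-class].
#' @param proportions training fractions (default 0.2, 0.4, 0.6, 0.8).
#' @param repeats random splits per proportion (default 10).
#' @param seed base seed; repeat r uses \code{seed + r}.
#' @param lambda ridge penalty forwarded to [fitPredictOvr()].
#' @return an [EvalResult-class].
#' @export
evaluateProtocol <- function(emb, labels,
                             proportions = c(0.2, 0.4, 0.6, 0.8),
                             repeats = 10, seed = 1, lambda = NULL) {
  repeats <- assert_positive_int(repeats, "repeats")
  if (any(proportions <= 0 | proportions >= 1))
    stop("proportions must lie strictly in (0, 1)")
  truthAll <- labels@labels
  rows <- vector("list", length(proportions) * repeats)
  i <- 0L
  for (p in proportions) {
    for (r in seq_len(repeats)) {
      sp <- splitNodes(labels, p, seed + r)
      pred <- fitPredictOvr(emb, labels, sp$train, sp$test, lambda)
      f1 <- microF1(pred, truthAll[sp$test])
      i <- i + 1L
      rows[[i]] <- data.frame(proportion = p, repeat_ = r, microF1 = f1)
    }
  }
  scores <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(scores, scores$proportion),
    function(d) data.frame(proportion = d$proportion[1],
                           mean = mean(d$microF1),
                           sd = if (nrow(d) > 1) sd(d$microF1) else 0)))
  rownames(summ) <- NULL
  new("EvalResult", scores = scores, summary = summ,
      config = list(proportions = proportions, repeats = repeats,
                    seed = seed))
}
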