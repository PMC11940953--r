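#' Build an (untrained) self-attention distance-regression model
#'
#' Constructs the parameters of the scaled dot-product self-attention
#' weighting model. Each of the \code{heads} heads carries query, key and
#' value projections of size dModel x dModel/heads (the split must be
#' exact); for more than one head the concatenated head outputs are mixed
#' by an output projection back to dModel. The attention output feeds a
#' three-layer MLP with (n*dModel, n*dModel/2, n-1) neurons, where
#' n = maxNeighbors + 1 counts the center plus the padded neighbor slots;
#' the n-1 outputs are the estimated center-neighbor distances the model is
#' trained to regress. Parameters are initialized from seeded
#' scaled-Gaussian draws.
#'
#' @param dModel embedding dimension (default 128).
#' @param heads number of attention heads (1 = one-head model; default 4).
#' @param maxNeighbors neighbor cap n - 1 (default 10).
#' @param seed integer seed for initialization.
#' @return an [AttentionModel-class].
#' @export
buildAttentionModel <- function(dModel = 128, heads = 4, maxNeighbors = 10,
                                seed = 1) {
  dModel <- assert_positive_int(dModel, "dModel")
  heads <- assert_positive_int(heads, "heads")
  maxNeighbors <- assert_positive_int(maxNeighbors, "maxNeighbors")
  if (dModel %% heads != 0)
    stop("dModel (", dModel, ") must be divisible by heads (", heads, ")")
  dk <- dModel %/% heads
  n <- maxNeighbors + 1L
  nd <- n * dModel
  if (nd %% 2 != 0) stop("n * dModel must be even for the MLP hidden layer")
  hid <- nd %/% 2L
  params <- with_seed(seed, {
    gmat <- function(nr, nc) matrix(rnorm(nr * nc, sd = 1 / sqrt(nr)),
                                    nr, nc)
    p <- list(
      Wq = lapply(seq_len(heads), function(i) gmat(dModel, dk)),
      Wk = lapply(seq_len(heads), function(i) gmat(dModel, dk)),
      Wv = lapply(seq_len(heads), function(i) gmat(dModel, dk)),
      W1 = gmat(nd, hid), b1 = numeric(hid),
      W2 = gmat(hid, n - 1L), b2 = numeric(n - 1L))
    if (heads > 1) p$Wout <- gmat(heads * dk, dModel)
    p
  })
  new("AttentionModel", dModel = dModel, heads = heads,
      dK = dk, dV = dk, maxNeighbors = maxNeighbors,
      params = params, trained = FALSE, seed = as.integer(seed))
}

#' Assemble a padded training batch from neighborhood contexts
#'
#' For each context, stacks the center's self-representational vector (row
#' 1) and its neighbors' vectors, zero-padded to maxNeighbors + 1 rows,
#' together with the mask of real rows and the target center-neighbor
#' Euclidean distances (NA at padded slots).
#'
#' @param contexts list of [NeighborContext-class] objects.
#' @param emb a [NodeEmbedding-class] covering all referenced nodes.
#' @param maxNeighbors padded neighbor capacity; every context must fit.
#' @return a [TrainingBatch-class].
#' @export
buildTrainingBatch <- function(contexts, emb, maxNeighbors = 10) {
  stopifnot(is(emb, "NodeEmbedding"))
  if (is(contexts, "NeighborContext")) contexts <- list(contexts)
  maxNeighbors <- assert_positive_int(maxNeighbors, "maxNeighbors")
  m <- embMatrix(emb)
  n <- maxNeighbors + 1L
  d <- embDim(emb)
  inputs <- vector("list", length(contexts))
  masks <- vector("list", length(contexts))
  targets <- vector("list", length(contexts))
  for (i in seq_along(contexts)) {
    ctx <- contexts[[i]]
    stopifnot(is(ctx, "NeighborContext"))
    k <- length(ctx@neighbors)
    if (k > maxNeighbors)
      stop("context for ", ctx@center, " has ", k,
           " neighbors; model capacity is ", maxNeighbors)
    if (k == 0)
      stop("degree-0 context cannot enter an attention batch")
    need <- c(ctx@center, ctx@neighbors)
    if (!all(need %in% rownames(m)))
      stop("embedding does not cover: ",
           paste(setdiff(need, rownames(m)), collapse = ", "))
    I <- matrix(0, n, d)
    I[seq_len(k + 1L), ] <- m[need, , drop = FALSE]
    inputs[[i]] <- I
    masks[[i]] <- c(rep(TRUE, k + 1L), rep(FALSE, n - k - 1L))
    targets[[i]] <- c(ctx@distances, rep(NA_real_, maxNeighbors - k))
  }
  new("TrainingBatch", inputs = inputs, masks = masks, targets = targets,
      contexts = contexts)
}

# Row-wise softmax with -Inf masking, numerically stabilized.
row_softmax <- function(s) {
  mx <- apply(s, 1, max)
  e <- exp(s - mx)
  e[!is.finite(s)] <- 0
  e / rowSums(e)
}

# Full forward pass for one context. Returns intermediates for backprop.
attn_forward_one <- function(p, heads, dk, I, mask) {
  n <- nrow(I)
  A <- Q <- K <- V <- O <- vector("list", heads)
  for (i in seq_len(heads)) {
    Q[[i]] <- I %*% p$Wq[[i]]
    K[[i]] <- I %*% p$Wk[[i]]
    V[[i]] <- I %*% p$Wv[[i]]
    S <- Q[[i]] %*% t(K[[i]]) / sqrt(dk)
    S[, !mask] <- -Inf
    A[[i]] <- row_softmax(S)
    O[[i]] <- A[[i]] %*% V[[i]]
  }
  Ocat <- do.call(cbind, O)
  Ofin <- if (heads > 1) Ocat %*% p$Wout else Ocat
  Ofin[!mask, ] <- 0
  x <- as.vector(t(Ofin))  # row-major flatten: node blocks contiguous
  h1pre <- drop(x %*% p$W1) + p$b1
  h1 <- pmax(h1pre, 0)
  dpred <- drop(h1 %*% p$W2) + p$b2
  list(Q = Q, K = K, V = V, A = A, Ocat = Ocat, x = x,
       h1pre = h1pre, h1 = h1, dpred = dpred)
}

# Backprop for one context; returns gradient list matching p's shapes.
# ddpred is dLoss/ddpred (already masked).
attn_backward_one <- function(p, heads, dk, I, mask, fwd, ddpred) {
  g <- list(Wq = vector("list", heads), Wk = vector("list", heads),
            Wv = vector("list", heads))
  g$W2 <- outer(fwd$h1, ddpred)
  g$b2 <- ddpred
  dh1 <- drop(p$W2 %*% ddpred)
  dh1pre <- dh1 * (fwd$h1pre > 0)
  g$W1 <- outer(fwd$x, dh1pre)
  g$b1 <- dh1pre
  dx <- drop(p$W1 %*% dh1pre)
  n <- nrow(I)
  dOfin <- matrix(dx, n, length(dx) / n, byrow = TRUE)
  dOfin[!mask, ] <- 0
  if (heads > 1) {
    g$Wout <- t(fwd$Ocat) %*% dOfin
    dOcat <- dOfin %*% t(p$Wout)
  } else {
    dOcat <- dOfin
  }
  for (i in seq_len(heads)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    dOi <- dOcat[, cols, drop = FALSE]
    dA <- dOi %*% t(fwd$V[[i]])
    dV <- t(fwd$A[[i]]) %*% dOi
    A <- fwd$A[[i]]
    dS <- A * (dA - rowSums(dA * A))
    dQ <- dS %*% fwd$K[[i]] / sqrt(dk)
    dK <- t(dS) %*% fwd$Q[[i]] / sqrt(dk)
    g$Wq[[i]] <- t(I) %*% dQ
    g$Wk[[i]] <- t(I) %*% dK
    g$Wv[[i]] <- t(I) %*% dV
  }
  g
}

# Extract the center's neighbor weights from per-head attention matrices:
# average the center row over heads, drop the self column and padded
# columns, renormalize.
extract_weights <- function(A, mask, k) {
  row1 <- Reduce(`+`, lapply(A, function(a) a[1, ])) / length(A)
  w <- row1[1L + seq_len(k)]
  w / sum(w)
}

#' Run the attention model forward over a batch
#'
#' Pure (no training) forward pass: per context it returns the estimated
#' center-neighbor distances from the MLP head (NA at padded slots) and
#' the per-context attention weight vector — the center row of the
#' (head-averaged) attention matrix restricted to real neighbor columns and
#' renormalized. When targets are present the masked mean squared
#' distance-regression error is also returned.
#'
#' @param model an [AttentionModel-class] (training not required).
#' @param batch a [TrainingBatch-class].
#' @return list with elements \code{distances} (list of numeric vectors),
#'   \code{weights} (list of [WeightVector-class]) and \code{loss}
#'   (mean squared error over real neighbor slots, averaged over contexts).
#' @export
attentionForward <- function(model, batch) {
  stopifnot(is(model, "AttentionModel"), is(batch, "TrainingBatch"))
  p <- model@params
  tag <- if (model@heads == 1L) "1H" else "MH"
  nctx <- length(batch@inputs)
  distances <- vector("list", nctx)
  weights <- vector("list", nctx)
  losses <- numeric(nctx)
  for (i in seq_len(nctx)) {
    I <- batch@inputs[[i]]
    if (ncol(I) != model@dModel || nrow(I) != model@maxNeighbors + 1L)
      stop("batch shape does not match the model (dModel/maxNeighbors)")
    mask <- batch@masks[[i]]
    fwd <- attn_forward_one(p, model@heads, model@dK, I, mask)
    k <- sum(mask) - 1L
    d <- fwd$dpred
    d[seq_len(length(d)) > k] <- NA_real_
    distances[[i]] <- d
    w <- extract_weights(fwd$A, mask, k)
    weights[[i]] <- new("WeightVector",
                        weights = setNames(w,
                          batch@contexts[[i]]@neighbors),
                        mode = tag)
    tgt <- batch@targets[[i]][seq_len(k)]
    losses[i] <- mean((d[seq_len(k)] - tgt)^2)
  }
  list(distances = distances, weights = weights, loss = mean(losses))
}

#' Train the attention model on the distance-regression task
#'
#' Minimizes the masked mean squared error between the MLP's estimated
#' distances and the true center-neighbor Euclidean distances in embedding
#' space, by seeded mini-batch Adam. This is the unsupervised learning
#' signal that gives the attention weights their geometric meaning: no node
#' labels are involved. Returns the trained model and the per-epoch mean
#' training loss.
#'
#' @param model an [AttentionModel-class].
#' @param contexts list of [NeighborContext-class] objects (non-empty).
#' @param emb the [NodeEmbedding-class] the distances live in.
#' @param epochs training epochs (default 100); 0 returns the model
#'   unchanged with an empty history.
#' @param learningRate Adam step size (default 1e-3).
#' @param batchSize mini-batch size (default 32).
#' @param seed integer seed for shuffling.
#' @return list with elements \code{model} (trained
#'   [AttentionModel-class]) and \code{history} (numeric, one mean loss per
#'   epoch).
#' @export
trainAttention <- function(model, contexts, emb, epochs = 100,
                           learningRate = 1e-3, batchSize = 32, seed = 1) {
  stopifnot(is(model, "AttentionModel"))
  if (length(contexts) == 0) stop("no training contexts")
  epochs <- as.integer(epochs)
  if (epochs < 0) stop("epochs must be >= 0")
  if (epochs == 0) return(list(model = model, history = numeric(0)))
  batchSize <- assert_positive_int(batchSize, "batchSize")
  batch <- buildTrainingBatch(contexts, emb, model@maxNeighbors)
  p <- model@params
  flat <- flatten_params(p, model@heads)
  mAd <- lapply(flat, function(x) x * 0)
  vAd <- lapply(flat, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  nctx <- length(batch@inputs)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(nctx)
      eploss <- 0
      for (start in seq(1, nctx, by = batchSize)) {
        ids <- ord[start:min(start + batchSize - 1L, nctx)]
        acc <- lapply(flat, function(x) x * 0)
        bloss <- 0
        for (i in ids) {
          I <- batch@inputs[[i]]
          mask <- batch@masks[[i]]
          fwd <- attn_forward_one(p, model@heads, model@dK, I, mask)
          k <- sum(mask) - 1L
          tgt <- batch@targets[[i]][seq_len(k)]
          resid <- fwd$dpred[seq_len(k)] - tgt
          bloss <- bloss + mean(resid^2)
          ddpred <- numeric(model@maxNeighbors)
          ddpred[seq_len(k)] <- 2 * resid / k
          g <- attn_backward_one(p, model@heads, model@dK, I, mask,
                                 fwd, ddpred)
          gf <- flatten_params(g, model@heads)
          for (j in seq_along(acc)) acc[[j]] <- acc[[j]] + gf[[j]]
        }
        nb <- length(ids)
        bloss <- bloss / nb
        if (!is.finite(bloss))
          stop("non-finite training loss; reduce the learning rate")
        eploss <- eploss + bloss * nb
        step <- step + 1L
        for (j in seq_along(acc)) {
          gj <- acc[[j]] / nb
          mAd[[j]] <- b1 * mAd[[j]] + (1 - b1) * gj
          vAd[[j]] <- b2 * vAd[[j]] + (1 - b2) * gj^2
          mhat <- mAd[[j]] / (1 - b1^step)
          vhat <- vAd[[j]] / (1 - b2^step)
          flat[[j]] <- flat[[j]] - learningRate * mhat / (sqrt(vhat) + eps)
        }
        p <- unflatten_params(flat, p, model@heads)
      }
      history[ep] <- eploss / nctx
    }
  })
  model@params <- p
  model@trained <- TRUE
  list(model = model, history = history)
}

# Parameter list <-> flat list-of-arrays helpers (named, stable order).
flatten_params <- function(p, heads) {
  out <- list()
  for (nm in c("Wq", "Wk", "Wv"))
    for (i in seq_len(heads)) out[[paste0(nm, i)]] <- p[[nm]][[i]]
  if (!is.null(p$Wout)) out$Wout <- p$Wout
  out$W1 <- p$W1; out$b1 <- p$b1; out$W2 <- p$W2; out$b2 <- p$b2
  out
}

unflatten_params <- function(flat, proto, heads) {
  p <- proto
  for (nm in c("Wq", "Wk", "Wv"))
    for (i in seq_len(heads)) p[[nm]][[i]] <- flat[[paste0(nm, i)]]
  if (!is.null(proto$Wout)) p$Wout <- flat$Wout
  p$W1 <- flat$W1; p$b1 <- flat$b1; p$W2 <- flat$W2; p$b2 <- flat$b2
  p
}

#' Attention weights for a single neighborhood context
#'
#' Convenience wrapper: builds the padded input for one context, runs
#' [attentionForward()], and returns the center's attention weight vector,
#' tagged \code{"1H"} for a one-head model or \code{"MH"} for a multi-head
#' model.
#'
#' @param model an [AttentionModel-class].
#' @param ctx a [NeighborContext-class] with at least one neighbor.
#' @param emb the [NodeEmbedding-class].
#' @return a [WeightVector-class].
#' @export
attentionWeights <- function(model, ctx, emb) {
  batch <- buildTrainingBatch(list(ctx), emb, model@maxNeighbors)
  attentionForward(model, batch)$weights[[1]]
}

#' Save / load an attention model
#'
#' Serializes the full parameter set and architecture to a single
#' self-describing file (R's native serialization), so a trained model can
#' be reloaded for weight extraction in a later session.
#'
#' @param model an [AttentionModel-class].
#' @param path file path.
#' @return \code{saveAttentionModel} returns \code{path} invisibly;
#'   \code{loadAttentionModel} returns the [AttentionModel-class].
#' @export
saveAttentionModel <- function(model, path) {
  stopifnot(is(model, "AttentionModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveAttentionModel
#' @export
loadAttentionModel <- function(path) {
  model <- readRDS(path)
  if (!is(model, "AttentionModel"))
    stop("file does not contain an AttentionModel")
  validObject(model)
  model
}
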