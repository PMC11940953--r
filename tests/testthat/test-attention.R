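test_that("model construction enforces the architecture", {
  m <- buildAttentionModel(dModel = 16, heads = 1, maxNeighbors = 10,
                           seed = 1)
  # MLP sizes (n*d, n*d/2, n-1) with n = 11
  expect_equal(dim(m@params$W1), c(11 * 16, 11 * 16 / 2))
  expect_equal(dim(m@params$W2), c(11 * 16 / 2, 10))
  expect_null(m@params$Wout)

  m4 <- buildAttentionModel(dModel = 16, heads = 4, maxNeighbors = 10,
                            seed = 1)
  expect_equal(m4@dK, 4L)
  expect_equal(dim(m4@params$Wq[[1]]), c(16, 4))
  expect_equal(dim(m4@params$Wout), c(16, 16))
  expect_error(buildAttentionModel(16, 3, 10, 1), "divisible")
})

test_that("forward weights are masked-normalized and match the oracle", {
  fx <- random_graph_embedding(20, 0.3, 16, seed = 21)
  ctxs <- contexts_for_graph(fx$graph, fx$emb, maxNeighbors = 6)
  for (heads in c(1, 4)) {
    model <- buildAttentionModel(16, heads, 6, seed = 31)
    batch <- buildTrainingBatch(ctxs, fx$emb, 6)
    out <- attentionForward(model, batch)
    for (i in seq_along(ctxs)) {
      k <- length(ctxs[[i]]@neighbors)
      w <- weightValues(out$weights[[i]])
      expect_length(w, k)              # padded slots carry no weight
      expect_true(all(w > 0))
      expect_equal(sum(w), 1, tolerance = 1e-12)
      # padded distance slots are NA
      expect_true(all(is.na(out$distances[[i]][seq_len(6) > k])))
      # center-row scaled-dot-product oracle, computed independently
      expect_equal(unname(w),
                   oracle_attention_weights(model, ctxs[[i]], fx$emb),
                   tolerance = 1e-10)
    }
    expect_identical(modeTag(out$weights[[1]]),
                     if (heads == 1) "1H" else "MH")
  }
})

test_that("a singleton neighborhood always gets weight one", {
  g <- graph_from_pairs("u v")
  m <- matrix(rnorm(16), 2, 8, dimnames = list(c("u", "v"), NULL))
  emb <- embedding_from_matrix(m)
  ctx <- neighborContext(g, emb, "u", 5, 1)
  model <- buildAttentionModel(8, 2, 5, seed = 7)
  expect_equal(unname(weightValues(attentionWeights(model, ctx, emb))), 1)
})

test_that("weights are equivariant under neighbor permutation", {
  fx <- random_graph_embedding(15, 0.5, 8, seed = 13)
  model <- buildAttentionModel(8, 2, 8, seed = 3)
  ctxs <- contexts_for_graph(fx$graph, fx$emb, maxNeighbors = 8)
  ctx <- ctxs[[which.max(vapply(ctxs, function(cx)
    length(cx@neighbors), numeric(1)))]]
  k <- length(ctx@neighbors)
  set.seed(1)
  perm <- sample.int(k)
  ctxP <- new("NeighborContext", center = ctx@center,
              neighbors = ctx@neighbors[perm],
              distances = ctx@distances[perm],
              maxNeighbors = ctx@maxNeighbors,
              fullDegree = ctx@fullDegree)
  w <- weightValues(attentionWeights(model, ctx, fx$emb))
  wP <- weightValues(attentionWeights(model, ctxP, fx$emb))
  expect_equal(unname(wP), unname(w[perm]), tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  # tiny architecture so central differences are cheap and well-conditioned
  fx <- random_graph_embedding(8, 0.6, 4, seed = 5)
  ctxs <- contexts_for_graph(fx$graph, fx$emb, maxNeighbors = 3)[1:2]
  model <- buildAttentionModel(4, 2, 3, seed = 11)
  batch <- buildTrainingBatch(ctxs, fx$emb, 3)
  p <- model@params
  lossAt <- function(p) {
    tot <- 0
    for (i in seq_along(ctxs)) {
      fwd <- walkaggr:::attn_forward_one(p, 2L, 2L, batch@inputs[[i]],
                                         batch@masks[[i]])
      k <- sum(batch@masks[[i]]) - 1L
      tot <- tot + mean((fwd$dpred[seq_len(k)] -
                           batch@targets[[i]][seq_len(k)])^2)
    }
    tot / length(ctxs)
  }
  # analytic gradient, averaged over the two contexts
  gtot <- NULL
  for (i in seq_along(ctxs)) {
    I <- batch@inputs[[i]]; mask <- batch@masks[[i]]
    fwd <- walkaggr:::attn_forward_one(p, 2L, 2L, I, mask)
    k <- sum(mask) - 1L
    resid <- fwd$dpred[seq_len(k)] - batch@targets[[i]][seq_len(k)]
    dd <- numeric(3); dd[seq_len(k)] <- 2 * resid / k
    g <- walkaggr:::attn_backward_one(p, 2L, 2L, I, mask, fwd, dd)
    gf <- walkaggr:::flatten_params(g, 2L)
    gtot <- if (is.null(gtot)) gf else
      Map(`+`, gtot, gf)
  }
  gtot <- lapply(gtot, function(x) x / length(ctxs))
  flat <- walkaggr:::flatten_params(p, 2L)
  eps <- 1e-5
  set.seed(99)
  for (nm in names(flat)) {
    idx <- sample(length(flat[[nm]]), min(4, length(flat[[nm]])))
    for (j in idx) {
      pp <- flat; pp[[nm]][j] <- pp[[nm]][j] + eps
      pm <- flat; pm[[nm]][j] <- pm[[nm]][j] - eps
      num <- (lossAt(walkaggr:::unflatten_params(pp, p, 2L)) -
                lossAt(walkaggr:::unflatten_params(pm, p, 2L))) / (2 * eps)
      expect_equal(gtot[[nm]][j], num, tolerance = 1e-5)
    }
  }
})

test_that("training reduces the distance-regression loss and is seeded", {
  fx <- random_graph_embedding(25, 0.25, 8, seed = 17)
  ctxs <- contexts_for_graph(fx$graph, fx$emb, maxNeighbors = 5)[1:20]
  model <- buildAttentionModel(8, 1, 5, seed = 23)
  batch <- buildTrainingBatch(ctxs, fx$emb, 5)
  loss0 <- attentionForward(model, batch)$loss
  tr <- trainAttention(model, ctxs, fx$emb, epochs = 50,
                       learningRate = 1e-3, batchSize = 8, seed = 41)
  expect_length(tr$history, 50)
  expect_true(all(is.finite(tr$history)))
  lossT <- attentionForward(tr$model, batch)$loss
  expect_lt(lossT, loss0)
  expect_true(tr$model@trained)

  # zero epochs: untouched parameters, empty history
  tr0 <- trainAttention(model, ctxs, fx$emb, epochs = 0, seed = 41)
  expect_identical(tr0$model@params, model@params)
  expect_length(tr0$history, 0)

  # identical seed and config reproduce the loss trajectory exactly
  tr2 <- trainAttention(model, ctxs, fx$emb, epochs = 50,
                        learningRate = 1e-3, batchSize = 8, seed = 41)
  expect_identical(tr$history, tr2$history)
})

test_that("attention models survive a save/load round trip", {
  model <- buildAttentionModel(8, 2, 4, seed = 2)
  f <- tempfile(fileext = ".rds")
  saveAttentionModel(model, f)
  back <- loadAttentionModel(f)
  expect_identical(back@params, model@params)
  expect_equal(back@heads, 2L)
})
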