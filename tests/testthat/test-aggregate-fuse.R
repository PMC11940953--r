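test_that("mean and weighted aggregation agree with direct arithmetic", {
  g <- graph_from_pairs(c("u a", "u b"))
  m <- rbind(u = c(0, 0), a = c(1, 0), b = c(0, 1))
  emb <- embedding_from_matrix(m)
  ctx <- neighborContext(g, emb, "u", 10, 1)
  expect_equal(meanAggregate(ctx, emb), c(0.5, 0.5))

  wv <- function(w) new("WeightVector", weights = setNames(w, c("a", "b")),
                        mode = "N")
  expect_equal(weightedAggregate(ctx, wv(c(1 - 1e-12, 1e-12)), emb),
               c(1, 0), tolerance = 1e-9)
  expect_equal(weightedAggregate(ctx, wv(c(0.6, 0.4)), emb), c(0.6, 0.4))

  # single neighbor: its own vector
  ctxa <- neighborContext(graph_from_pairs("u a"), emb, "u", 10, 1)
  expect_equal(meanAggregate(ctxa, emb), c(1, 0))

  # misalignment errors
  bad <- new("WeightVector", weights = c(a = 0.5, b = 0.25, c = 0.25),
             mode = "N")
  expect_error(weightedAggregate(ctx, bad, emb), "length")
})

test_that("uniform weights reproduce the mean aggregator exactly", {
  fx <- random_graph_embedding(30, 0.2, 6, seed = 51)
  ctxs <- contexts_for_graph(fx$graph, fx$emb, maxNeighbors = 30)
  for (ctx in ctxs) {
    k <- length(ctx@neighbors)
    u <- new("WeightVector",
             weights = setNames(rep(1 / k, k), ctx@neighbors), mode = "N")
    expect_equal(weightedAggregate(ctx, u, fx$emb),
                 meanAggregate(ctx, fx$emb), tolerance = 1e-12)
  }
})

test_that("stacked aggregation equals the dense weight-matrix product", {
  for (s in 1:20) {
    n <- sample(10:50, 1)
    fx <- random_graph_embedding(n, 0.3, 5, seed = 600 + s)
    nodes <- nodeNames(fx$graph)
    R <- embMatrix(fx$emb)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    agg <- matrix(NA_real_, n, 5, dimnames = list(nodes, NULL))
    for (u in nodes) {
      ctx <- neighborContext(fx$graph, fx$emb, u, maxNeighbors = n,
                             seed = 1)
      if (length(ctx@neighbors) == 0) {
        agg[u, ] <- 0
        next
      }
      w <- nonlearningWeights(ctx, "N")
      W[u, names(weightValues(w))] <- weightValues(w)
      agg[u, ] <- weightedAggregate(ctx, w, fx$emb)
      # convexity: inside the coordinate-wise hull of neighbor vectors
      nb <- R[ctx@neighbors, , drop = FALSE]
      expect_true(all(agg[u, ] <= apply(nb, 2, max) + 1e-12))
      expect_true(all(agg[u, ] >= apply(nb, 2, min) - 1e-12))
    }
    expect_equal(agg, W %*% R, tolerance = 1e-10,
                 ignore_attr = "dimnames")
  }
})

test_that("localVectors applies the identity fallback to isolated nodes", {
  g <- graph_from_pairs(c("a b", "c c"))  # c is isolated
  m <- matrix(rnorm(9), 3, 3, dimnames = list(c("a", "b", "c"), NULL))
  emb <- embedding_from_matrix(m)
  expect_warning(loc <- localVectors(g, emb, "N"), "degree-0")
  expect_equal(embMatrix(loc)["c", ], m["c", ])
  expect_equal(embMatrix(loc)["a", ], m["b", ])  # sole neighbor
})

test_that("concatenation puts the self vector first", {
  fx <- random_graph_embedding(12, 0.4, 7, seed = 71)
  loc <- suppressWarnings(localVectors(fx$graph, fx$emb, "N"))
  cc <- concatRepresentations(fx$emb, loc)
  expect_equal(embDim(cc), 14)
  expect_equal(embMatrix(cc)[, 1:7], embMatrix(fx$emb))
  expect_equal(embMatrix(cc)[, 8:14], embMatrix(loc)[rownames(
    embMatrix(fx$emb)), ])
  # node-set mismatch is an error listing the missing node
  short <- embedding_from_matrix(embMatrix(loc)[-1, , drop = FALSE])
  expect_error(concatRepresentations(fx$emb, short), "v1")
})

test_that("PCA fusion is centered, orthonormal and deterministic", {
  set.seed(81)
  m <- matrix(rnorm(40 * 10), 40, 10,
              dimnames = list(paste0("v", 1:40), NULL))
  emb <- embedding_from_matrix(m)
  f <- pcaFuse(emb, 4)
  expect_equal(embDim(f), 4)
  # orthonormal components
  expect_equal(t(f@rotation) %*% f@rotation, diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  # identical input rows stay identical (centering kills constant data)
  const <- embedding_from_matrix(matrix(3, 20, 6,
             dimnames = list(paste0("c", 1:20), NULL)))
  fc <- pcaFuse(const, 2)
  expect_true(all(abs(embMatrix(fc)) < 1e-12))
  # variance bound against the eigendecomposition oracle
  cm <- scale(m, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(cm) / (nrow(m) - 1), symmetric = TRUE)$values
  fusedVar <- sum(apply(embMatrix(f), 2, var))
  expect_lt(fusedVar, sum(ev) + 1e-10)
  expect_equal(fusedVar, sum(ev[1:4]), tolerance = 1e-10)
  # full rank retained: total variance preserved
  fAll <- pcaFuse(emb, 10)
  expect_equal(sum(apply(embMatrix(fAll), 2, var)), sum(ev),
               tolerance = 1e-10)
  # bit-determinism under the sign convention
  expect_identical(embMatrix(pcaFuse(emb, 4)), embMatrix(f))
  expect_error(pcaFuse(emb, 11), "outDim")
})
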