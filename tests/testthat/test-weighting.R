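test_that("neighbor contexts hold Euclidean distances and truncate", {
  m <- rbind(u = c(0, 0), v = c(3, 4))
  g <- graph_from_pairs("u v")
  emb <- embedding_from_matrix(m)
  ctx <- neighborContext(g, emb, "u", maxNeighbors = 10, seed = 1)
  expect_equal(ctx@distances, 5)  # 3-4-5 triangle
  expect_equal(ctx@fullDegree, 1L)

  # degree below the cap: everything kept, canonical order
  star4 <- graph_from_pairs(paste("hub", paste0("s", 1:4)))
  m4 <- matrix(rnorm(10), 5, 2,
               dimnames = list(c("hub", paste0("s", 1:4)), NULL))
  ctx4 <- neighborContext(star4, embedding_from_matrix(m4), "hub",
                          maxNeighbors = 10, seed = 1)
  expect_identical(ctx4@neighbors, paste0("s", 1:4))

  # degree above the cap: seeded sample of exactly maxNeighbors, repeatable
  star25 <- graph_from_pairs(paste("hub", paste0("s", 1:25)))
  m25 <- matrix(rnorm(52), 26, 2,
                dimnames = list(c("hub", paste0("s", 1:25)), NULL))
  e25 <- embedding_from_matrix(m25)
  c1 <- neighborContext(star25, e25, "hub", maxNeighbors = 10, seed = 3)
  c2 <- neighborContext(star25, e25, "hub", maxNeighbors = 10, seed = 3)
  expect_length(c1@neighbors, 10)
  expect_identical(c1@neighbors, c2@neighbors)
  expect_equal(c1@fullDegree, 25L)
})

test_that("sigmoid distance normalization matches its closed forms", {
  expect_equal(normalizeDistance(0, "N"), 0.5)
  expect_equal(normalizeDistance(0, "F"), 0.5)
  # frozen high-precision evaluations of 1/(1+e^d) and 1/(1+e^-d)
  expect_equal(normalizeDistance(1, "N"), 0.26894142136999512, tolerance = 1e-12)
  expect_equal(normalizeDistance(2, "F"), 0.88079707797788231, tolerance = 1e-12)
  # complementarity and monotonicity
  d <- seq(0, 5, by = 0.25)
  expect_equal(normalizeDistance(d, "N") + normalizeDistance(d, "F"),
               rep(1, length(d)))
  expect_true(all(diff(normalizeDistance(d, "N")) < 0))
  expect_true(all(diff(normalizeDistance(d, "F")) > 0))
  expect_error(normalizeDistance(Inf, "N"), "finite")
})

test_that("closed-form weights match the frozen worked example", {
  # equal distances: softmax symmetry
  w0 <- nonlearningWeights(context_with_distances(c(2, 2, 2)), "N")
  expect_equal(unname(weightValues(w0)), rep(1 / 3, 3))

  # distances (1, 2): frozen values from independent evaluation of the
  # normalize-then-softmax chain
  wN <- nonlearningWeights(context_with_distances(c(1, 2)), "N")
  expect_equal(unname(weightValues(wN)), c(0.5374, 0.4626),
               tolerance = 1e-3)
  wF <- nonlearningWeights(context_with_distances(c(1, 2)), "F")
  expect_equal(unname(weightValues(wF)), c(0.4626, 0.5374),
               tolerance = 1e-3)
  expect_identical(modeTag(wN), "N")
  expect_error(nonlearningWeights(context_with_distances(numeric(0))),
               "no neighbors")
})

test_that("weights normalize and are monotone in distance", {
  for (ctx in random_contexts(200, seed = 8)) {
    wN <- weightValues(nonlearningWeights(ctx, "N"))
    wF <- weightValues(nonlearningWeights(ctx, "F"))
    expect_lt(abs(sum(wN) - 1), 1e-9)
    expect_lt(abs(sum(wF) - 1), 1e-9)
    ord <- order(ctx@distances)
    if (length(ord) > 1 && !anyDuplicated(ctx@distances)) {
      expect_true(all(diff(wN[ord]) < 0))  # N: closer => heavier
      expect_true(all(diff(wF[ord]) > 0))  # F: farther => heavier
    }
  }
})

test_that("the weighting policy dispatcher routes and tags correctly", {
  ctx <- context_with_distances(c(0.5, 1.5))
  direct <- nonlearningWeights(ctx, "N")
  via <- selectWeighting(ctx, "N")
  expect_identical(weightValues(via), weightValues(direct))

  model <- buildAttentionModel(dModel = 8, heads = 1, maxNeighbors = 4,
                               seed = 1)
  m <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(c("u", "x1", "x2"), NULL))
  emb <- embedding_from_matrix(m)
  ctx2 <- new("NeighborContext", center = "u",
              neighbors = c("x1", "x2"),
              distances = c(1, 2), maxNeighbors = 4L, fullDegree = 2L)
  # hybrid: low-degree node goes to attention ...
  w1 <- selectWeighting(ctx2, "1H+N", model = model, degreeThreshold = 10,
                        emb = emb)
  expect_identical(modeTag(w1), "1H")
  # ... high-degree node falls back to the closed form
  ctx25 <- context_with_distances(rnorm(4)^2, maxNeighbors = 4,
                                  fullDegree = 25)
  w2 <- selectWeighting(ctx25, "1H+N", model = model, degreeThreshold = 10,
                        emb = emb)
  expect_identical(modeTag(w2), "N")
  expect_error(selectWeighting(ctx2, "MH"), "AttentionModel")
})
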