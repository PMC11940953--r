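test_that("edge lists are read into simple symmetric graphs", {
  g <- graph_from_pairs(c("a b", "b c"))
  expect_equal(numNodes(g), 3)
  expect_equal(numEdges(g), 2)
  expect_setequal(neighborsOf(g, "b"), c("a", "c"))
  # symmetry both ways
  expect_true("b" %in% neighborsOf(g, "a"))
  expect_true("b" %in% neighborsOf(g, "c"))

  # duplicates collapsed, self-loops dropped
  g2 <- graph_from_pairs(c("a b", "b a", "a a"))
  expect_equal(numNodes(g2), 2)
  expect_equal(numEdges(g2), 1)

  # empty file
  g3 <- graph_from_pairs(character(0))
  expect_equal(numNodes(g3), 0)
  expect_equal(numEdges(g3), 0)

  # node order is first appearance, ids stay opaque strings
  g4 <- graph_from_pairs(c("07 3", "3 b"))
  expect_identical(nodeNames(g4), c("07", "3", "b"))
})

test_that("malformed edge lists fail with the offending line", {
  f <- tempfile()
  writeLines(c("a b", "loner"), f)
  expect_error(suppressMessages(readEdgelist(f)), "line 2")
  expect_error(readEdgelist(tempfile()), "not found")
})

test_that("label tables are parsed with single- and multi-label lines", {
  f <- tempfile()
  writeLines(c("n1 A", "n2 B"), f)
  lt <- readLabelTable(f)
  expect_false(isMultilabel(lt))
  expect_equal(labelUniverse(lt), c("A", "B"))
  expect_equal(labelsOf(lt, "n1"), "A")

  writeLines(c("n1 A,B"), f)
  lt2 <- readLabelTable(f)
  expect_true(isMultilabel(lt2))
  expect_setequal(labelsOf(lt2, "n1"), c("A", "B"))

  writeLines(c("n1"), f)
  expect_error(readLabelTable(f), "no labels")

  writeLines(c("n1 A", "n1 B"), f)
  expect_warning(lt3 <- readLabelTable(f), "unioned")
  expect_setequal(labelsOf(lt3, "n1"), c("A", "B"))
})

test_that("embedding files round-trip losslessly", {
  m <- matrix(c(pi, -1 / 3, 1e-17, 2, exp(1), -7), 2, 3,
              dimnames = list(c("a", "b"), NULL))
  emb <- embedding_from_matrix(m)
  f <- tempfile()
  writeEmbeddings(emb, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  expect_identical(lines[1], "2 3")
  back <- readEmbeddings(f)
  expect_equal(embMatrix(back), m, tolerance = 1e-12)
  zero <- embedding_from_matrix(
    matrix(numeric(0), 0, 3, dimnames = list(character(0), NULL)))
  expect_error(writeEmbeddings(zero, f), "empty")
})

test_that("planted-partition generator matches its combinatorial oracle", {
  fx <- three_cliques(seed = 1)
  # 3 * C(10,2) edges; brute-force count over all within-block pairs
  expected <- sum(vapply(split(paste0("n", 1:30),
                               rep(1:3, each = 10)), function(blk)
    nrow(t(combn(blk, 2))), numeric(1)))
  expect_equal(numEdges(fx$graph), expected)  # 135
  expect_equal(numEdges(fx$graph), 135)
  # labels equal connected-component identity in the extreme regime
  comp <- igraph::components(fx$graph@graph)$membership
  lab <- vapply(nodeNames(fx$graph),
                function(u) labelsOf(fx$labels, u), character(1))
  expect_equal(length(unique(paste(comp, lab))), 3)
  expect_false(isMultilabel(fx$labels))

  # determinism
  a <- sbmGraph(300, 3, 0.05, 0.005, seed = 7)
  b <- sbmGraph(300, 3, 0.05, 0.005, seed = 7)
  expect_identical(igraph::as_edgelist(a$graph@graph),
                   igraph::as_edgelist(b$graph@graph))
  expect_error(sbmGraph(30, 3, 0.01, 0.5, seed = 1), "pIn")
})

test_that("planted-partition densities track pIn and pOut", {
  nin <- nout <- ein <- eout <- 0
  for (s in 1:20) {
    fx <- sbmGraph(60, 3, 0.2, 0.05, seed = 100 + s)
    blk <- rep(1:3, each = 20)
    el <- igraph::as_edgelist(fx$graph@graph)
    bi <- blk[match(el[, 1], nodeNames(fx$graph))]
    bj <- blk[match(el[, 2], nodeNames(fx$graph))]
    ein <- ein + sum(bi == bj)
    eout <- eout + sum(bi != bj)
    nin <- nin + 3 * choose(20, 2)
    nout <- nout + choose(60, 2) - 3 * choose(20, 2)
  }
  # within 3 binomial standard errors
  expect_lt(abs(ein / nin - 0.2), 3 * sqrt(0.2 * 0.8 / nin))
  expect_lt(abs(eout / nout - 0.05), 3 * sqrt(0.05 * 0.95 / nout))
})

test_that("multilabel generator honors its degenerate and error cases", {
  a <- multilabelGraph(60, 4, 0.3, 0.02, labelsPerNode = c(1, 3), seed = 5)
  b <- multilabelGraph(60, 4, 0.3, 0.02, labelsPerNode = c(1, 3), seed = 5)
  expect_identical(igraph::as_edgelist(a$graph@graph),
                   igraph::as_edgelist(b$graph@graph))
  expect_true(isMultilabel(a$labels))
  # every label used
  expect_length(labelUniverse(a$labels), 4)

  # fixed one label per node reduces to single-label behavior
  s <- multilabelGraph(40, 4, 0.3, 0.02, labelsPerNode = 1, seed = 2)
  expect_false(isMultilabel(s$labels))

  # pIn == pOut: label-independent Erdos-Renyi limit is accepted
  er <- multilabelGraph(40, 4, 0.1, 0.1, labelsPerNode = c(1, 2), seed = 3)
  expect_s4_class(er$graph, "NodeGraph")

  expect_error(multilabelGraph(40, 2, 0.3, 0.02, labelsPerNode = c(1, 3),
                               seed = 1), "labelsPerNode")
})
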