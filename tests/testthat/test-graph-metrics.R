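test_that("the sparsity grid has the documented cardinality", {
  expect_length(sparsityGrid(), 49)
  expect_equal(sparsityGrid(0.1, 0.1, 0.05), 0.1)
  expect_equal(sparsityGrid(0.1, 0.2, 0.05), c(0.1, 0.15, 0.2))
  expect_error(sparsityGrid(0.5, 0.2), "degenerate")
  expect_error(sparsityGrid(0.1, 0.2, 0), "degenerate")
})

test_that("thresholding keeps the floor(s*N(N-1)/2) strongest edges", {
  cm <- randomW(90, seed = 3)
  expect_equal(igraph::gsize(thresholdBySparsity(cm, 0.02)), 80)
  g1 <- thresholdBySparsity(randomW(12, seed = 4), 1)
  expect_equal(igraph::gsize(g1), 66)  # complete K_12
  cm20 <- randomW(20, seed = 5)
  for (s in sparsityGrid(0.05, 0.5, 0.15))
    expect_equal(igraph::gsize(thresholdBySparsity(cm20, s)),
                 floor(s * 20 * 19 / 2))
  expect_error(thresholdBySparsity(cm20, 0), "sparsity")
  expect_error(thresholdBySparsity(cm20, 1.2), "sparsity")
})

test_that("ties at the cut are broken lexicographically", {
  W <- matrix(0.8, 6, 6); diag(W) <- 1
  cm <- new("ConnectivityMatrix", nodes = 1:6, W = W)
  g <- thresholdBySparsity(cm, 0.5)   # 7 of 15 equal-weight pairs
  got <- igraph::as_edgelist(g)
  got <- got[order(got[, 1], got[, 2]), ]
  expect_equal(unname(got), unname(connectionIndexPairs(6)[1:7, ]))
})

test_that("complete and star graphs reproduce hand-enumerated metrics", {
  k5 <- adjToGraph(matrix(1, 5, 5) - diag(5))
  m <- globalMetrics(k5, nNulls = 3, seed = 1)
  expect_equal(unname(m["Cp"]), 1)
  expect_equal(unname(m["Lp"]), 1)
  expect_equal(unname(m["Eglobal"]), 1)
  nk <- nodalMetrics(k5)
  expect_equal(nk$degree, rep(4, 5))
  expect_equal(nk$betweenness, rep(0, 5))

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  ms <- globalMetrics(star, nNulls = 3, seed = 1)
  expect_equal(unname(ms["Eglobal"]), 0.7)
  expect_equal(unname(ms["Ar"]), -1)
  expect_equal(unname(ms["Cp"]), 0)
  ns <- nodalMetrics(star)
  expect_equal(ns$betweenness, c(6, 0, 0, 0, 0))
})

test_that("modularity of two disjoint cliques is one half", {
  adj <- matrix(0, 10, 10)
  adj[1:5, 1:5] <- 1; adj[6:10, 6:10] <- 1; diag(adj) <- 0
  g <- adjToGraph(adj)
  m <- globalMetrics(g, nNulls = 3, seed = 1)
  expect_equal(unname(m["Q"]), 0.5)
  expect_equal(bruteModularity(adj, rep(1:2, each = 5)), 0.5)
  expect_equal(unname(m["connected"]), 0)
})

test_that("path-graph betweenness matches pair enumeration", {
  p4 <- adjToGraph(rbind(c(0,1,0,0), c(1,0,1,0), c(0,1,0,1), c(0,0,1,0)))
  expect_equal(nodalMetrics(p4)$betweenness, c(0, 2, 2, 0))
})

test_that("metrics agree exactly with a Floyd-Warshall brute-force oracle", {
  set.seed(11)
  for (k in 1:30) {
    n <- sample(4:7, 1)
    adj <- randomConnectedAdj(n, runif(1, 0.35, 0.8))
    g <- adjToGraph(adj)
    m <- globalMetrics(g, nNulls = 2, seed = k)
    expect_equal(unname(m["Lp"]), bruteCharPath(adj), tolerance = 1e-12)
    expect_equal(unname(m["Eglobal"]), bruteGlobalEff(adj), tolerance = 1e-12)
    nt <- nodalMetrics(g)
    expect_equal(nt$betweenness, bruteBetweenness(adj), tolerance = 1e-12)
    d <- fwDistances(adj); diag(d) <- NA
    expect_equal(nt$shortestPath, rowMeans(d, na.rm = TRUE), tolerance = 1e-12,
                 ignore_attr = TRUE)
    inv <- 1 / d; inv[is.na(inv)] <- 0
    expect_equal(nt$efficiency, rowSums(inv) / (n - 1), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(nt$degree, rowSums(adj), ignore_attr = TRUE)
  }
})

test_that("small-world sigma is identically gamma over lambda", {
  set.seed(13)
  for (k in 1:5) {
    g <- adjToGraph(randomConnectedAdj(12, 0.4))
    m <- globalMetrics(g, nNulls = 5, seed = k)
    expect_equal(unname(m["sigma"]), unname(m["gamma"] / m["lambda"]),
                 tolerance = 1e-9)
  }
})

test_that("AUC over thresholds is the trapezoidal integral", {
  grid <- sparsityGrid()
  expect_equal(aucOverThresholds(rep(3, 49), grid), 3 * 0.48,
               tolerance = 1e-12)
  expect_equal(aucOverThresholds(c(0, 0.5, 1), c(0, 0.5, 1)), 0.5)
  set.seed(17)
  v <- runif(49)
  expect_equal(aucOverThresholds(v, grid), bruteTrapz(grid, v),
               tolerance = 1e-12)
  expect_error(aucOverThresholds(1:3, 1:4), "same length")
  expect_error(aucOverThresholds(1, 1), "at least 2")
})

test_that("rewired nulls preserve the degree sequence and the seed", {
  set.seed(19)
  for (k in 1:20) {
    g <- adjToGraph(randomConnectedAdj(sample(8:14, 1), 0.4))
    gn <- generateNull(g, seed = k)
    expect_equal(sort(igraph::degree(gn)), sort(igraph::degree(g)))
    expect_equal(igraph::degree(gn), igraph::degree(g))  # per node
  }
  g <- adjToGraph(ringOfCliques(4, 5))
  a <- generateNull(g, seed = 99)
  b <- generateNull(g, seed = 99)
  expect_identical(igraph::as_edgelist(a), igraph::as_edgelist(b))
})

test_that("rewiring destroys clustering in a clique-rich graph", {
  g <- adjToGraph(ringOfCliques(4, 5))
  tri <- function(x) sum(igraph::count_triangles(x)) / 3
  t0 <- tri(g)
  reduced <- vapply(1:100, function(k) tri(generateNull(g, seed = k)) < t0,
                    logical(1))
  expect_gte(mean(reduced), 0.95)
})

test_that("gamma and lambda are near one for an already-random graph", {
  set.seed(23)
  g0 <- igraph::sample_gnp(60, 0.15)
  while (!igraph::is_connected(g0)) g0 <- igraph::sample_gnp(60, 0.15)
  g <- generateNull(g0, seed = 1)   # input is itself a rewired random graph
  m <- globalMetrics(g, nNulls = 20, seed = 2)
  expect_lt(abs(m["lambda"] - 1), 0.05)
  expect_lt(abs(m["gamma"] - 1), 0.35)
})

test_that("the per-subject panel aggregates AUCs consistently", {
  cm <- randomW(12, seed = 29)
  grid <- sparsityGrid(0.2, 0.5, 0.1)
  panel <- subjectMetricPanel(cm, grid, nNulls = 2, seed = 5)
  expect_length(panel$globalAuc, 11)
  expect_length(panel$nodalAuc, 5 * 12)
  expect_length(panel$connected, length(grid))
  deg <- subset(panel$nodal, metric == "degree" & node == 1)
  expect_equal(unname(panel$nodalAuc["degree.1"]),
               bruteTrapz(grid, deg$value[order(deg$threshold)]),
               tolerance = 1e-12)
})
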