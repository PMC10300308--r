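#' Sparsity threshold grid
#'
#' Inclusive arithmetic grid of sparsity values at which weighted networks
#' are binarised. The defaults (0.02 to 0.5 in steps of 0.01) give exactly
#' 49 thresholds, the grid used for metric-versus-sparsity curves and their
#' AUC aggregation.
#'
#' @param lo,hi,step grid bounds and increment.
#' @return numeric vector of thresholds.
#' @examples
#' length(sparsityGrid())  # 49
#' @export
sparsityGrid <- function(lo = 0.02, hi = 0.5, step = 0.01) {
  if (!(lo <= hi) || step <= 0) stop("degenerate grid: need lo <= hi, step > 0")
  n <- floor((hi - lo) / step + 1e-9) + 1L
  lo + step * (0:(n - 1L))
}

#' Binarise a weighted network at a sparsity threshold
#'
#' Retains the \eqn{k = \lfloor s\,N(N-1)/2 \rfloor} largest off-diagonal
#' weights as edges of a binary undirected graph. Ties at the cut are
#' broken deterministically by lexicographic (i, j) node-pair order.
#'
#' @param cm a [ConnectivityMatrix-class] (or symmetric numeric matrix).
#' @param s sparsity in (0, 1].
#' @return an \pkg{igraph} undirected graph with vertex attribute
#'   \code{roi} and graph attribute \code{sparsity}.
#' @export
thresholdBySparsity <- function(cm, s) {
  if (is(cm, "ConnectivityMatrix")) { W <- cm@W; nodes <- cm@nodes }
  else { W <- cm; nodes <- seq_len(nrow(cm)) }
  if (!is.numeric(s) || length(s) != 1 || s <= 0 || s > 1)
    stop("sparsity must lie in (0, 1]")
  n <- nrow(W)
  pairs <- upperPairs(n)
  w <- W[pairs]
  k <- floor(s * n * (n - 1) / 2)
  ord <- order(-w, pairs[, 1], pairs[, 2])
  keep <- pairs[ord[seq_len(k)], , drop = FALSE]
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  igraph::V(g)$roi <- nodes
  g$sparsity <- s
  g
}

# Global efficiency: mean of 1/d over ordered pairs, unreachable pairs
# contributing 0; equals 1 on a complete graph.
globalEfficiency <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

# Characteristic path length: mean shortest path over reachable ordered
# pairs only (disconnected graphs are handled on reachable pairs, with the
# connectedness flag recorded by the caller).
charPathLength <- function(g) {
  d <- igraph::distances(g)
  d <- d[row(d) != col(d)]
  d <- d[is.finite(d)]
  if (!length(d)) stop("graph has no reachable pairs")
  mean(d)
}

localClustering <- function(g) {
  c <- igraph::transitivity(g, type = "local", isolates = "zero")
  ifelse(is.nan(c), 0, c)
}

#' Global graph-metric panel for one binary graph
#'
#' Computes the 11-metric global panel: assortativity \eqn{A_r}, modularity
#' \eqn{Q} (greedy agglomerative Newman optimisation, deterministic),
#' hierarchy \eqn{H_r} (exponent \eqn{\beta} of \eqn{C \propto k^{-\beta}}
#' fitted over nodes with \eqn{C_i > 0, k_i > 1}), global and local
#' efficiency, clustering coefficient \eqn{C_p}, characteristic path length
#' \eqn{L_p} (reachable pairs), synchronization
#' \eqn{S_r = \lambda_2/\lambda_{max}} of the graph Laplacian, and the
#' null-normalised \eqn{\gamma = C_p/\langle C_p^{rand}\rangle},
#' \eqn{\lambda = L_p/\langle L_p^{rand}\rangle} and small-worldness
#' \eqn{\sigma = \gamma/\lambda}, using degree-preserving rewired null
#' graphs.
#'
#' @param g binary undirected \pkg{igraph} graph (with edges).
#' @param nNulls number of rewired null graphs for gamma/lambda (default
#'   100; reducible).
#' @param rewireMultiplier rewiring attempts per null as a multiple of the
#'   edge count.
#' @param seed seed for null generation (local RNG scope).
#' @return named numeric vector of the 11 metrics plus a \code{connected}
#'   0/1 flag.
#' @export
globalMetrics <- function(g, nNulls = 100L, rewireMultiplier = 10,
                          seed = NULL) {
  if (igraph::gsize(g) == 0) stop("graph has no edges")
  cp <- mean(localClustering(g))
  lp <- charPathLength(g)
  eg <- globalEfficiency(g)
  deg <- igraph::degree(g)
  el <- mean(vapply(seq_len(igraph::vcount(g)), function(v) {
    nb <- as.integer(igraph::neighbors(g, v))
    if (length(nb) < 2) return(0)
    globalEfficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1)))
  ar <- suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  q <- igraph::modularity(igraph::cluster_fast_greedy(g))
  ci <- localClustering(g)
  fit <- deg > 1 & ci > 0
  hr <- if (sum(fit) >= 2 && stats::sd(log(deg[fit])) > 0)
    -unname(stats::coef(stats::lm(log(ci[fit]) ~ log(deg[fit])))[2]) else NA_real_
  lap <- igraph::laplacian_matrix(g, sparse = FALSE)
  ev <- sort(eigen(lap, symmetric = TRUE, only.values = TRUE)$values)
  sr <- ev[2] / ev[length(ev)]
  nullStats <- withSeed(seed, vapply(seq_len(nNulls), function(k) {
    gn <- igraph::rewire(g, igraph::keeping_degseq(
      niter = max(1, round(rewireMultiplier * igraph::gsize(g)))))
    c(mean(localClustering(gn)), charPathLength(gn))
  }, numeric(2)))
  cpNull <- mean(nullStats[1, ]); lpNull <- mean(nullStats[2, ])
  gamma <- if (cpNull > 0) cp / cpNull else NA_real_
  lambda <- lp / lpNull
  c(Ar = ar, Q = q, Hr = hr, Eglobal = eg, Elocal = el, Cp = cp,
    gamma = gamma, lambda = lambda, sigma = gamma / lambda, Lp = lp,
    Sr = sr, connected = as.numeric(igraph::is_connected(g)))
}

#' Nodal graph-metric table for one binary graph
#'
#' Per-node degree centrality, betweenness centrality (each unordered pair
#' counted once, with fractional credit split across equally short paths),
#' nodal clustering coefficient, nodal shortest path length (mean distance
#' to reachable others; 0 for isolated nodes) and nodal efficiency (mean
#' inverse distance to all others, in [0, 1]).
#'
#' @param g binary undirected \pkg{igraph} graph (with edges).
#' @return data.frame with columns node, degree, betweenness, clustering,
#'   shortestPath, efficiency.
#' @export
nodalMetrics <- function(g) {
  if (igraph::gsize(g) == 0) stop("graph has no edges")
  n <- igraph::vcount(g)
  d <- igraph::distances(g)
  diag(d) <- NA
  spl <- apply(d, 1, function(r) {
    r <- r[is.finite(r) & !is.na(r)]
    if (length(r)) mean(r) else 0
  })
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  eff <- rowSums(inv, na.rm = TRUE) / (n - 1)
  data.frame(node = seq_len(n),
             degree = as.numeric(igraph::degree(g)),
             betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
             clustering = localClustering(g),
             shortestPath = as.numeric(spl),
             efficiency = as.numeric(eff))
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of the per-threshold metric values against the
#' sparsity grid, the scalar summary used as classifier input.
#'
#' @param values per-threshold metric values.
#' @param grid sparsity thresholds (same length, >= 2).
#' @return the trapezoidal AUC.
#' @export
aucOverThresholds <- function(values, grid) {
  if (length(values) != length(grid))
    stop("values and grid must have the same length")
  if (length(grid) < 2) stop("need at least 2 thresholds")
  trapz(grid, values)
}

#' Degree-preserving rewired null graph
#'
#' Randomises a binary graph by double-edge swaps that keep every node's
#' degree fixed, the reference model for the normalised metrics gamma,
#' lambda and sigma. If few swappable edge pairs exist the result is the
#' best effort achieved within the attempt budget.
#'
#' @param g binary undirected \pkg{igraph} graph.
#' @param nRewires swap attempts (default 10 per edge).
#' @param seed RNG seed (local scope); same seed, same null.
#' @return a rewired graph with the identical degree sequence.
#' @export
generateNull <- function(g, nRewires = 10 * igraph::gsize(g), seed = NULL) {
  if (igraph::gsize(g) < 2)
    stop("need >= 2 edges to rewire")
  withSeed(seed,
    igraph::rewire(g, igraph::keeping_degseq(niter = max(1, nRewires))))
}

#' Metric panel across the sparsity grid for one subject
#'
#' Thresholds a subject's weighted network at every sparsity in the grid,
#' computes the global panel and nodal table at each threshold, and
#' aggregates each metric into its trapezoidal AUC. This is the per-subject
#' feature extractor feeding group statistics and classification.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param sparsities threshold grid (default [sparsityGrid()]).
#' @param nNulls,rewireMultiplier null-model settings per threshold.
#' @param seed base seed; threshold index is folded in for independence.
#' @return list with \code{global} (long data.frame threshold x metric),
#'   \code{nodal} (long data.frame threshold x node x metric),
#'   \code{globalAuc} (named length-11 vector), \code{nodalAuc} (named
#'   length-5N vector, metric-major then node) and \code{connected}
#'   (per-threshold flag).
#' @export
subjectMetricPanel <- function(cm, sparsities = sparsityGrid(),
                               nNulls = 100L, rewireMultiplier = 10,
                               seed = 1L) {
  gm <- vector("list", length(sparsities))
  nm <- vector("list", length(sparsities))
  for (k in seq_along(sparsities)) {
    g <- thresholdBySparsity(cm, sparsities[k])
    gm[[k]] <- globalMetrics(g, nNulls = nNulls,
                             rewireMultiplier = rewireMultiplier,
                             seed = seed + 1000L * k)
    nm[[k]] <- nodalMetrics(g)
  }
  gmat <- do.call(rbind, gm)
  connected <- gmat[, "connected"]
  gmat <- gmat[, setdiff(colnames(gmat), "connected"), drop = FALSE]
  globalAuc <- apply(gmat, 2, aucOverThresholds, grid = sparsities)
  nodalNames <- c("degree", "betweenness", "clustering", "shortestPath",
                  "efficiency")
  nNodes <- nrow(nm[[1]])
  nodalAuc <- unlist(lapply(nodalNames, function(m) {
    vals <- vapply(nm, function(tab) tab[[m]], numeric(nNodes))
    a <- apply(vals, 1, aucOverThresholds, grid = sparsities)
    names(a) <- paste0(m, ".", seq_len(nNodes))
    a
  }))
  globalLong <- data.frame(
    threshold = rep(sparsities, each = ncol(gmat)),
    metric = rep(colnames(gmat), length(sparsities)),
    value = as.numeric(t(gmat)))
  nodalLong <- do.call(rbind, lapply(seq_along(sparsities), function(k) {
    tab <- nm[[k]]
    data.frame(threshold = sparsities[k],
               node = rep(tab$node, length(nodalNames)),
               metric = rep(nodalNames, each = nNodes),
               value = unlist(tab[nodalNames], use.names = FALSE))
  }))
  list(global = globalLong, nodal = nodalLong, globalAuc = globalAuc,
       nodalAuc = nodalAuc, connected = connected)
}
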