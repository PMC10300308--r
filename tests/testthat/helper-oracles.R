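# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and igraph) so that agreement is evidence, not tautology.

# direct term-by-term KL summation on discrete mass vectors
bruteKL <- function(p, q) {
  total <- 0
  for (k in seq_along(p)) {
    if (p[k] > 0) {
      if (q[k] == 0) return(Inf)
      total <- total + p[k] * log(p[k] / q[k])
    }
  }
  total
}

bruteJS <- function(p, q) {
  m <- 0.5 * (p + q)
  0.5 * (bruteKL(p, m) + bruteKL(q, m))
}

asDensity <- function(mass, grid = seq_along(mass))
  new("DensityEstimate", grid = as.numeric(grid),
      mass = mass / sum(mass), bandwidth = 1)

# Floyd-Warshall all-pairs distances on an adjacency matrix
fwDistances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# shortest-path counts by BFS layer dynamic programming from one source
pathCounts <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); cnt <- numeric(n)
  dist[s] <- 0; cnt[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (w in which(adj[v, ] == 1)) {
      if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; nxt <- c(nxt, w) }
      if (dist[w] == dist[v] + 1) cnt[w] <- cnt[w] + cnt[v]
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, cnt = cnt)
}

# pair-enumeration betweenness: each unordered pair once, fractional credit
bruteBetweenness <- function(adj) {
  n <- nrow(adj)
  bc <- pc <- vector("list", n)
  for (s in seq_len(n)) pc[[s]] <- pathCounts(adj, s)
  bet <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    dst <- pc[[s]]$dist[t]
    if (is.infinite(dst) || pc[[s]]$cnt[t] == 0) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (pc[[s]]$dist[v] + pc[[t]]$dist[v] == dst)
        bet[v] <- bet[v] + pc[[s]]$cnt[v] * pc[[t]]$cnt[v] / pc[[s]]$cnt[t]
    }
  }
  bet
}

bruteCharPath <- function(adj) {
  d <- fwDistances(adj)
  d <- d[row(d) != col(d)]
  mean(d[is.finite(d)])
}

bruteGlobalEff <- function(adj) {
  n <- nrow(adj)
  d <- fwDistances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

bruteModularity <- function(adj, membership) {
  m <- sum(adj) / 2
  q <- 0
  n <- nrow(adj)
  deg <- rowSums(adj)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (membership[i] == membership[j])
      q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

bruteTrapz <- function(x, y) {
  s <- 0
  for (k in seq_len(length(x) - 1))
    s <- s + (x[k + 1] - x[k]) * (y[k] + y[k + 1]) / 2
  s
}

bruteAuc <- function(scores, labels, case = "PD") {
  xs <- scores[labels == case]; ys <- scores[labels != case]
  tot <- 0
  for (a in xs) for (b in ys) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(xs) * length(ys))
}

brutePooledT <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  t <- (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
  p <- 2 * pt(abs(t), nx + ny - 2, lower.tail = FALSE)
  c(t = t, p = p)
}

# random connected undirected graph adjacency (retries until connected)
randomConnectedAdj <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0L, n, n)
    up <- upper.tri(adj)
    adj[up] <- rbinom(sum(up), 1, p)
    adj <- adj + t(adj)
    if (all(is.finite(fwDistances(adj)))) return(adj)
  }
}

adjToGraph <- function(adj)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
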