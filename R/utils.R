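# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so package randomness never perturbs user code.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Upper-triangle (i < j) node-index pairs in lexicographic order, as a
# two-column matrix. This single ordering defines the connection feature
# layout everywhere in the package.
upperPairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

# Stratified K-fold assignment: within each class, subjects are permuted and
# dealt round-robin so fold sizes differ by at most one per class.
stratifiedFolds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k)
      stop("stratification error: class '", cl, "' has fewer subjects (",
           length(idx), ") than folds (", k, ")")
    folds[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# Vectorised pooled-variance (Student) two-sample t-test over the columns of
# two matrices. Returns t, two-sided p, group means and sds. Columns with
# zero pooled variance get t = 0 / p = 1 when the means agree, otherwise
# +-Inf / p = smallest double (flagged by the caller as degenerate).
colTtests <- function(X, Y) {
  nx <- nrow(X); ny <- nrow(Y)
  stopifnot(nx >= 2, ny >= 2, ncol(X) == ncol(Y))
  mx <- colMeans(X); my <- colMeans(Y)
  vx <- (colSums(X^2) - nx * mx^2) / (nx - 1)
  vy <- (colSums(Y^2) - ny * my^2) / (ny - 1)
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)   # guard fp cancellation
  sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  t <- (mx - my) / se
  df <- nx + ny - 2
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  zero <- se == 0
  if (any(zero)) {
    eq <- zero & (mx == my)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & (mx != my)
    t[ne] <- sign(mx[ne] - my[ne]) * Inf
    p[ne] <- .Machine$double.xmin
  }
  list(t = t, p = p, meanX = mx, meanY = my,
       sdX = sqrt(vx), sdY = sqrt(vy), degenerate = zero & (mx != my))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
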