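#' Kernel bandwidth rules
#'
#' Silverman's rule-of-thumb \eqn{h = 0.9\,\min(s, IQR/1.34)\, n^{-1/5}}
#' (default) or Scott's \eqn{h = 1.06\, s\, n^{-1/5}}. When the IQR is zero
#' but the SD is not, the SD alone is used so the bandwidth stays positive.
#'
#' @param x numeric sample.
#' @param rule `"silverman"` or `"scott"`.
#' @return bandwidth (0 for a zero-spread sample).
#' @export
kdeBandwidth <- function(x, rule = c("silverman", "scott")) {
  rule <- match.arg(rule)
  n <- length(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  if (rule == "scott") return(1.06 * s * n^(-1 / 5))
  iqr <- stats::IQR(x) / 1.34
  a <- if (iqr > 0) min(s, iqr) else s
  0.9 * a * n^(-1 / 5)
}

#' Shared evaluation grid for a subject
#'
#' One uniform grid spanning the subject's pooled intensity range extended
#' by three times the largest per-ROI bandwidth on each side, so that every
#' ROI density of the subject lives on a common support.
#'
#' @param s a [ROISampleSet-class].
#' @param gridSize number of grid points G (default 256).
#' @param bandwidthRule see [kdeBandwidth()].
#' @return list with `grid` (length G) and `bandwidths` (one per ROI).
#' @export
sharedGrid <- function(s, gridSize = 256L, bandwidthRule = "silverman") {
  stopifnot(is(s, "ROISampleSet"), gridSize >= 2)
  h <- vapply(s@samples, kdeBandwidth, numeric(1), rule = bandwidthRule)
  pooled <- range(unlist(s@samples, use.names = FALSE))
  pad <- 3 * max(h, 0)
  if (pad == 0) pad <- max(1e-8, abs(pooled[1]) * 1e-8 + 1e-8)
  list(grid = seq(pooled[1] - pad, pooled[2] + pad, length.out = gridSize),
       bandwidths = h)
}

#' Estimate a discretised PDF by Gaussian kernel density estimation
#'
#' Evaluates a Gaussian-kernel KDE of the sample on the supplied grid and
#' renormalises the evaluations to probability masses summing to one, so
#' divergences become finite sums. A zero-spread sample degrades to a point
#' mass at the nearest grid point, with a warning.
#'
#' @param samples numeric intensity sample (length >= 2).
#' @param grid shared evaluation grid (strictly increasing).
#' @param bandwidth kernel bandwidth; if `NULL`, chosen by
#'   `bandwidthRule`.
#' @param bandwidthRule see [kdeBandwidth()].
#' @return a [DensityEstimate-class].
#' @examples
#' g <- seq(-4, 4, length.out = 128)
#' p <- estimatePdf(rnorm(500), g)
#' sum(p@mass)
#' @export
estimatePdf <- function(samples, grid, bandwidth = NULL,
                        bandwidthRule = "silverman") {
  if (!length(samples)) stop("empty sample")
  if (length(samples) < 2) stop("need >= 2 samples")
  if (!all(is.finite(samples))) stop("samples must be finite")
  if (is.null(bandwidth)) bandwidth <- kdeBandwidth(samples, bandwidthRule)
  if (bandwidth == 0) {
    warning("zero-spread sample: falling back to a point mass")
    mass <- numeric(length(grid))
    mass[which.min(abs(grid - samples[1]))] <- 1
    return(new("DensityEstimate", grid = as.numeric(grid), mass = mass,
               bandwidth = 0))
  }
  f <- rowMeans(stats::dnorm(outer(grid, samples, "-"), sd = bandwidth))
  tot <- sum(f)
  if (tot <= 0) stop("grid does not cover the sample support")
  new("DensityEstimate", grid = as.numeric(grid), mass = f / tot,
      bandwidth = bandwidth)
}

checkSameGrid <- function(P, Q) {
  if (length(P@grid) != length(Q@grid) ||
      max(abs(P@grid - Q@grid)) > 0)
    stop("density estimates must share the same grid")
}

#' Kullback-Leibler divergence between discretised densities
#'
#' \eqn{D_{KL}(P\|Q) = \sum_g P_g \ln(P_g/Q_g)} in nats, with the
#' convention \eqn{0 \ln(0/q) = 0}. Returns `Inf` when P places mass where
#' Q has none; KL is asymmetric, which is exactly why the network weight
#' uses the Jensen-Shannon divergence instead.
#'
#' @param P,Q [DensityEstimate-class] objects on the same grid.
#' @return divergence in nats (>= 0, possibly `Inf`).
#' @export
klDivergence <- function(P, Q) {
  checkSameGrid(P, Q)
  p <- P@mass; q <- Q@mass
  pos <- p > 0
  if (any(pos & q == 0)) return(Inf)
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Jensen-Shannon divergence between discretised densities
#'
#' \eqn{D_{JS}(P\|Q) = \tfrac12[D_{KL}(P\|M) + D_{KL}(Q\|M)]} with the
#' mixture \eqn{M = (P+Q)/2}. Symmetric, always finite, and bounded in
#' \eqn{[0, \ln 2]} in nats.
#'
#' @inheritParams klDivergence
#' @return divergence in nats, in \eqn{[0, \ln 2]}.
#' @export
jsDivergence <- function(P, Q) {
  checkSameGrid(P, Q)
  p <- P@mass; q <- Q@mass
  m <- (p + q) / 2
  pp <- p > 0; qq <- q > 0
  d <- 0.5 * (sum(p[pp] * log(p[pp] / m[pp])) +
              sum(q[qq] * log(q[qq] / m[qq])))
  min(max(d, 0), log(2))   # clip fp noise at the analytic bounds
}

#' JSSE similarity weight
#'
#' The network edge weight \eqn{W = \exp(-D_{JS}(P\|Q))}, which maps the
#' bounded divergence onto \eqn{[e^{-\ln 2}, 1] = [0.5, 1]}: identical
#' densities give 1, disjoint supports give 0.5, and no weight is ever
#' negative.
#'
#' @inheritParams klDivergence
#' @return similarity in \eqn{[0.5, 1]}.
#' @export
jsseSimilarity <- function(P, Q) exp(-jsDivergence(P, Q))

# All-pairs JS divergence on a G x N column-stochastic mass matrix;
# returns the symmetric N x N divergence matrix. Vectorised over j for
# each i so network assembly is O(N^2 G) with N cached densities.
jsDivergenceMatrix <- function(M) {
  n <- ncol(M)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    p <- M[, i]
    Qs <- M[, (i + 1L):n, drop = FALSE]
    Mid <- (p + Qs) / 2
    t1 <- p * log(p / Mid)
    t1[p == 0, ] <- 0
    t2 <- Qs * log(Qs / Mid)
    t2[Qs == 0] <- 0
    d <- 0.5 * (colSums(t1) + colSums(t2))
    d <- pmin(pmax(d, 0), log(2))
    D[i, (i + 1L):n] <- d
    D[(i + 1L):n, i] <- d
  }
  D
}

#' Build a subject's JSSE metabolic network
#'
#' Estimates every ROI's intensity density on one shared per-subject grid
#' and assembles the similarity matrix
#' \eqn{W_{ij} = \exp(-D_{JS}(P_i\|P_j))}, computed once per unordered
#' pair, with unit diagonal. The shared grid guarantees a common support;
#' the result is symmetric with all weights in \eqn{[0.5, 1]}.
#'
#' @param s a [ROISampleSet-class].
#' @param gridSize grid points G for the shared grid (default 256).
#' @param bandwidthRule see [kdeBandwidth()].
#' @return a [ConnectivityMatrix-class].
#' @examples
#' co <- generateCohort(cohortSpec(nPerGroup = 2, nRois = 4,
#'                                 voxelsPerRoi = 60, seed = 3))
#' buildNetwork(cohortSubjects(co)[[1]], gridSize = 64)
#' @export
buildNetwork <- function(s, gridSize = 256L, bandwidthRule = "silverman") {
  stopifnot(is(s, "ROISampleSet"))
  sg <- sharedGrid(s, gridSize, bandwidthRule)
  dens <- lapply(seq_along(s@roiIds), function(k)
    estimatePdf(s@samples[[k]], sg$grid, bandwidth =
                if (sg$bandwidths[k] > 0) sg$bandwidths[k] else NULL))
  M <- vapply(dens, slot, numeric(gridSize), "mass")
  W <- exp(-jsDivergenceMatrix(M))
  diag(W) <- 1
  dimnames(W) <- list(s@roiIds, s@roiIds)
  new("ConnectivityMatrix", nodes = s@roiIds, W = W)
}

#' Connectivity matrix text I/O
#'
#' `writeConnectivityCsv()` writes the square matrix as CSV with the ROI
#' codes as header/rownames; `writeEdgeTsv()` writes the long upper-triangle
#' form (roi_i, roi_j, weight). Weights are serialised with 17 significant
#' digits so both dialects read back bit-exactly via their `read*`
#' counterparts.
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param path output file.
#' @param meta optional character metadata lines written as leading
#'   \code{#} comments (ignored by the readers).
#' @return the path invisibly; readers return a [ConnectivityMatrix-class].
#' @export
writeConnectivityCsv <- function(cm, path, meta = NULL) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  w <- format(cm@W, digits = 17, trim = TRUE, scientific = FALSE)
  tab <- cbind(roi = cm@nodes, w)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(meta, con)
  utils::write.table(tab, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = c("roi", cm@nodes))
  invisible(path)
}

#' @rdname writeConnectivityCsv
#' @export
readConnectivityCsv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  nodes <- as.integer(tab[[1]])
  W <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(W) <- list(nodes, nodes)
  new("ConnectivityMatrix", nodes = nodes, W = W)
}

#' @rdname writeConnectivityCsv
#' @export
writeEdgeTsv <- function(cm, path) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  pairs <- upperPairs(length(cm@nodes))
  tab <- data.frame(roi_i = cm@nodes[pairs[, 1]], roi_j = cm@nodes[pairs[, 2]],
                    weight = format(cm@W[pairs], digits = 17, trim = TRUE,
                                    scientific = FALSE))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConnectivityCsv
#' @export
readEdgeTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  nodes <- sort(unique(c(tab$roi_i, tab$roi_j)))
  n <- length(nodes)
  W <- diag(1, n)
  i <- match(tab$roi_i, nodes); j <- match(tab$roi_j, nodes)
  W[cbind(i, j)] <- tab$weight
  W[cbind(j, i)] <- tab$weight
  dimnames(W) <- list(nodes, nodes)
  new("ConnectivityMatrix", nodes = as.integer(nodes), W = W)
}
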