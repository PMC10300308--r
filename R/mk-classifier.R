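#' Assemble a subject's feature blocks
#'
#' Flattens one subject's network, metric panel and uptake summaries into
#' the five classifier feature blocks: \code{connection} (upper-triangle
#' weights in lexicographic (i < j) pair order, length N(N-1)/2),
#' \code{global} (the 11 global-metric AUCs), \code{nodal} (the 5N
#' nodal-metric AUCs, metric-major then node), and \code{suvMean} /
#' \code{suvMax} (length N each).
#'
#' @param cm a [ConnectivityMatrix-class].
#' @param panel output of [subjectMetricPanel()] for the same subject.
#' @param suv output of [suvFeatures()] for the same subject.
#' @return named list of named numeric vectors (the five blocks).
#' @export
assembleFeatures <- function(cm, panel, suv) {
  stopifnot(is(cm, "ConnectivityMatrix"))
  if (is.null(panel$globalAuc) || is.null(panel$nodalAuc))
    stop("missing metric block: panel must carry globalAuc and nodalAuc")
  if (is.null(suv$suvMean) || is.null(suv$suvMax))
    stop("missing SUV block")
  n <- length(cm@nodes)
  pairs <- upperPairs(n)
  conn <- cm@W[pairs]
  names(conn) <- paste0("e", cm@nodes[pairs[, 1]], "_", cm@nodes[pairs[, 2]])
  list(connection = conn, global = panel$globalAuc, nodal = panel$nodalAuc,
       suvMean = suv$suvMean, suvMax = suv$suvMax)
}

#' Map connection-feature indices back to edge pairs
#'
#' The inverse of the flattening used by [assembleFeatures()]: feature k of
#' the connection block corresponds to row k of `upper-triangle pairs`.
#'
#' @param n number of nodes.
#' @return two-column integer matrix (i, j), one row per connection feature.
#' @export
connectionIndexPairs <- function(n) upperPairs(n)

#' t-test feature selection
#'
#' Marks the features whose pooled-variance two-sample t-test between the
#' two training classes has p below \code{alpha} (default 0.05), computed
#' on training subjects only. Zero-variance features are excluded with a
#' warning.
#'
#' Non-finite features (e.g. a normalised metric undefined at
#' some threshold) are likewise excluded.
#'
#' @param X training feature matrix (subjects x features).
#' @param labels training group labels (both classes present).
#' @param alpha selection threshold on the uncorrected p value.
#' @param case case-group label.
#' @return logical mask over the columns of \code{X}.
#' @export
selectFeaturesTtest <- function(X, labels, alpha = 0.05, case = "PD") {
  lv <- unique(labels)
  if (length(lv) != 2) stop("both classes must be present in the training set")
  usable <- apply(X, 2, function(col) all(is.finite(col)))
  zeroVar <- usable
  zeroVar[usable] <- apply(X[, usable, drop = FALSE], 2, stats::sd) == 0
  excluded <- !usable | zeroVar
  if (any(excluded))
    warning(sum(excluded),
            " zero-variance or non-finite features excluded from selection")
  mask <- rep(FALSE, ncol(X))
  keep <- which(!excluded)
  if (length(keep)) {
    res <- colTtests(X[labels == case, keep, drop = FALSE],
                     X[labels != case, keep, drop = FALSE])
    mask[keep] <- res$p < alpha
  }
  mask
}

standardizeFit <- function(X) {
  s <- apply(X, 2, stats::sd)
  s[s == 0] <- 1
  list(mean = colMeans(X), sd = s)
}

# Non-finite entries (a metric undefined for one subject at one threshold
# can slip past a mask fitted on other subjects) are imputed at the
# training mean, i.e. z = 0, so a single undefined feature cannot poison a
# kernel row.
standardizeApply <- function(X, fit) {
  Z <- sweep(sweep(X, 2, fit$mean, "-"), 2, fit$sd, "/")
  Z[!is.finite(Z)] <- 0
  Z
}

#' Linear kernel on standardised selected features
#'
#' Inner-product kernel between two feature matrices after z-scoring with
#' statistics fitted on the training rows only. An empty feature mask
#' yields an all-zero kernel with a warning.
#'
#' @param A,B feature matrices (rows = subjects) already restricted to the
#'   selected features.
#' @param fit standardisation statistics fitted on the training rows
#'   (means and sds per feature); defaults to fitting on \code{A}.
#' @return kernel matrix \code{nrow(A)} x \code{nrow(B)}.
#' @export
linearKernel <- function(A, B = A, fit = standardizeFit(A)) {
  if (ncol(A) == 0) {
    warning("empty feature mask: zero kernel")
    return(matrix(0, nrow(A), nrow(B)))
  }
  standardizeApply(A, fit) %*% t(standardizeApply(B, fit))
}

#' Convex combination of block kernels
#'
#' \eqn{K = \sum_m \beta_m K_m} with \eqn{\beta} on the simplex
#' (\eqn{\beta_m \ge 0}, \eqn{\sum \beta_m = 1}); positive
#' semidefiniteness is preserved.
#'
#' @param kernels list of equally sized kernel matrices.
#' @param beta numeric weights on the simplex.
#' @return the combined kernel matrix.
#' @export
combineKernels <- function(kernels, beta) {
  if (length(kernels) != length(beta)) stop("one weight per kernel required")
  if (any(beta < 0) || abs(sum(beta) - 1) > 1e-9)
    stop("beta must be non-negative and sum to 1")
  Reduce(`+`, Map(function(K, b) b * K, kernels, beta))
}

#' Simplex grid of kernel weights
#'
#' All weight vectors with entries that are multiples of \code{step} and
#' sum to 1 (e.g. 66 candidates for 3 kernels at step 0.1).
#'
#' @param m number of kernels.
#' @param step grid resolution (1/step must be an integer).
#' @return matrix, one candidate weight vector per row.
#' @export
simplexGrid <- function(m, step = 0.1) {
  units <- round(1 / step)
  if (abs(units - 1 / step) > 1e-9) stop("1/step must be an integer")
  compose <- function(total, parts) {
    if (parts == 1) return(matrix(total, 1, 1))
    do.call(rbind, lapply(0:total, function(k)
      cbind(k, compose(total - k, parts - 1))))
  }
  unname(compose(units, m) / units)
}

# Fit a C-SVC on a precomputed training kernel and return decision values
# for the (training, test) kernel rows. kernlab's decision sign is label-
# order dependent, so the orientation is fixed on training decisions only:
# cases are made to score high.
svmDecision <- function(Ktrain, ytrain, Ktest, cost, case = "PD") {
  y <- factor(ytrain, levels = c(setdiff(unique(ytrain), case), case))
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(Ktrain), y,
                     type = "C-svc", C = cost, scaled = FALSE)
  sv <- kernlab::SVindex(m)
  decTr <- as.numeric(kernlab::predict(
    m, kernlab::as.kernelMatrix(Ktrain[, sv, drop = FALSE]),
    type = "decision"))
  flip <- if (mean(decTr[ytrain == case]) >= mean(decTr[ytrain != case])) 1 else -1
  decTe <- as.numeric(kernlab::predict(
    m, kernlab::as.kernelMatrix(Ktest[, sv, drop = FALSE]),
    type = "decision"))
  list(train = flip * decTr, test = flip * decTe)
}

#' Tie-aware rank AUC
#'
#' Area under the ROC curve computed from the rank statistic (equivalent to
#' the Mann-Whitney U, ties counted half), invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores decision values (higher = more case-like).
#' @param labels true labels.
#' @param case case label.
#' @return AUC in [0, 1].
#' @export
rankAuc <- function(scores, labels, case = "PD") {
  pos <- labels == case
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification performance at a decision threshold
#'
#' Confusion-matrix metrics at the given decision threshold (default 0, the
#' SVM decision boundary) plus the tie-aware rank AUC and the ROC curve.
#'
#' @param scores decision values (higher = more case-like).
#' @param labels true labels.
#' @param case case label (counted as "positive").
#' @param threshold decision threshold.
#' @return list with accuracy, sensitivity, specificity, auc, predicted and
#'   a data.frame \code{roc} of (fpr, tpr) points.
#' @export
evaluateScores <- function(scores, labels, case = "PD", threshold = 0) {
  lv <- unique(labels)
  if (length(lv) != 2 || !case %in% lv) stop("both classes required")
  control <- setdiff(lv, case)
  predicted <- ifelse(scores > threshold, case, control)
  tp <- sum(predicted == case & labels == case)
  fn <- sum(predicted == control & labels == case)
  tn <- sum(predicted == control & labels == control)
  fp <- sum(predicted == case & labels == control)
  cut <- sort(unique(scores), decreasing = TRUE)
  roc <- data.frame(
    fpr = c(0, vapply(cut, function(th)
      sum(scores >= th & labels == control) / sum(labels == control),
      numeric(1))),
    tpr = c(0, vapply(cut, function(th)
      sum(scores >= th & labels == case) / sum(labels == case), numeric(1))))
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       auc = rankAuc(scores, labels, case), predicted = predicted, roc = roc)
}

#' DeLong test for two correlated ROC curves
#'
#' Nonparametric comparison of the AUCs of two models scored on the same
#' subjects, using the DeLong placement-value estimate of the covariance of
#' the paired AUCs, a z-test on the difference and a 95 percent confidence
#' interval. A zero-variance difference with equal AUCs returns p = 1.
#'
#' @param scores1,scores2 paired decision values of the two models.
#' @param labels true labels (both classes present).
#' @param case case label.
#' @return list with auc1, auc2, diff, z, p, ci (length-2 95 pct CI) and
#'   the variance of the difference.
#' @export
delongTest <- function(scores1, scores2, labels, case = "PD") {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(labels))
  pos <- labels == case
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  placements <- function(s) {
    X <- s[pos]; Y <- s[!pos]
    psi <- outer(X, Y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  p1 <- placements(scores1); p2 <- placements(scores2)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  varDiff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
             (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- p1$auc - p2$auc
  if (varDiff <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
    p <- if (d == 0) 1 else .Machine$double.xmin
  } else {
    z <- d / sqrt(varDiff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  half <- stats::qnorm(0.975) * sqrt(max(varDiff, 0))
  list(auc1 = p1$auc, auc2 = p2$auc, diff = d, z = z, p = p,
       ci = c(d - half, d + half), varDiff = varDiff)
}

#' Default model set
#'
#' The nine classifier models: the two uptake baselines, the three single
#' blocks (Connection, Global, Nodal) and their kernel combinations.
#'
#' @return named list mapping model name to feature-block names.
#' @export
defaultModels <- function() {
  list("SUVmax" = "suvMax", "SUVmean" = "suvMean",
       "C" = "connection", "G" = "global", "N" = "nodal",
       "C+G" = c("connection", "global"),
       "C+N" = c("connection", "nodal"),
       "G+N" = c("global", "nodal"),
       "C+G+N" = c("connection", "global", "nodal"))
}

#' Nested cross-validated multi-kernel SVM classification
#'
#' Stratified outer K-fold evaluation with an inner K-fold loop on every
#' outer-training set that chooses, per model, the kernel weights
#' \eqn{\beta} (simplex grid) and the SVM cost C; the t-test feature mask
#' and the z-scoring statistics are fitted on the outer-training set.
#' Feature selection, standardisation and all hyperparameter choices use
#' training subjects only; out-of-fold decision values are pooled into one
#' ROC per model. Single-block models are the corner cases
#' \eqn{\beta = e_m} of the multi-kernel machine.
#'
#' @param blocks named list of feature matrices (subjects x features), as
#'   assembled by [assembleFeatures()] across subjects.
#' @param labels group label per subject (>= 4 per class).
#' @param models named list of block combinations (default
#'   [defaultModels()]).
#' @param outerFolds,innerFolds fold counts (defaults 10 and 5).
#' @param betaStep simplex grid resolution for kernel weights.
#' @param costGrid SVM cost candidates (default \eqn{2^{-5}..2^5}).
#' @param alpha t-test selection threshold.
#' @param case case label.
#' @param seed seed for the fold assignment (local RNG scope).
#' @return named list of [CVResult-class], one per model.
#' @export
nestedCv <- function(blocks, labels, models = defaultModels(),
                     outerFolds = 10L, innerFolds = 5L, betaStep = 0.1,
                     costGrid = 2^(-5:5), alpha = 0.05, case = "PD",
                     seed = 1L) {
  stopifnot(is.list(blocks), all(vapply(blocks, is.matrix, logical(1))))
  nSub <- length(labels)
  if (min(table(labels)) < 4) stop("need >= 4 subjects per class")
  for (m in models)
    if (!all(m %in% names(blocks)))
      stop("missing block(s): ", paste(setdiff(m, names(blocks)), collapse = ", "))
  withSeed(seed, {
    folds <- stratifiedFolds(labels, outerFolds)
    lapply(stats::setNames(nm = names(models)), function(modelName) {
      useBlocks <- models[[modelName]]
      nb <- length(useBlocks)
      betas <- if (nb == 1) matrix(1, 1, 1) else simplexGrid(nb, betaStep)
      scores <- numeric(nSub)
      foldMasks <- vector("list", outerFolds)
      hyper <- vector("list", outerFolds)
      for (f in seq_len(outerFolds)) {
        tr <- which(folds != f); te <- which(folds == f)
        masks <- list(); Ktr <- list(); Kte <- list()
        for (b in useBlocks) {
          Xb <- blocks[[b]]
          mask <- suppressWarnings(
            selectFeaturesTtest(Xb[tr, , drop = FALSE], labels[tr],
                                alpha = alpha, case = case))
          masks[[b]] <- mask
          Atr <- Xb[tr, mask, drop = FALSE]
          fit <- standardizeFit(Atr)
          Ktr[[b]] <- suppressWarnings(linearKernel(Atr, Atr, fit))
          Kte[[b]] <- suppressWarnings(
            linearKernel(Xb[te, mask, drop = FALSE], Atr, fit))
        }
        # inner loop: choose (beta, C) by pooled inner-validation AUC
        inner <- stratifiedFolds(labels[tr], innerFolds)
        best <- NULL
        for (bi in seq_len(nrow(betas))) {
          Kc <- combineKernels(Ktr, betas[bi, ])
          for (cost in costGrid) {
            innerScores <- numeric(length(tr))
            ok <- TRUE
            for (g in seq_len(innerFolds)) {
              itr <- which(inner != g); ite <- which(inner == g)
              if (length(unique(labels[tr][itr])) < 2 ||
                  length(unique(labels[tr][ite])) < 2) { ok <- FALSE; break }
              dec <- tryCatch(
                svmDecision(Kc[itr, itr, drop = FALSE], labels[tr][itr],
                            Kc[ite, itr, drop = FALSE], cost, case),
                error = function(e) NULL)
              if (is.null(dec)) { ok <- FALSE; break }
              innerScores[ite] <- dec$test
            }
            if (!ok) next
            a <- rankAuc(innerScores, labels[tr], case)
            # ties broken toward larger connection weight, then grid order
            connW <- if ("connection" %in% useBlocks)
              betas[bi, match("connection", useBlocks)] else 0
            if (is.null(best) || a > best$auc + 1e-12 ||
                (abs(a - best$auc) <= 1e-12 && connW > best$connW + 1e-12)) {
              best <- list(auc = a, beta = betas[bi, ], cost = cost,
                           connW = connW)
            }
          }
        }
        if (is.null(best))
          best <- list(auc = NA_real_, beta = betas[1, ], cost = 1, connW = 0)
        KcTr <- combineKernels(Ktr, best$beta)
        KcTe <- combineKernels(Kte, best$beta)
        dec <- svmDecision(KcTr, labels[tr], KcTe, best$cost, case)
        scores[te] <- dec$test
        foldMasks[[f]] <- masks
        hyper[[f]] <- list(beta = stats::setNames(best$beta, useBlocks),
                           cost = best$cost, innerAuc = best$auc)
      }
      ev <- evaluateScores(scores, labels, case)
      new("CVResult", model = modelName, scores = scores,
          labels = as.character(labels), predicted = ev$predicted,
          accuracy = ev$accuracy, sensitivity = ev$sensitivity,
          specificity = ev$specificity, auc = ev$auc, roc = ev$roc,
          foldMasks = foldMasks, hyper = hyper)
    })
  })
}

#' Consensus connections across cross-validation folds
#'
#' Connection features passing the t-test selection in every outer fold
#' form the consensus set; the full selection-frequency table is returned
#' so alternative cutoffs remain recoverable. Effect direction and mean p
#' are taken from the edgewise group tests.
#'
#' @param foldMasks list (one per fold) of logical connection-feature
#'   masks, e.g. \code{lapply(res@foldMasks, `[[`, "connection")}.
#' @param edgeTests data.frame from [edgewiseGroupTest()], rows in the same
#'   canonical upper-triangle order as the connection features.
#' @return list with \code{consensus} (data.frame of edges selected in all
#'   folds: feature index, i, j, frequency, meanP, direction, sorted by
#'   frequency then meanP) and \code{frequency} (table over all selected
#'   edges).
#' @export
consensusConnections <- function(foldMasks, edgeTests) {
  if (!length(foldMasks)) stop("need >= 1 fold")
  sel <- do.call(rbind, lapply(foldMasks, as.logical))
  freq <- colMeans(sel)
  idx <- which(freq > 0)
  tab <- data.frame(feature = idx,
                    i = edgeTests$i[idx], j = edgeTests$j[idx],
                    frequency = freq[idx], meanP = edgeTests$p[idx],
                    direction = edgeTests$direction[idx])
  tab <- tab[order(-tab$frequency, tab$meanP), ]
  rownames(tab) <- NULL
  list(consensus = tab[tab$frequency == 1, ], frequency = tab)
}
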