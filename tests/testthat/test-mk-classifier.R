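test_that("feature blocks have the documented shapes and ordering", {
  cm <- randomW(90, seed = 61)
  panel <- list(globalAuc = stats::setNames(runif(11), paste0("m", 1:11)),
                nodalAuc = stats::setNames(runif(450), paste0("n", 1:450)))
  suv <- list(suvMean = runif(90), suvMax = runif(90))
  fb <- assembleFeatures(cm, panel, suv)
  expect_length(fb$connection, 4005)
  expect_length(fb$global, 11)
  expect_length(fb$nodal, 450)
  expect_length(fb$suvMean, 90)
  cm3 <- randomW(3, seed = 62)
  fb3 <- assembleFeatures(cm3, panel, suv)
  W <- wMatrix(cm3)
  expect_equal(unname(fb3$connection), c(W[1, 2], W[1, 3], W[2, 3]))
  # index <-> pair mapping is a bijection
  pairs <- connectionIndexPairs(90)
  expect_equal(nrow(pairs), 4005)
  expect_equal(nrow(unique(pairs)), 4005)
  expect_true(all(pairs[, 1] < pairs[, 2]))
  expect_error(assembleFeatures(cm3, list(), suv), "missing metric block")
})

test_that("t-test selection is computed on training data with p < alpha", {
  set.seed(63)
  X <- matrix(rnorm(40 * 30), 40)
  lab <- rep(c("PD", "NC"), each = 20)
  X[lab == "PD", 7] <- X[lab == "PD", 7] + 5   # one 5-SD feature
  mask <- selectFeaturesTtest(X, lab)
  expect_true(mask[7])
  # identical groups: nothing selected
  X0 <- rbind(X[1:5, ], X[1:5, ])
  expect_length(which(selectFeaturesTtest(X0, rep(c("PD", "NC"), each = 5))), 0)
  # zero-variance and non-finite features are excluded with a warning
  X[, 2] <- 1; X[, 3] <- NA
  expect_warning(mask2 <- selectFeaturesTtest(X, lab), "excluded")
  expect_false(mask2[2] || mask2[3])
  expect_true(mask2[7])
})

test_that("a 5-SD effect is selected in nearly every resample", {
  hits <- vapply(1:50, function(k) {
    set.seed(k)
    X <- matrix(rnorm(40 * 10), 40)
    lab <- rep(c("PD", "NC"), each = 20)
    X[lab == "PD", 4] <- X[lab == "PD", 4] + 5
    selectFeaturesTtest(X, lab)[4]
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})

test_that("the linear kernel is a standardised inner product", {
  A <- matrix(c(-1, 1), 2, 1)  # already z-scored single feature
  K <- linearKernel(A, A, fit = list(mean = 0, sd = 1))
  expect_equal(K, rbind(c(1, -1), c(-1, 1)), ignore_attr = TRUE)
  set.seed(67)
  X <- matrix(rnorm(12 * 5), 12)
  fit <- jsseNet:::standardizeFit(X)
  Z <- scale(X)
  expect_equal(linearKernel(X, X, fit), Z %*% t(Z), tolerance = 1e-10,
               ignore_attr = TRUE)
  K2 <- linearKernel(X)
  expect_equal(K2, t(K2))
  expect_gte(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_warning(K0 <- linearKernel(X[, 0, drop = FALSE]), "empty feature mask")
  expect_true(all(K0 == 0))
})

test_that("kernel combination is a convex sum preserving PSD", {
  set.seed(71)
  mk <- function() { Z <- matrix(rnorm(36), 6); Z %*% t(Z) }
  Ks <- list(mk(), mk(), mk())
  expect_equal(combineKernels(Ks, c(1, 0, 0)), Ks[[1]])
  expect_equal(combineKernels(list(Ks[[1]], Ks[[1]], Ks[[1]]), rep(1, 3) / 3),
               Ks[[1]], tolerance = 1e-12)
  Kc <- combineKernels(Ks, c(0.2, 0.3, 0.5))
  expect_gte(min(eigen(Kc, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  expect_error(combineKernels(Ks, c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(combineKernels(Ks, c(-0.2, 0.7, 0.5)), "non-negative")
})

test_that("the simplex grid enumerates stars-and-bars candidates", {
  g3 <- simplexGrid(3, 0.1)
  expect_equal(nrow(g3), 66)
  expect_true(all(abs(rowSums(g3) - 1) < 1e-12))
  expect_true(all(g3 >= 0))
  expect_equal(nrow(unique(g3)), 66)
  expect_equal(nrow(simplexGrid(2, 0.5)), 3)
})

test_that("evaluation reproduces confusion-matrix arithmetic and ROC limits", {
  labels <- rep(c("PD", "NC"), c(10, 10))
  scores <- c(rep(1, 9), -1, rep(-1, 8), 1, 1)   # TP 9, FN 1, TN 8, FP 2
  ev <- evaluateScores(scores, labels)
  expect_equal(ev$sensitivity, 0.9)
  expect_equal(ev$specificity, 0.8)
  expect_equal(ev$accuracy, 0.85)
  sep <- evaluateScores(c(2, 3, -1, -2), c("PD", "PD", "NC", "NC"))
  expect_equal(sep$auc, 1)
  expect_equal(max(sep$roc$tpr), 1)
  expect_error(evaluateScores(1:3, rep("PD", 3)), "both classes")
})

test_that("rank AUC matches pair enumeration and is monotone-invariant", {
  set.seed(73)
  for (k in 1:20) {
    n <- sample(6:15, 1)
    lab <- sample(rep(c("PD", "NC"), c(3, n - 3)))
    sc <- sample(seq(-2, 2, 0.5), n, replace = TRUE)  # ties likely
    a <- rankAuc(sc, lab)
    expect_equal(a, bruteAuc(sc, lab), tolerance = 1e-12)
    expect_equal(rankAuc(exp(sc), lab), a, tolerance = 1e-12)
    expect_equal(rankAuc(sc^3, lab), a, tolerance = 1e-12)
  }
})

test_that("DeLong self-comparison and antisymmetry are exact", {
  set.seed(79)
  lab <- rep(c("PD", "NC"), each = 30)
  s1 <- rnorm(60, ifelse(lab == "PD", 1, 0))
  d <- delongTest(s1, s1, lab)
  expect_equal(d$diff, 0)
  expect_equal(d$p, 1)
  s2 <- rnorm(60, ifelse(lab == "PD", 0.5, 0))
  d12 <- delongTest(s1, s2, lab)
  d21 <- delongTest(s2, s1, lab)
  expect_equal(d12$z, -d21$z, tolerance = 1e-12)
  expect_equal(d12$diff, -d21$diff, tolerance = 1e-12)
  expect_equal(d12$auc1, rankAuc(s1, lab), tolerance = 1e-12)
})

test_that("DeLong agrees with an independent reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(83)
  lab <- rep(c("PD", "NC"), each = 40)
  latent <- rnorm(80, ifelse(lab == "PD", 1, 0))
  s1 <- latent + rnorm(80, sd = 0.8)
  s2 <- latent + rnorm(80, sd = 1.2)
  d <- delongTest(s1, s2, lab)
  ref <- pROC::roc.test(
    pROC::roc(lab, s1, levels = c("NC", "PD"), direction = "<", quiet = TRUE),
    pROC::roc(lab, s2, levels = c("NC", "PD"), direction = "<", quiet = TRUE),
    method = "delong", paired = TRUE)
  expect_equal(d$p, unname(ref$p.value), tolerance = 1e-9)
  expect_equal(d$z, unname(ref$statistic), tolerance = 1e-9)
})

test_that("DeLong variance agrees with a bootstrap oracle on synthetic scores", {
  set.seed(89)
  n <- 200
  lab <- rep(c("PD", "NC"), each = n / 2)
  latent <- rnorm(n, ifelse(lab == "PD", 0.8, 0))
  s1 <- latent + rnorm(n, sd = 0.7)
  s2 <- latent + rnorm(n, sd = 1.1)
  d <- delongTest(s1, s2, lab)
  boot <- vapply(1:2000, function(k) {
    idx <- c(sample(which(lab == "PD"), replace = TRUE),
             sample(which(lab == "NC"), replace = TRUE))
    rankAuc(s1[idx], lab[idx]) - rankAuc(s2[idx], lab[idx])
  }, numeric(1))
  expect_lt(abs(d$varDiff - var(boot)) / var(boot), 0.2)
})

test_that("a pure-corner kernel combination reproduces the single kernel", {
  set.seed(97)
  lab <- rep(c("PD", "NC"), each = 10)
  X1 <- matrix(rnorm(20 * 6, ifelse(lab == "PD", 0.8, 0)), 20)
  X2 <- matrix(rnorm(20 * 4), 20)
  K1 <- linearKernel(X1); K2 <- linearKernel(X2)
  tr <- c(1:7, 11:17); te <- setdiff(1:20, tr)
  single <- jsseNet:::svmDecision(K1[tr, tr], lab[tr], K1[te, tr], cost = 1)
  Kc <- combineKernels(list(K1, K2), c(1, 0))
  corner <- jsseNet:::svmDecision(Kc[tr, tr], lab[tr], Kc[te, tr], cost = 1)
  expect_equal(corner$test, single$test, tolerance = 1e-8)
})

test_that("nested CV separates an effect cohort and stays honest on folds", {
  dat <- smallCohortBlocks(nPerGroup = 8, nRois = 8, voxels = 80,
                           affected = 1:3, shift = 1.2, seed = 101)
  res <- suppressWarnings(nestedCv(
    dat$blocks, dat$labels, models = defaultModels()[c("C", "C+G+N")],
    outerFolds = 4, innerFolds = 2, betaStep = 0.5, costGrid = 2^c(-1, 1),
    seed = 7))
  for (r in res) {
    perf <- cvPerformance(r)
    expect_true(all(perf >= 0 & perf <= 1))
    expect_length(r@scores, 16)
    expect_length(r@foldMasks, 4)
    expect_gt(perf["auc"], 0.6)   # strong effect, small n
    # every fold records a simplex-valid beta and a cost from the grid
    for (h in r@hyper) {
      expect_equal(sum(h$beta), 1, tolerance = 1e-9)
      expect_true(h$cost %in% 2^c(-1, 1))
    }
  }
  # determinism under the same seed
  res2 <- suppressWarnings(nestedCv(
    dat$blocks, dat$labels, models = defaultModels()["C"],
    outerFolds = 4, innerFolds = 2, betaStep = 0.5, costGrid = 2^c(-1, 1),
    seed = 7))
  expect_identical(res2[["C"]]@scores, res[["C"]]@scores)
  expect_error(nestedCv(dat$blocks, rep("PD", 16)), "2 groups|both classes|>= 4")
})

test_that("consensus connections are the every-fold intersection", {
  masks <- list(c(TRUE, TRUE, FALSE, TRUE),
                c(TRUE, FALSE, FALSE, TRUE),
                c(TRUE, TRUE, FALSE, TRUE))
  et <- data.frame(i = c(1, 1, 1, 2), j = c(2, 3, 4, 3),
                   p = c(0.01, 0.2, 0.5, 0.03),
                   direction = c("increase", "decrease", "none", "increase"))
  cc <- consensusConnections(masks, et)
  expect_equal(cc$consensus$feature, c(1, 4))
  expect_equal(cc$consensus$direction, c("increase", "increase"))
  # feature 2 selected in 2/3 folds: in the frequency table, not consensus
  expect_equal(cc$frequency$frequency[cc$frequency$feature == 2], 2 / 3)
  one <- consensusConnections(masks[2], et)
  expect_equal(one$consensus$feature, c(1, 4))
  expect_error(consensusConnections(list(), et), "1 fold")
})
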