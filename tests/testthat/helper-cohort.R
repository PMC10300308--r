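# Shared fixture builders: everything is generated in code at test time.

# Feature blocks + labels for a small cohort, end to end. Sized for speed:
# coarse KDE grid, short sparsity grid, 2 rewired nulls.
smallCohortBlocks <- function(nPerGroup = 8, nRois = 8, voxels = 80,
                              affected = integer(0), shift = 0, seed = 5,
                              sparsities = sparsityGrid(0.2, 0.5, 0.1)) {
  co <- generateCohort(cohortSpec(
    nPerGroup = nPerGroup, nRois = nRois, voxelsPerRoi = voxels,
    affectedRois = affected, locationShift = shift, seed = seed))
  nets <- lapply(cohortSubjects(co), buildNetwork, gridSize = 64)
  feats <- lapply(seq_along(nets), function(k) {
    panel <- subjectMetricPanel(nets[[k]], sparsities, nNulls = 2, seed = k)
    assembleFeatures(nets[[k]], panel, suvFeatures(cohortSubjects(co)[[k]]))
  })
  blocks <- lapply(stats::setNames(nm = names(feats[[1]])), function(b)
    do.call(rbind, lapply(feats, `[[`, b)))
  list(blocks = blocks, labels = cohortGroups(co), cohort = co, nets = nets)
}

# Cohort -> feature blocks with explicit sizing, shared by the slower
# end-to-end checks.
cohortPipeline <- function(co, gridSize = 64, sparsities = sparsityGrid(0.2, 0.5, 0.1),
                           nNulls = 2, normalize = FALSE) {
  nets <- lapply(cohortSubjects(co), function(s) {
    if (normalize) s <- globalIntensityNormalize(s)
    buildNetwork(s, gridSize = gridSize)
  })
  feats <- lapply(seq_along(nets), function(k) {
    panel <- subjectMetricPanel(nets[[k]], sparsities, nNulls = nNulls,
                                seed = k)
    assembleFeatures(nets[[k]], panel, suvFeatures(cohortSubjects(co)[[k]]))
  })
  blocks <- lapply(stats::setNames(nm = names(feats[[1]])), function(b)
    do.call(rbind, lapply(feats, `[[`, b)))
  list(blocks = blocks, labels = cohortGroups(co), nets = nets, cohort = co)
}

# A deliberately clustered graph: k cliques joined in a ring.
ringOfCliques <- function(nCliques = 4, cliqueSize = 5) {
  n <- nCliques * cliqueSize
  adj <- matrix(0L, n, n)
  for (c in seq_len(nCliques)) {
    idx <- ((c - 1) * cliqueSize + 1):(c * cliqueSize)
    adj[idx, idx] <- 1L
    nxt <- idx[cliqueSize] %% n + 1L
    adj[idx[cliqueSize], nxt] <- adj[nxt, idx[cliqueSize]] <- 1L
  }
  diag(adj) <- 0L
  adj
}

# Valid random ConnectivityMatrix without running KDE (for shape tests).
randomW <- function(n, seed = 1) {
  withr::with_seed(seed, {
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, 0.5, 1)
    W <- W + t(W)
    diag(W) <- 1
    new("ConnectivityMatrix", nodes = seq_len(n), W = W)
  })
}
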