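# Pipeline orchestration: simulate -> network -> metrics -> classify ->
# report, each stage reading the previous stage's plain-text artifacts from
# the configured output directory. Every artifact embeds the config hash
# and seed so reruns are identifiable and idempotent given fixed seeds.

#' Default run configuration
#'
#' Nested list of every tunable of the pipeline, overridable via
#' [readRunConfig()] or by merging a partial list. Sub-lists: cohort
#' (generator spec), kde (grid size, bandwidth rule), sparsity (grid),
#' nulls (count, rewire multiplier), cv (folds, beta step, cost exponents,
#' alpha), normalize (global intensity normalisation on/off), outDir and
#' seed.
#'
#' @return the configuration list.
#' @export
defaultRunConfig <- function() {
  list(outDir = tempfile("jssenet"),
       seed = 1L,
       normalize = TRUE,
       cohort = list(nPerGroup = 10L, nRois = 20L, voxelsPerRoi = 150L,
                     affectedRois = integer(0), locationShift = 0,
                     scaleFactor = 1, baseFamily = "gaussian"),
       kde = list(gridSize = 128L, bandwidthRule = "silverman"),
       sparsity = list(lo = 0.02, hi = 0.5, step = 0.01),
       nulls = list(nNulls = 100L, rewireMultiplier = 10),
       cv = list(outerFolds = 10L, innerFolds = 5L, betaStep = 0.1,
                 costExponents = -5:5, alpha = 0.05))
}

mergeConfig <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]))
      mergeConfig(base[[k]], override[[k]]) else override[[k]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [defaultRunConfig()].
#'
#' @param path YAML file path, or a partial configuration list.
#' @return the completed configuration list.
#' @export
readRunConfig <- function(path) {
  override <- if (is.character(path)) yaml::read_yaml(path) else path
  mergeConfig(defaultRunConfig(), override)
}

# Polynomial rolling hash of the deparsed config: a stable short
# fingerprint without an external hashing dependency.
configHash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(config), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

artifactHeader <- function(config)
  sprintf("# jsseNet config=%s seed=%d", configHash(config),
          as.integer(config$seed))

writeArtifact <- function(df, path, config, sep = ",") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifactHeader(config), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

readArtifact <- function(path, sep = ",")
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    check.names = FALSE)

cohortFromConfig <- function(config) {
  cc <- config$cohort
  generateCohort(cohortSpec(
    nPerGroup = cc$nPerGroup, nRois = cc$nRois,
    voxelsPerRoi = cc$voxelsPerRoi,
    affectedRois = as.integer(unlist(cc$affectedRois)),
    locationShift = cc$locationShift, scaleFactor = cc$scaleFactor,
    baseFamily = cc$baseFamily, seed = config$seed))
}

#' Pipeline stage commands
#'
#' Thin orchestration wrappers over the package functions, one per stage:
#' `cmdSimulate()` writes the synthetic cohort (samples TSV + JSON
#' manifest); `cmdNetwork()` builds and writes one JSSE connectivity CSV
#' per subject; `cmdMetrics()` writes the tidy per-threshold metric tables
#' and the AUC summary; `cmdClassify()` runs the nested-CV multi-kernel
#' classification and writes the per-model performance table, ROC points,
#' DeLong comparisons against the combined model, and consensus
#' connections; `cmdReport()` condenses the run into a JSON report. Each
#' stage reads its inputs from \code{config$outDir} as written by the
#' previous stage.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a YAML
#'   path accepted by [readRunConfig()].
#' @return invisibly, the paths written (and for `cmdClassify()` the
#'   [CVResult-class] list as attribute \code{"results"}).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
cmdSimulate <- function(config) {
  config <- readRunConfig(config)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  cohort <- cohortFromConfig(config)
  writeCohortTsv(cohort,
                 file.path(config$outDir, "samples.tsv"),
                 file.path(config$outDir, "manifest.json"))
  invisible(file.path(config$outDir, c("samples.tsv", "manifest.json")))
}

#' @rdname pipeline
#' @export
cmdNetwork <- function(config) {
  config <- readRunConfig(config)
  cohort <- readCohortTsv(file.path(config$outDir, "samples.tsv"),
                          file.path(config$outDir, "manifest.json"))
  paths <- vapply(cohort@subjects, function(s) {
    if (isTRUE(config$normalize)) s <- globalIntensityNormalize(s)
    cm <- buildNetwork(s, gridSize = config$kde$gridSize,
                       bandwidthRule = config$kde$bandwidthRule)
    p <- file.path(config$outDir, sprintf("network_%s.csv", s@subjectId))
    writeConnectivityCsv(cm, p, meta = artifactHeader(config))
    p
  }, character(1))
  invisible(paths)
}

pipelineNetworks <- function(config, cohort) {
  lapply(cohort@subjects, function(s) {
    if (isTRUE(config$normalize)) s <- globalIntensityNormalize(s)
    buildNetwork(s, gridSize = config$kde$gridSize,
                 bandwidthRule = config$kde$bandwidthRule)
  })
}

#' @rdname pipeline
#' @export
cmdMetrics <- function(config) {
  config <- readRunConfig(config)
  man <- jsonlite::read_json(file.path(config$outDir, "manifest.json"),
                             simplifyVector = TRUE)
  ids <- man$subjects$subject_id
  grid <- sparsityGrid(config$sparsity$lo, config$sparsity$hi,
                       config$sparsity$step)
  globalRows <- list(); nodalRows <- list(); aucRows <- list()
  for (k in seq_along(ids)) {
    cm <- readConnectivityCsv(file.path(config$outDir,
                                        sprintf("network_%s.csv", ids[k])))
    panel <- subjectMetricPanel(cm, grid, nNulls = config$nulls$nNulls,
                                rewireMultiplier = config$nulls$rewireMultiplier,
                                seed = config$seed + k)
    globalRows[[k]] <- cbind(subject_id = ids[k], panel$global)
    nodalRows[[k]] <- cbind(subject_id = ids[k], panel$nodal)
    aucRows[[k]] <- data.frame(
      subject_id = ids[k],
      feature = c(paste0("global:", names(panel$globalAuc)),
                  paste0("nodal:", names(panel$nodalAuc))),
      value = c(panel$globalAuc, panel$nodalAuc))
  }
  writeArtifact(do.call(rbind, globalRows),
                file.path(config$outDir, "metrics_global.csv"), config)
  writeArtifact(do.call(rbind, nodalRows),
                file.path(config$outDir, "metrics_nodal.csv"), config)
  writeArtifact(do.call(rbind, aucRows),
                file.path(config$outDir, "metrics_auc.csv"), config)
  invisible(file.path(config$outDir,
                      c("metrics_global.csv", "metrics_nodal.csv",
                        "metrics_auc.csv")))
}

# Assemble the per-subject feature-block matrices from written artifacts.
blocksFromArtifacts <- function(config) {
  cohort <- readCohortTsv(file.path(config$outDir, "samples.tsv"),
                          file.path(config$outDir, "manifest.json"))
  auc <- readArtifact(file.path(config$outDir, "metrics_auc.csv"))
  ids <- vapply(cohort@subjects, slot, character(1), "subjectId")
  blocks <- list()
  rowsOf <- function(s) {
    cm <- readConnectivityCsv(file.path(config$outDir,
                                        sprintf("network_%s.csv", s@subjectId)))
    a <- auc[auc$subject_id == s@subjectId, ]
    panel <- list(
      globalAuc = stats::setNames(
        a$value[startsWith(a$feature, "global:")],
        sub("^global:", "", a$feature[startsWith(a$feature, "global:")])),
      nodalAuc = stats::setNames(
        a$value[startsWith(a$feature, "nodal:")],
        sub("^nodal:", "", a$feature[startsWith(a$feature, "nodal:")])))
    sN <- if (isTRUE(config$normalize)) globalIntensityNormalize(s) else s
    assembleFeatures(cm, panel, suvFeatures(sN))
  }
  feats <- lapply(cohort@subjects, rowsOf)
  for (b in names(feats[[1]]))
    blocks[[b]] <- do.call(rbind, lapply(feats, `[[`, b))
  list(blocks = blocks, labels = cohort@groups, ids = ids, cohort = cohort)
}

#' @rdname pipeline
#' @export
cmdClassify <- function(config) {
  config <- readRunConfig(config)
  dat <- blocksFromArtifacts(config)
  results <- nestedCv(dat$blocks, dat$labels,
                      outerFolds = config$cv$outerFolds,
                      innerFolds = config$cv$innerFolds,
                      betaStep = config$cv$betaStep,
                      costGrid = 2^config$cv$costExponents,
                      alpha = config$cv$alpha,
                      seed = config$seed)
  perf <- do.call(rbind, lapply(results, function(r)
    data.frame(Method = r@model, Accuracy = 100 * r@accuracy,
               Sensitivity = 100 * r@sensitivity,
               Specificity = 100 * r@specificity, AUC = r@auc)))
  writeArtifact(perf, file.path(config$outDir, "performance.csv"), config)
  for (r in results)
    writeArtifact(r@roc, file.path(config$outDir,
                                   sprintf("roc_%s.tsv", gsub("\\+", "", r@model))),
                  config, sep = "\t")
  combined <- results[["C+G+N"]]
  if (!is.null(combined)) {
    dl <- do.call(rbind, lapply(intersect(c("C", "G", "N"), names(results)),
      function(m) {
        d <- delongTest(combined@scores, results[[m]]@scores, dat$labels)
        data.frame(comparison = paste0("C+G+N vs ", m), aucCombined = d$auc1,
                   aucSingle = d$auc2, diff = d$diff, z = d$z, p = d$p,
                   ciLow = d$ci[1], ciHigh = d$ci[2])
      }))
    writeArtifact(dl, file.path(config$outDir, "delong.csv"), config)
    nets <- lapply(dat$ids, function(id)
      readConnectivityCsv(file.path(config$outDir,
                                    sprintf("network_%s.csv", id))))
    edges <- edgewiseGroupTest(nets, dat$labels)
    cons <- consensusConnections(
      lapply(combined@foldMasks, `[[`, "connection"), edges)
    writeArtifact(cons$frequency,
                  file.path(config$outDir, "consensus.tsv"), config,
                  sep = "\t")
  }
  out <- file.path(config$outDir, "performance.csv")
  attr(out, "results") <- results
  invisible(out)
}

#' @rdname pipeline
#' @export
cmdReport <- function(config) {
  config <- readRunConfig(config)
  perf <- readArtifact(file.path(config$outDir, "performance.csv"))
  consPath <- file.path(config$outDir, "consensus.tsv")
  cons <- if (file.exists(consPath)) readArtifact(consPath, sep = "\t") else NULL
  report <- list(config_hash = configHash(config), seed = config$seed,
                 performance = perf,
                 n_consensus = if (is.null(cons)) NA_integer_
                               else sum(cons$frequency == 1))
  path <- file.path(config$outDir, "report.json")
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
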