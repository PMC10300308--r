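#' @import methods
NULL

#' Per-subject ROI voxel-intensity samples
#'
#' Container mapping each region of interest (ROI) to the vector of voxel
#' intensities gathered from that region of a subject's intensity volume.
#' The ROI order is canonical (ascending integer code) and defines the node
#' index used by every downstream network object, so it must be identical
#' across the subjects of a cohort.
#'
#' @slot subjectId single character subject identifier.
#' @slot roiIds integer vector of ROI codes, strictly increasing.
#' @slot samples named list (names = ROI codes) of numeric intensity vectors.
#'
#' @seealso [extractRoiSamples()], [buildNetwork()], [suvFeatures()]
#' @export
setClass("ROISampleSet",
  representation(subjectId = "character", roiIds = "integer", samples = "list"))

setValidity("ROISampleSet", function(object) {
  msgs <- character()
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msgs <- c(msgs, "subjectId must be a single non-NA string")
  if (is.unsorted(object@roiIds, strictly = TRUE))
    msgs <- c(msgs, "roiIds must be strictly increasing")
  if (!identical(names(object@samples), as.character(object@roiIds)))
    msgs <- c(msgs, "samples must be named by roiIds, in the same order")
  n <- vapply(object@samples, length, integer(1))
  if (length(n) && any(n < 2L))
    msgs <- c(msgs, sprintf("every ROI needs >= 2 samples (violated: %s)",
                            paste(object@roiIds[n < 2L], collapse = ", ")))
  finite <- vapply(object@samples, function(x) all(is.finite(x)), logical(1))
  if (length(finite) && !all(finite))
    msgs <- c(msgs, "all intensities must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Discretised probability density estimate
#'
#' A probability density function evaluated on a shared grid and renormalised
#' to unit mass, as produced by [estimatePdf()]. The grid is shared across
#' all ROIs of a subject so that divergences between any two densities are
#' computed on a common support.
#'
#' @slot grid numeric vector of G strictly increasing evaluation points
#'   (intensity units).
#' @slot mass numeric vector of G non-negative probability masses summing to 1.
#' @slot bandwidth kernel bandwidth used (0 for a degenerate point mass).
#'
#' @export
setClass("DensityEstimate",
  representation(grid = "numeric", mass = "numeric", bandwidth = "numeric"))

setValidity("DensityEstimate", function(object) {
  msgs <- character()
  if (length(object@grid) != length(object@mass))
    msgs <- c(msgs, "grid and mass must have equal length")
  if (is.unsorted(object@grid, strictly = TRUE))
    msgs <- c(msgs, "grid must be strictly increasing")
  if (any(object@mass < 0))
    msgs <- c(msgs, "mass must be non-negative")
  if (abs(sum(object@mass) - 1) > 1e-9)
    msgs <- c(msgs, "mass must sum to 1 (tolerance 1e-9)")
  if (length(object@bandwidth) != 1L || object@bandwidth < 0)
    msgs <- c(msgs, "bandwidth must be a single value >= 0")
  if (length(msgs)) msgs else TRUE
})

#' JSSE connectivity matrix
#'
#' Symmetric matrix of pairwise metabolic-connectivity weights
#' \eqn{W_{ij} = \exp(-D_{JS}(P_i \| P_j))} between per-ROI intensity
#' densities. With natural-log divergences every weight lies in
#' \eqn{[e^{-\ln 2}, 1] = [0.5, 1]} and the diagonal is exactly 1, so the
#' network has no negative connections by construction.
#'
#' @slot nodes integer vector of ROI codes in canonical node order.
#' @slot W numeric N x N weight matrix, dimnames = ROI codes.
#'
#' @seealso [buildNetwork()], [thresholdBySparsity()]
#' @export
setClass("ConnectivityMatrix",
  representation(nodes = "integer", W = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  msgs <- character()
  W <- object@W
  n <- length(object@nodes)
  if (!is.numeric(W) || nrow(W) != n || ncol(W) != n)
    msgs <- c(msgs, "W must be a numeric N x N matrix matching nodes")
  else {
    if (max(abs(W - t(W))) > 1e-9) msgs <- c(msgs, "W must be symmetric")
    if (max(abs(diag(W) - 1)) > 1e-9) msgs <- c(msgs, "diag(W) must be 1")
    if (any(W < 0.5 - 1e-9) || any(W > 1 + 1e-9))
      msgs <- c(msgs, "weights must lie in [0.5, 1]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Synthetic two-group phantom cohort
#'
#' Output of [generateCohort()]: a list of per-subject [ROISampleSet] objects
#' with group labels, together with the ground truth (which ROIs carry a
#' group effect, and the implied set of truly-different edges, namely every
#' edge incident to at least one affected ROI).
#'
#' @slot subjects list of [ROISampleSet] objects.
#' @slot groups character vector, one of \code{"PD"}/\code{"NC"} per subject.
#' @slot spec the validated generating spec (list).
#' @slot truth list with \code{affectedRois} and \code{truthEdges}
#'   (two-column matrix of node index pairs, i < j).
#'
#' @export
setClass("SyntheticCohort",
  representation(subjects = "list", groups = "character",
                 spec = "list", truth = "list"))

setValidity("SyntheticCohort", function(object) {
  msgs <- character()
  if (length(object@subjects) != length(object@groups))
    msgs <- c(msgs, "one group label per subject required")
  tab <- table(object@groups)
  if (length(tab) == 2L && tab[[1]] != tab[[2]])
    msgs <- c(msgs, "group sizes must be equal")
  if (length(msgs)) msgs else TRUE
})

#' Nested cross-validation result
#'
#' Pooled out-of-fold predictions and summary performance of one classifier
#' model (a feature-block combination) from [nestedCv()].
#'
#' @slot model model name, e.g. \code{"C+G+N"}.
#' @slot scores numeric out-of-fold decision values, one per subject.
#' @slot labels character true group labels.
#' @slot predicted character predicted labels at decision threshold 0.
#' @slot accuracy,sensitivity,specificity,auc scalar performance in [0, 1].
#' @slot roc data.frame of ROC points (fpr, tpr).
#' @slot foldMasks list (one per outer fold) of per-block logical
#'   feature-selection masks.
#' @slot hyper list (one per outer fold) of chosen hyperparameters
#'   (kernel weights beta, SVM cost C).
#'
#' @export
setClass("CVResult",
  representation(model = "character", scores = "numeric", labels = "character",
                 predicted = "character", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 auc = "numeric", roc = "data.frame", foldMasks = "list",
                 hyper = "list"))

setMethod("show", "ROISampleSet", function(object) {
  n <- vapply(object@samples, length, integer(1))
  cat("ROISampleSet for subject", object@subjectId, "\n")
  cat(" ", length(object@roiIds), "ROIs;",
      "voxels per ROI:", if (length(n)) paste0(min(n), "-", max(n)) else "0", "\n")
})

setMethod("show", "DensityEstimate", function(object) {
  cat("DensityEstimate:", length(object@grid), "grid points on [",
      format(min(object@grid), digits = 4), ",",
      format(max(object@grid), digits = 4), "], bandwidth",
      format(object@bandwidth, digits = 4), "\n")
})

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@W[upper.tri(object@W)]
  cat("ConnectivityMatrix:", length(object@nodes), "nodes,",
      length(w), "edges; weight range [",
      format(min(w), digits = 4), ",", format(max(w), digits = 4), "]\n")
})

setMethod("show", "SyntheticCohort", function(object) {
  tab <- table(object@groups)
  cat("SyntheticCohort:", length(object@subjects), "subjects (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ");",
      length(object@truth$affectedRois), "affected ROIs\n")
})

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult [%s]: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f (n=%d)\n",
              object@model, object@accuracy, object@sensitivity,
              object@specificity, object@auc, length(object@labels)))
})
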