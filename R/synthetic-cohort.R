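#' Specify a synthetic phantom cohort
#'
#' Describes a two-group cohort (cases \code{"PD"} vs controls \code{"NC"})
#' of subjects whose per-ROI voxel-intensity distributions are identical
#' between groups except for a chosen set of affected ROIs, which in the
#' case group are shifted in location and/or rescaled. ROI base parameters
#' (mean, SD) are drawn once per cohort from a fixed hyperprior: means
#' uniform on an SUV-like 2-8 range, SDs uniform on 0.3-1, giving
#' overlapping but distinct region distributions resembling globally
#' normalised FDG uptake.
#'
#' @param nPerGroup subjects per group (>= 2).
#' @param nRois number of ROIs (default 90, the cerebral AAL convention).
#' @param voxelsPerRoi voxels sampled per ROI: a single count or a length-2
#'   range from which per-ROI counts are drawn uniformly (>= 10).
#' @param affectedRois integer ROI codes (subset of \code{1:nRois}) that
#'   carry the group effect.
#' @param locationShift case-group mean shift of affected ROIs, in units of
#'   that ROI's SD.
#' @param scaleFactor multiplier on the SD of affected ROIs in cases (> 0).
#' @param baseFamily \code{"gaussian"} or \code{"gamma"}; the gamma option
#'   is moment-matched (shape/scale chosen to reproduce the target mean and
#'   SD) and exercises skewed, strictly positive intensities.
#' @param seed integer seed making the cohort fully reproducible.
#'
#' @return a validated list of class \code{"CohortSpec"}.
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(nPerGroup = 49L, nRois = 90L, voxelsPerRoi = 200L,
                       affectedRois = integer(0), locationShift = 0,
                       scaleFactor = 1, baseFamily = c("gaussian", "gamma"),
                       seed = 1L) {
  baseFamily <- match.arg(baseFamily)
  bad <- function(field, why) stop("invalid CohortSpec field '", field, "': ", why,
                                   call. = FALSE)
  if (!is.numeric(nPerGroup) || length(nPerGroup) != 1 || nPerGroup < 2)
    bad("nPerGroup", "must be a single count >= 2")
  if (!is.numeric(nRois) || length(nRois) != 1 || nRois < 2)
    bad("nRois", "must be a single count >= 2")
  if (!is.numeric(voxelsPerRoi) || !length(voxelsPerRoi) %in% 1:2 ||
      any(voxelsPerRoi < 10))
    bad("voxelsPerRoi", "must be a count or range, each >= 10")
  affectedRois <- as.integer(affectedRois)
  if (length(affectedRois) &&
      (anyDuplicated(affectedRois) || any(affectedRois < 1 | affectedRois > nRois)))
    bad("affectedRois", "must be distinct ROI codes within 1..nRois")
  if (!is.numeric(locationShift) || length(locationShift) != 1 ||
      !is.finite(locationShift))
    bad("locationShift", "must be a single finite number")
  if (!is.numeric(scaleFactor) || length(scaleFactor) != 1 || scaleFactor <= 0)
    bad("scaleFactor", "must be > 0")
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    bad("seed", "must be a single integer")
  structure(list(nPerGroup = as.integer(nPerGroup), nRois = as.integer(nRois),
                 voxelsPerRoi = as.integer(voxelsPerRoi),
                 affectedRois = sort(affectedRois),
                 locationShift = locationShift, scaleFactor = scaleFactor,
                 baseFamily = baseFamily, seed = as.integer(seed)),
            class = "CohortSpec")
}

# Draw from the base family with given mean/sd. Gamma is moment-matched:
# shape = (mean/sd)^2, scale = sd^2/mean (requires mean > 0, which the
# hyperprior guarantees).
rBase <- function(n, mean, sd, family) {
  if (family == "gaussian") stats::rnorm(n, mean, sd)
  else stats::rgamma(n, shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Generate a synthetic phantom cohort
#'
#' Draws the cohort described by a [cohortSpec()]: control subjects sample
#' every ROI from its cohort-level base distribution; case subjects are
#' identical except that affected ROIs have their mean shifted by
#' \code{locationShift} times the ROI SD and their SD multiplied by
#' \code{scaleFactor}. All randomness is governed by \code{spec$seed}, so
#' two calls with the same spec return byte-identical samples. The ground
#' truth attached to the cohort marks the affected ROIs and the truly
#' different edges (every node pair touching at least one affected ROI,
#' since an edge weight \eqn{W_{ij}} changes iff \eqn{P_i} or \eqn{P_j}
#' changes).
#'
#' @param spec a \code{"CohortSpec"} from [cohortSpec()].
#' @return a [SyntheticCohort-class] object.
#' @examples
#' co <- generateCohort(cohortSpec(nPerGroup = 3, nRois = 5,
#'                                 voxelsPerRoi = 50, seed = 7))
#' co
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "CohortSpec")) spec <- do.call(cohortSpec, spec)
  withSeed(spec$seed, {
    # cohort-level ROI base parameters from the hyperprior
    mu <- stats::runif(spec$nRois, 2, 8)
    sdv <- stats::runif(spec$nRois, 0.3, 1.0)
    nvox <- if (length(spec$voxelsPerRoi) == 2L)
      sample(spec$voxelsPerRoi[1]:spec$voxelsPerRoi[2], spec$nRois, replace = TRUE)
    else rep.int(spec$voxelsPerRoi, spec$nRois)
    muCase <- mu; sdCase <- sdv
    aff <- spec$affectedRois
    muCase[aff] <- mu[aff] + spec$locationShift * sdv[aff]
    sdCase[aff] <- sdv[aff] * spec$scaleFactor
    mkSubject <- function(id, m, s) {
      smp <- lapply(seq_len(spec$nRois), function(r)
        rBase(nvox[r], m[r], s[r], spec$baseFamily))
      names(smp) <- as.character(seq_len(spec$nRois))
      new("ROISampleSet", subjectId = id,
          roiIds = seq_len(spec$nRois), samples = smp)
    }
    subjects <- c(
      lapply(seq_len(spec$nPerGroup), function(k)
        mkSubject(sprintf("PD%02d", k), muCase, sdCase)),
      lapply(seq_len(spec$nPerGroup), function(k)
        mkSubject(sprintf("NC%02d", k), mu, sdv)))
    groups <- rep(c("PD", "NC"), each = spec$nPerGroup)
    pairs <- upperPairs(spec$nRois)
    truthEdges <- pairs[pairs[, 1] %in% aff | pairs[, 2] %in% aff, , drop = FALSE]
    new("SyntheticCohort", subjects = subjects, groups = groups,
        spec = unclass(spec),
        truth = list(affectedRois = aff, truthEdges = truthEdges))
  })
}

#' Render a subject as an intensity/label phantom volume pair
#'
#' Lays the subject's per-ROI samples out as disjoint blocks in a 3D grid:
#' ROI r occupies the next run of voxels in column-major scan order, the
#' label volume records r there, and unassigned voxels are background
#' (label 0, intensity 0). The round trip through [extractRoiSamples()]
#' recovers each ROI's samples exactly, which makes the pair a lossless
#' fixture for volume I/O.
#'
#' @param subject a [ROISampleSet-class].
#' @param gridShape integer length-3 array dimensions.
#' @return list with numeric arrays \code{intensity} and \code{label}.
#' @export
renderPhantomVolume <- function(subject, gridShape) {
  stopifnot(is(subject, "ROISampleSet"), length(gridShape) == 3)
  gridShape <- as.integer(gridShape)
  nvox <- vapply(subject@samples, length, integer(1))
  total <- prod(gridShape)
  if (sum(nvox) > total)
    stop("grid too small: ", sum(nvox), " ROI voxels but only ",
         total, " grid cells")
  intensity <- numeric(total)
  label <- integer(total)
  at <- 1L
  for (k in seq_along(subject@roiIds)) {
    idx <- at:(at + nvox[k] - 1L)
    intensity[idx] <- subject@samples[[k]]
    label[idx] <- subject@roiIds[k]
    at <- at + nvox[k]
  }
  list(intensity = array(intensity, gridShape),
       label = array(label, gridShape))
}

#' Write / read a cohort as plain-text artifacts
#'
#' `writeCohortTsv()` writes all subjects' samples as a single long-format
#' TSV (columns subject_id, roi_id, value) plus a JSON manifest recording
#' the generating spec, group labels, ground truth and a node-order hash;
#' `readCohortTsv()` reads the pair back into a [SyntheticCohort-class].
#'
#' @param cohort a [SyntheticCohort-class].
#' @param samplesPath TSV file path.
#' @param manifestPath JSON manifest path.
#' @return `writeCohortTsv()` the two paths, invisibly; `readCohortTsv()`
#'   the reconstructed cohort.
#' @export
writeCohortTsv <- function(cohort, samplesPath, manifestPath) {
  stopifnot(is(cohort, "SyntheticCohort"))
  rows <- lapply(cohort@subjects, function(s) {
    n <- vapply(s@samples, length, integer(1))
    data.frame(subject_id = s@subjectId,
               roi_id = rep.int(s@roiIds, n),
               value = unlist(s@samples, use.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ids <- vapply(cohort@subjects, slot, character(1), "subjectId")
  manifest <- list(
    spec = cohort@spec,
    subjects = data.frame(subject_id = ids, group = cohort@groups),
    truth = list(affected_rois = cohort@truth$affectedRois,
                 truth_edges = cohort@truth$truthEdges),
    node_order_hash = sum(cohort@subjects[[1]]@roiIds *
                          seq_along(cohort@subjects[[1]]@roiIds)))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(c(samples = samplesPath, manifest = manifestPath))
}

#' @rdname writeCohortTsv
#' @export
readCohortTsv <- function(samplesPath, manifestPath) {
  tab <- utils::read.table(samplesPath, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "numeric"))
  man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
  subjects <- lapply(seq_len(nrow(man$subjects)), function(k) {
    id <- man$subjects$subject_id[k]
    sub <- tab[tab$subject_id == id, ]
    rids <- sort(unique(sub$roi_id))
    smp <- split(sub$value, factor(sub$roi_id, levels = rids))
    names(smp) <- as.character(rids)
    new("ROISampleSet", subjectId = id, roiIds = as.integer(rids),
        samples = smp)
  })
  truthEdges <- man$truth$truth_edges
  if (is.null(truthEdges)) truthEdges <- upperPairs(2)[0, , drop = FALSE]
  truthEdges <- matrix(as.integer(truthEdges), ncol = 2,
                       dimnames = list(NULL, c("i", "j")))
  new("SyntheticCohort", subjects = subjects,
      groups = man$subjects$group, spec = as.list(man$spec),
      truth = list(affectedRois = as.integer(man$truth$affected_rois),
                   truthEdges = truthEdges))
}
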