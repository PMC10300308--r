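#' Extract per-ROI voxel samples from an intensity/label volume pair
#'
#' Collects, for each requested ROI code, the intensities of the voxels
#' whose label equals that code, in deterministic column-major scan order.
#' Background voxels (label 0) never contribute. Volumes are assumed to be
#' already spatially normalised and on the same grid; no resampling is
#' performed.
#'
#' @param intensity numeric 3D array (or matrix) of voxel intensities.
#' @param label integer array of the same shape; 0 = background.
#' @param roiIds ROI codes to extract (default: all positive labels
#'   present, ascending -- the canonical node order).
#' @param subjectId identifier stored in the result.
#' @param minVoxels strict-mode minimum voxels per ROI (default 30, chosen
#'   for kernel-density stability); set to 2 to accept any valid ROI.
#' @return a [ROISampleSet-class].
#' @examples
#' vol <- array(c(3, 5, 7, 9), c(2, 2, 1))
#' lab <- array(c(1L, 1L, 2L, 0L), c(2, 2, 1))
#' extractRoiSamples(vol, lab, minVoxels = 2)  # ROI 2 has 1 voxel: error
#' @export
extractRoiSamples <- function(intensity, label, roiIds = NULL,
                              subjectId = "subject", minVoxels = 30L) {
  if (!identical(dim(intensity), dim(label)))
    stop("intensity and label volumes must share the same shape")
  lab <- as.integer(label)
  if (anyNA(lab)) stop("label volume must be integer-valued")
  if (is.null(roiIds)) roiIds <- sort(unique(lab[lab > 0L]))
  roiIds <- as.integer(roiIds)
  present <- roiIds %in% lab
  if (!all(present))
    stop("ROIs absent from label volume: ",
         paste(roiIds[!present], collapse = ", "))
  smp <- lapply(roiIds, function(r) as.numeric(intensity)[lab == r])
  names(smp) <- as.character(roiIds)
  n <- vapply(smp, length, integer(1))
  if (any(n < minVoxels)) {
    warning("ROIs below the ", minVoxels, "-voxel minimum: ",
            paste(roiIds[n < minVoxels], collapse = ", "))
    stop("insufficient voxels for ROIs: ",
         paste(roiIds[n < minVoxels], collapse = ", "))
  }
  new("ROISampleSet", subjectId = subjectId, roiIds = roiIds, samples = smp)
}

#' Read an intensity + label NIfTI pair into ROI samples
#'
#' Thin wrapper reading both volumes with \pkg{RNifti} and delegating to
#' [extractRoiSamples()].
#'
#' @param intensityFile,labelFile paths to NIfTI volumes (.nii or .nii.gz).
#' @inheritParams extractRoiSamples
#' @return a [ROISampleSet-class].
#' @export
readNiftiRoiSamples <- function(intensityFile, labelFile, roiIds = NULL,
                                subjectId = "subject", minVoxels = 30L) {
  vol <- RNifti::readNifti(intensityFile)
  lab <- RNifti::readNifti(labelFile)
  extractRoiSamples(array(as.numeric(vol), dim(vol)),
                    array(as.integer(round(as.numeric(lab))), dim(lab)),
                    roiIds = roiIds, subjectId = subjectId,
                    minVoxels = minVoxels)
}

#' Write an intensity/label volume pair as NIfTI
#'
#' @param volumes list with arrays \code{intensity} and \code{label}, as
#'   from [renderPhantomVolume()].
#' @param intensityFile,labelFile output paths.
#' @return the two paths, invisibly.
#' @export
writeNiftiVolumes <- function(volumes, intensityFile, labelFile) {
  RNifti::writeNifti(RNifti::asNifti(volumes$intensity), intensityFile)
  RNifti::writeNifti(RNifti::asNifti(volumes$label * 1.0), labelFile)
  invisible(c(intensity = intensityFile, label = labelFile))
}

#' Per-ROI standardised-uptake-value summary features
#'
#' The per-region mean and maximum intensity (SUVmean / SUVmax), the
#' classical uptake features used as baseline classifiers alongside the
#' network-derived feature blocks.
#'
#' @param s a [ROISampleSet-class].
#' @return list with numeric vectors \code{suvMean} and \code{suvMax}
#'   (names = ROI codes).
#' @export
suvFeatures <- function(s) {
  stopifnot(is(s, "ROISampleSet"))
  if (!length(s@samples)) stop("empty sample set")
  list(suvMean = vapply(s@samples, mean, numeric(1)),
       suvMax = vapply(s@samples, max, numeric(1)))
}

#' Global intensity normalisation (proportional scaling)
#'
#' Divides every voxel intensity by the subject's pooled all-ROI mean, so
#' the pooled mean of the result is exactly 1. This mirrors global-mean
#' scaling of uptake images before between-subject comparison.
#'
#' @param s a [ROISampleSet-class].
#' @return a normalised [ROISampleSet-class].
#' @export
globalIntensityNormalize <- function(s) {
  stopifnot(is(s, "ROISampleSet"))
  pooled <- mean(unlist(s@samples, use.names = FALSE))
  if (!is.finite(pooled) || pooled <= 0)
    stop("pooled mean must be positive for proportional scaling (got ",
         format(pooled), ")")
  smp <- lapply(s@samples, function(x) x / pooled)
  new("ROISampleSet", subjectId = s@subjectId, roiIds = s@roiIds,
      samples = smp)
}

#' AAL-90 region lookup table
#'
#' The 90-region cerebral atlas convention (45 regions per hemisphere,
#' cerebellum excluded): sequential code, region name, abbreviation with
#' .L/.R suffix, and hemisphere.
#'
#' @return data.frame with columns code, name, abbreviation, hemisphere.
#' @export
aalLookup <- function() {
  utils::read.csv(system.file("extdata", "aal90.csv", package = "jsseNet"),
                  stringsAsFactors = FALSE)
}
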