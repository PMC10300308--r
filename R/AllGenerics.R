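#' Accessors for jsseNet objects
#'
#' Small accessor generics so that slots are never reached into directly.
#'
#' @param object a jsseNet S4 object.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("roiIds", function(object) standardGeneric("roiIds"))

#' @rdname accessors
#' @export
setGeneric("roiSamples", function(object) standardGeneric("roiSamples"))

#' @rdname accessors
#' @export
setGeneric("wMatrix", function(object) standardGeneric("wMatrix"))

#' @rdname accessors
#' @export
setGeneric("nodes", function(object) standardGeneric("nodes"))

#' @rdname accessors
#' @export
setGeneric("cohortSubjects", function(object) standardGeneric("cohortSubjects"))

#' @rdname accessors
#' @export
setGeneric("cohortGroups", function(object) standardGeneric("cohortGroups"))

#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(object) standardGeneric("cohortTruth"))

#' @rdname accessors
#' @export
setGeneric("cvScores", function(object) standardGeneric("cvScores"))

#' @rdname accessors
#' @export
setGeneric("cvPerformance", function(object) standardGeneric("cvPerformance"))

#' @rdname accessors
#' @export
setMethod("subjectId", "ROISampleSet", function(object) object@subjectId)

#' @rdname accessors
#' @export
setMethod("roiIds", "ROISampleSet", function(object) object@roiIds)

#' @rdname accessors
#' @export
setMethod("roiSamples", "ROISampleSet", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("wMatrix", "ConnectivityMatrix", function(object) object@W)

#' @rdname accessors
#' @export
setMethod("nodes", "ConnectivityMatrix", function(object) object@nodes)

#' @rdname accessors
#' @export
setMethod("cohortSubjects", "SyntheticCohort", function(object) object@subjects)

#' @rdname accessors
#' @export
setMethod("cohortGroups", "SyntheticCohort", function(object) object@groups)

#' @rdname accessors
#' @export
setMethod("cohortTruth", "SyntheticCohort", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("cvScores", "CVResult", function(object)
  data.frame(subject = seq_along(object@scores), score = object@scores,
             label = object@labels, predicted = object@predicted,
             stringsAsFactors = FALSE))

#' @rdname accessors
#' @export
setMethod("cvPerformance", "CVResult", function(object)
  c(accuracy = object@accuracy, sensitivity = object@sensitivity,
    specificity = object@specificity, auc = object@auc))
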