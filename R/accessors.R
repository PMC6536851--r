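#' Accessors for microdyn classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x a microdyn object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))
#' @rdname accessors
#' @export
setMethod("eegData", "Recording", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Segmentation", function(x) x@fs)

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)

#' @rdname accessors
#' @export
setGeneric("referenceState", function(x) standardGeneric("referenceState"))
#' @rdname accessors
#' @export
setMethod("referenceState", "Recording", function(x) x@reference)

#' @rdname accessors
#' @export
setGeneric("epochsArray", function(x) standardGeneric("epochsArray"))
#' @rdname accessors
#' @export
setMethod("epochsArray", "EpochSet", function(x) x@epochs)

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[1])
#' @rdname accessors
#' @export
setMethod("nEpochs", "Segmentation", function(x) nrow(x@labels))

#' @rdname accessors
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))
#' @rdname accessors
#' @export
setMethod("templates", "MicrostateModel", function(x) x@templates)

#' @rdname accessors
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))
#' @rdname accessors
#' @export
setMethod("nClasses", "MicrostateModel", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("nClasses", "Segmentation", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("gevOf", function(x) standardGeneric("gevOf"))
#' @rdname accessors
#' @export
setMethod("gevOf", "MicrostateModel", function(x) x@gev)

#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setMethod("stateLabels", "Segmentation", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("truncatedMask", function(x) standardGeneric("truncatedMask"))
#' @rdname accessors
#' @export
setMethod("truncatedMask", "Segmentation", function(x) x@truncated)

#' @rdname accessors
#' @export
setGeneric("networkData", function(x) standardGeneric("networkData"))
#' @rdname accessors
#' @export
setMethod("networkData", "NetworkTimecourseSet", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("networkNames", function(x) standardGeneric("networkNames"))
#' @rdname accessors
#' @export
setMethod("networkNames", "NetworkTimecourseSet", function(x) x@networkNames)

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))
#' @rdname accessors
#' @export
setMethod("repetitionTime", "NetworkTimecourseSet", function(x) x@trS)

#' @rdname accessors
#' @export
setGeneric("pairVariability", function(x) standardGeneric("pairVariability"))
#' @rdname accessors
#' @export
setMethod("pairVariability", "DFCVariability", function(x) x@pairSD)

#' @rdname accessors
#' @export
setGeneric("networkVariability", function(x) standardGeneric("networkVariability"))
#' @rdname accessors
#' @export
setMethod("networkVariability", "DFCVariability", function(x) x@networkMeanSD)

#' Convert temporal metrics to a one-row data frame
#'
#' Flattens a [TemporalMetrics-class] into one row per subject suitable for
#' binding into a cohort feature table: `duration_<class>`,
#' `occurrence_<class>`, `coverage_<class>` plus the means and the GFP peak
#' rate.
#'
#' @param x a TemporalMetrics object.
#' @param row.names,optional,... ignored (S3 signature compatibility).
#' @return a one-row data.frame.
#' @export
as.data.frame.TemporalMetrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  cn <- x@classNames
  out <- c(
    meanDurationMs = x@meanDurationMs,
    meanOccurrencePerS = mean(x@occurrencePerS, na.rm = TRUE),
    gfpPeaksPerS = x@gfpPeaksPerS,
    stats::setNames(x@durationMs, paste0("duration_", cn)),
    stats::setNames(x@occurrencePerS, paste0("occurrence_", cn)),
    stats::setNames(x@coverage, paste0("coverage_", cn))
  )
  as.data.frame(as.list(out))
}

#' @rdname accessors
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))
#' @rdname accessors
#' @export
setMethod("classNames", "TemporalMetrics", function(x) x@classNames)

#' @rdname accessors
#' @export
setGeneric("meanDuration", function(x) standardGeneric("meanDuration"))
#' @rdname accessors
#' @export
setMethod("meanDuration", "TemporalMetrics", function(x) x@meanDurationMs)

#' @rdname accessors
#' @export
setGeneric("classDuration", function(x) standardGeneric("classDuration"))
#' @rdname accessors
#' @export
setMethod("classDuration", "TemporalMetrics", function(x) {
  stats::setNames(x@durationMs, x@classNames)
})

#' @rdname accessors
#' @export
setGeneric("classOccurrence", function(x) standardGeneric("classOccurrence"))
#' @rdname accessors
#' @export
setMethod("classOccurrence", "TemporalMetrics", function(x) {
  stats::setNames(x@occurrencePerS, x@classNames)
})

#' @rdname accessors
#' @export
setGeneric("classCoverage", function(x) standardGeneric("classCoverage"))
#' @rdname accessors
#' @export
setMethod("classCoverage", "TemporalMetrics", function(x) {
  stats::setNames(x@coverage, x@classNames)
})

#' @rdname accessors
#' @export
setGeneric("observedTransitions", function(x) standardGeneric("observedTransitions"))
#' @rdname accessors
#' @export
setMethod("observedTransitions", "TransitionResult", function(x) x@observed)

#' @rdname accessors
#' @export
setGeneric("expectedTransitions", function(x) standardGeneric("expectedTransitions"))
#' @rdname accessors
#' @export
setMethod("expectedTransitions", "TransitionResult", function(x) x@expected)
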