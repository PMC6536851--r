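#' @import methods
NULL

#' Multichannel EEG recording
#'
#' Container for a continuous channels x samples signal block (microvolts)
#' with its sampling rate, channel labels and reference state.
#'
#' @slot data numeric matrix, channels x samples (microvolts).
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one label per channel (row).
#' @slot reference either \code{"original"} or \code{"average"}.
#'
#' @seealso [newRecording()], [averageReference()], [bandpassFilter()]
#' @export
setClass("Recording",
  representation(
    data = "matrix",
    fs = "numeric",
    channelLabels = "character",
    reference = "character"
  )
)

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a single positive number")
  if (length(object@channelLabels) != nrow(object@data)) {
    msg <- c(msg, sprintf(
      "channel label count (%d) must equal channel (row) count (%d)",
      length(object@channelLabels), nrow(object@data)
    ))
  }
  if (!object@reference %in% c("original", "average")) {
    msg <- c(msg, "reference must be 'original' or 'average'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Recording
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param channelLabels channel names; defaults to \code{Ch1..Chn}.
#' @param reference reference state, \code{"original"} or \code{"average"}.
#' @return A [Recording-class] object.
#' @export
newRecording <- function(data, fs, channelLabels = NULL, reference = "original") {
  data <- as.matrix(data)
  if (is.null(channelLabels)) {
    channelLabels <- if (!is.null(rownames(data))) rownames(data) else paste0("Ch", seq_len(nrow(data)))
  }
  new("Recording",
    data = data, fs = as.numeric(fs),
    channelLabels = as.character(channelLabels), reference = reference
  )
}

#' Set of fixed-length EEG epochs
#'
#' Non-overlapping, contiguous epochs cut from a [Recording-class],
#' stored as an n_epochs x channels x samples_per_epoch array.
#'
#' @slot epochs numeric array, epochs x channels x samples.
#' @slot fs sampling rate (Hz).
#' @slot epochLengthS epoch length in seconds.
#' @slot channelLabels channel names.
#' @export
setClass("EpochSet",
  representation(
    epochs = "array",
    fs = "numeric",
    epochLengthS = "numeric",
    channelLabels = "character"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  if (length(dim(object@epochs)) != 3L) msg <- c(msg, "epochs must be a 3-d array")
  expected <- round(object@fs * object@epochLengthS)
  if (length(dim(object@epochs)) == 3L && dim(object@epochs)[3] != expected) {
    msg <- c(msg, sprintf(
      "samples per epoch (%d) must equal round(fs * epoch_length) = %d",
      dim(object@epochs)[3], expected
    ))
  }
  if (length(msg)) msg else TRUE
})

#' Microstate model: templates plus fit quality
#'
#' A set of k unit-GFP, average-referenced template topographies with the
#' global explained variance (GEV) they achieve on the maps they were fit to.
#'
#' @slot templates channels x k numeric matrix; each column has channel mean 0
#'   and unit global field power.
#' @slot k number of microstate classes.
#' @slot polarityInvariant logical; whether a map and its negation count as
#'   the same state (the resting-state convention).
#' @slot gev global explained variance in [0, 1].
#' @export
setClass("MicrostateModel",
  representation(
    templates = "matrix",
    k = "integer",
    polarityInvariant = "logical",
    gev = "numeric"
  )
)

setValidity("MicrostateModel", function(object) {
  msg <- character()
  if (ncol(object@templates) != object@k) msg <- c(msg, "template count must equal k")
  cm <- colMeans(object@templates)
  if (any(abs(cm) > 1e-8)) msg <- c(msg, "templates must be average-referenced (channel mean 0)")
  g <- sqrt(colMeans(object@templates^2) - colMeans(object@templates)^2)
  if (any(abs(g - 1) > 1e-6)) msg <- c(msg, "templates must be unit-GFP normalized")
  if (length(object@gev) != 1L || is.na(object@gev) || object@gev < -1e-12 || object@gev > 1 + 1e-12) {
    msg <- c(msg, "gev must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Per-sample microstate labelling of an epoch set
#'
#' @slot labels integer matrix, epochs x samples; entries in 1..k or NA
#'   (unassigned).
#' @slot truncated logical matrix, same shape; TRUE where a sample belongs to
#'   a run touching an epoch boundary (potentially truncated, excluded from
#'   temporal statistics).
#' @slot fs sampling rate (Hz).
#' @slot k number of classes.
#' @slot source \code{"peaks_interpolated"} or \code{"all_samples"}.
#' @slot nPeaks integer vector, GFP peak count per epoch.
#' @export
setClass("Segmentation",
  representation(
    labels = "matrix",
    truncated = "matrix",
    fs = "numeric",
    k = "integer",
    source = "character",
    nPeaks = "integer"
  )
)

setValidity("Segmentation", function(object) {
  msg <- character()
  if (!all(dim(object@labels) == dim(object@truncated))) {
    msg <- c(msg, "labels and truncated must have identical shape")
  }
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k)) {
    msg <- c(msg, "labels must lie in 1..k or be NA")
  }
  if (!object@source %in% c("peaks_interpolated", "all_samples")) {
    msg <- c(msg, "source must be 'peaks_interpolated' or 'all_samples'")
  }
  if (length(msg)) msg else TRUE
})

#' Temporal microstate statistics for one subject
#'
#' @slot durationMs per-class mean run duration (ms), NA for absent classes.
#' @slot meanDurationMs mean of per-class durations (classes with runs).
#' @slot occurrencePerS per-class run starts per second of analysed time.
#' @slot coverage per-class fraction of analysed (assigned, non-truncated)
#'   time; sums to 1.
#' @slot gfpPeaksPerS GFP peak rate over the whole epoch set.
#' @slot classNames class labels (A, B, C, ...).
#' @export
setClass("TemporalMetrics",
  representation(
    durationMs = "numeric",
    meanDurationMs = "numeric",
    occurrencePerS = "numeric",
    coverage = "numeric",
    gfpPeaksPerS = "numeric",
    classNames = "character"
  )
)

#' Microstate transition probabilities
#'
#' Observed row-stochastic transition matrix between consecutive distinct,
#' non-truncated runs (never across epochs), and the matrix expected if the
#' next class were drawn independently in proportion to class run counts.
#'
#' @slot observed k x k matrix, zero diagonal, rows sum to 1 (NA rows where a
#'   class has no outgoing transitions).
#' @slot expected k x k matrix under the independence model.
#' @slot counts k x k integer matrix of raw transition counts.
#' @slot nTransitions total transition count.
#' @export
setClass("TransitionResult",
  representation(
    observed = "matrix",
    expected = "matrix",
    counts = "matrix",
    nTransitions = "integer"
  )
)

#' Network time courses (e.g. resting-state fMRI networks)
#'
#' @slot data networks x volumes numeric matrix.
#' @slot trS repetition time (seconds per volume).
#' @slot networkNames network labels.
#' @export
setClass("NetworkTimecourseSet",
  representation(
    data = "matrix",
    trS = "numeric",
    networkNames = "character"
  )
)

setValidity("NetworkTimecourseSet", function(object) {
  msg <- character()
  if (any(!is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (nrow(object@data) < 2L) msg <- c(msg, "at least 2 networks required")
  if (length(object@networkNames) != nrow(object@data)) {
    msg <- c(msg, "network name count must equal row count")
  }
  if (object@trS <= 0) msg <- c(msg, "trS must be positive")
  if (length(msg)) msg else TRUE
})

#' Dynamic-connectivity variability summary
#'
#' Standard deviation over sliding windows of pairwise network connectivity,
#' plus per-network means over the connections involving each network.
#'
#' @slot pairSD named numeric vector, SD over windows per network pair.
#' @slot networkMeanSD named numeric vector, mean pair SD per network.
#' @slot windowVolumes,stepVolumes window parameters used.
#' @export
setClass("DFCVariability",
  representation(
    pairSD = "numeric",
    networkMeanSD = "numeric",
    windowVolumes = "integer",
    stepVolumes = "integer"
  )
)

## ---- show methods ----

setMethod("show", "Recording", function(object) {
  cat(sprintf(
    "Recording: %d channels x %d samples @ %g Hz (%.1f s), reference: %s\n",
    nrow(object@data), ncol(object@data), object@fs,
    ncol(object@data) / object@fs, object@reference
  ))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf(
    "EpochSet: %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
    d[1], d[2], d[3], object@epochLengthS, object@fs
  ))
})

setMethod("show", "MicrostateModel", function(object) {
  cat(sprintf(
    "MicrostateModel: k = %d classes, %d channels, GEV = %.3f, polarity-%s\n",
    object@k, nrow(object@templates), object@gev,
    if (object@polarityInvariant) "invariant" else "sensitive"
  ))
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf(
    "Segmentation (%s): %d epochs x %d samples, k = %d, %.1f%% assigned\n",
    object@source, nrow(object@labels), ncol(object@labels), object@k,
    100 * mean(!is.na(object@labels))
  ))
})

setMethod("show", "TemporalMetrics", function(object) {
  cat("TemporalMetrics\n")
  df <- data.frame(
    class = object@classNames,
    duration_ms = round(object@durationMs, 2),
    occurrence_per_s = round(object@occurrencePerS, 2),
    coverage = round(object@coverage, 3)
  )
  print(df, row.names = FALSE)
  cat(sprintf(
    "mean duration: %.1f ms; GFP peaks/s: %.2f\n",
    object@meanDurationMs, object@gfpPeaksPerS
  ))
})

setMethod("show", "TransitionResult", function(object) {
  cat(sprintf("TransitionResult: %d transitions\nobserved:\n", object@nTransitions))
  print(round(object@observed, 3))
})

setMethod("show", "NetworkTimecourseSet", function(object) {
  cat(sprintf(
    "NetworkTimecourseSet: %d networks x %d volumes, TR = %g s\n",
    nrow(object@data), ncol(object@data), object@trS
  ))
})

setMethod("show", "DFCVariability", function(object) {
  cat(sprintf(
    "DFCVariability: %d pairs, window = %d volumes (step %d)\n",
    length(object@pairSD), object@windowVolumes, object@stepVolumes
  ))
  print(round(object@networkMeanSD, 4))
})
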