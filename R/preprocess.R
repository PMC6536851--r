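#' Zero-phase Butterworth band-pass filter
#'
#' Applies the stated Butterworth band-pass design forward and backward
#' (zero-phase) to every channel, so microstate timing is not phase-shifted.
#' Channel means are removed first, which nulls the DC component exactly.
#' Typical uses are the broad acquisition band (0.3–54 Hz) and the 2–20 Hz
#' band conventionally applied before microstate segmentation.
#'
#' @param rec a [Recording-class].
#' @param lowHz,highHz band edges (Hz), 0 < low < high < fs/2.
#' @param order filter order of the underlying low/high-pass prototypes
#'   (default 2; applied twice by the zero-phase pass).
#' @return a filtered [Recording-class] (reference state preserved).
#' @export
bandpassFilter <- function(rec, lowHz = 2, highHz = 20, order = 2L) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  if (!(lowHz > 0 && lowHz < highHz && highHz < fs / 2)) {
    stop(sprintf(
      "band edges must satisfy 0 < low < high < fs/2 = %g Hz (got %g, %g)",
      fs / 2, lowHz, highHz
    ))
  }
  bf <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  x <- rec@data
  x <- x - rowMeans(x) # exact DC removal; filtfilt edge transients leak DC otherwise
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(bf, ch)))
  new("Recording",
    data = out, fs = fs, channelLabels = rec@channelLabels,
    reference = rec@reference
  )
}

#' Re-reference to the common average
#'
#' Subtracts, at every sample, the mean over channels, so each column of the
#' data has zero mean. Idempotent; invariant to common-mode offsets.
#'
#' @param rec a [Recording-class] with at least 2 channels.
#' @return the average-referenced [Recording-class] (reference = "average").
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "Recording"))
  if (nrow(rec@data) < 2L) stop("average reference requires at least 2 channels")
  new("Recording",
    data = .avgRef(rec@data), fs = rec@fs,
    channelLabels = rec@channelLabels, reference = "average"
  )
}

#' Cut non-overlapping epochs and keep the first n clean ones
#'
#' Splits the recording into contiguous, non-overlapping epochs of
#' \code{epochS} seconds (in temporal order), drops any epoch containing a
#' sample whose absolute amplitude exceeds \code{rejectThresholdUv} (a simple
#' stand-in for artefact rejection), and returns the first \code{nKeep}
#' survivors. Subjects with fewer than \code{nKeep} clean epochs are excluded
#' by raising an error, mirroring the selection rule of microstate studies
#' that require a fixed epoch count per subject.
#'
#' @param rec a [Recording-class].
#' @param epochS epoch length (s), default 2.
#' @param nKeep number of epochs to keep, default 30.
#' @param rejectThresholdUv amplitude rejection threshold (microvolts);
#'   \code{Inf} disables rejection.
#' @return an [EpochSet-class].
#' @export
epochAndSelect <- function(rec, epochS = 2, nKeep = 30L, rejectThresholdUv = Inf) {
  stopifnot(is(rec, "Recording"))
  .assertScalarNumeric(epochS, "epochS", positive = TRUE)
  spe <- round(rec@fs * epochS)
  nAvail <- floor(ncol(rec@data) / spe)
  if (nAvail < 1L) stop("recording shorter than one epoch")
  keep <- integer(0)
  for (e in seq_len(nAvail)) {
    idx <- ((e - 1L) * spe + 1L):(e * spe)
    if (max(abs(rec@data[, idx])) <= rejectThresholdUv) keep <- c(keep, e)
    if (length(keep) == nKeep) break
  }
  if (length(keep) < nKeep) {
    stop(sprintf(
      "only %d artefact-free epochs available, %d required: subject excluded",
      length(keep), nKeep
    ))
  }
  ep <- array(0, dim = c(nKeep, nrow(rec@data), spe))
  for (j in seq_along(keep)) {
    idx <- ((keep[j] - 1L) * spe + 1L):(keep[j] * spe)
    ep[j, , ] <- rec@data[, idx]
  }
  new("EpochSet",
    epochs = ep, fs = rec@fs, epochLengthS = epochS,
    channelLabels = rec@channelLabels
  )
}
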