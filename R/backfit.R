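#' Fit microstate templates back to EEG epochs
#'
#' In the default \code{"peaks_interpolated"} mode each GFP peak is assigned
#' to the template with the highest (polarity-invariant) spatial correlation,
#' and samples between consecutive peaks inherit the nearer peak's label with
#' the boundary halfway between them: for peaks p < q the run of q starts at
#' sample \code{ceiling((p + q) / 2)} (so the exactly-halfway sample of an
#' even gap belongs to the later peak). Samples before the first and after
#' the last peak inherit that peak's label. The first and last run of every
#' epoch are flagged as potentially truncated and excluded from temporal
#' statistics downstream. In \code{"all_samples"} mode every sample is
#' labelled independently by maximal correlation (the robustness variant that
#' does not restrict fitting to GFP peaks).
#'
#' @param templates channels x k matrix (or [MicrostateModel-class]) of
#'   unit-GFP, average-referenced templates.
#' @param epochs an [EpochSet-class] (or a single channels x samples matrix),
#'   average-referenced.
#' @param mode \code{"peaks_interpolated"} (default) or \code{"all_samples"}.
#' @param polarityInvariant match on |correlation| (default TRUE).
#' @param minGFP samples whose GFP is below this fraction of the epoch's
#'   median GFP are still labelled (labels are defined by correlation, which
#'   is scale-free); kept for API completeness, default 0 labels everything.
#' @return a [Segmentation-class].
#' @export
backfit <- function(templates, epochs, mode = c("peaks_interpolated", "all_samples"),
                    polarityInvariant = TRUE, minGFP = 0) {
  mode <- match.arg(mode)
  if (is(templates, "MicrostateModel")) {
    polarityInvariant <- templates@polarityInvariant
    templates <- templates@templates
  }
  templates <- as.matrix(templates)
  k <- ncol(templates)
  Tn <- .unitGFP(.avgRef(templates))

  if (is(epochs, "EpochSet")) {
    arr <- epochs@epochs
    fs <- epochs@fs
  } else {
    m <- as.matrix(epochs)
    arr <- array(m, dim = c(1L, nrow(m), ncol(m)))
    fs <- NA_real_
  }
  nEp <- dim(arr)[1]
  spe <- dim(arr)[3]
  labels <- matrix(NA_integer_, nEp, spe)
  truncated <- matrix(FALSE, nEp, spe)
  nPeaks <- integer(nEp)

  for (e in seq_len(nEp)) {
    ep <- arr[e, , ]
    g <- computeGFP(ep)
    nPeaks[e] <- length(g$peaks)
    if (mode == "all_samples") {
      ok <- g$values > 0
      cc <- crossprod(Tn, .unitGFP(ep[, ok, drop = FALSE])) / nrow(Tn)
      if (polarityInvariant) cc <- abs(cc)
      lab <- rep(NA_integer_, spe)
      lab[ok] <- max.col(t(cc), ties.method = "first")
      labels[e, ] <- lab
    } else {
      pk <- g$peaks
      if (length(pk) < 2L) {
        warning(sprintf("epoch %d has fewer than 2 GFP peaks; skipped", e))
        next
      }
      cc <- crossprod(Tn, .unitGFP(ep[, pk, drop = FALSE])) / nrow(Tn)
      if (polarityInvariant) cc <- abs(cc)
      pkLab <- max.col(t(cc), ties.method = "first")
      lab <- integer(spe)
      # boundaries: run of peak i spans [start_i, start_{i+1} - 1]
      starts <- c(1L, as.integer(ceiling((pk[-length(pk)] + pk[-1]) / 2)))
      ends <- c(starts[-1] - 1L, spe)
      for (i in seq_along(pk)) lab[starts[i]:ends[i]] <- pkLab[i]
      labels[e, ] <- lab
    }
    # flag potentially truncated runs at the epoch boundaries
    lab <- labels[e, ]
    if (!all(is.na(lab))) {
      r <- rle(lab)
      endsR <- cumsum(r$lengths)
      startsR <- endsR - r$lengths + 1L
      truncated[e, startsR[1]:endsR[1]] <- TRUE
      nR <- length(r$lengths)
      truncated[e, startsR[nR]:endsR[nR]] <- TRUE
    }
  }
  new("Segmentation",
    labels = labels, truncated = truncated, fs = fs, k = as.integer(k),
    source = mode, nPeaks = nPeaks
  )
}

#' Temporal microstate statistics from a segmentation
#'
#' Runs touching an epoch boundary (potentially truncated) and unassigned
#' samples are excluded. Per class: duration is the mean run length (ms);
#' occurrence is the number of runs per second of analysed time (total
#' assigned, non-truncated time); coverage is the class's share of analysed
#' time. With these definitions duration x occurrence = coverage x 1000
#' exactly, per class. The mean duration is the unweighted mean over classes
#' that have at least one run; classes without runs are reported as NA with a
#' warning.
#'
#' @param seg a [Segmentation-class] from [backfit()].
#' @param fs sampling rate override when the segmentation carries none.
#' @return a [TemporalMetrics-class].
#' @export
temporalMetrics <- function(seg, fs = NULL) {
  stopifnot(is(seg, "Segmentation"))
  if (is.null(fs)) fs <- seg@fs
  if (is.na(fs) || fs <= 0) stop("sampling rate required (none stored in segmentation)")
  k <- seg@k
  dtMs <- 1000 / fs

  runLengths <- vector("list", k)
  for (e in seq_len(nrow(seg@labels))) {
    lab <- seg@labels[e, ]
    tr <- seg@truncated[e, ]
    if (all(is.na(lab))) next
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (is.na(r$values[i])) next
      if (any(tr[starts[i]:ends[i]])) next
      cl <- r$values[i]
      runLengths[[cl]] <- c(runLengths[[cl]], r$lengths[i])
    }
  }
  nRuns <- vapply(runLengths, length, integer(1))
  classSamples <- vapply(runLengths, sum, numeric(1))
  analyzedS <- sum(classSamples) / fs
  if (analyzedS <= 0) stop("no non-truncated assigned samples to analyse")

  durationMs <- ifelse(nRuns > 0, classSamples / pmax(nRuns, 1) * dtMs, NA_real_)
  occurrencePerS <- nRuns / analyzedS
  coverage <- classSamples / sum(classSamples)
  if (any(nRuns == 0)) {
    warning(sprintf(
      "class(es) %s have no non-truncated runs; duration undefined, excluded from the mean",
      paste(.classLetters(k)[nRuns == 0], collapse = ", ")
    ))
  }
  totalS <- length(seg@labels) / fs
  new("TemporalMetrics",
    durationMs = durationMs,
    meanDurationMs = mean(durationMs, na.rm = TRUE),
    occurrencePerS = occurrencePerS,
    coverage = coverage,
    gfpPeaksPerS = sum(seg@nPeaks) / totalS,
    classNames = .classLetters(k)
  )
}
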