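# Welch spectral estimates: dominant frequency and band powers.

#' Default EEG frequency bands
#'
#' delta 0.5-4, theta 4-5.5, high-theta 5.5-8, alpha 8-13, beta 13-30 Hz.
#' @return named list of c(low, high) band edges in Hz.
#' @export
defaultBands <- function() {
  list(
    delta = c(0.5, 4), theta = c(4, 5.5), highTheta = c(5.5, 8),
    alpha = c(8, 13), beta = c(13, 30)
  )
}

#' Occipital channel subset
#'
#' The posterior channel set conventionally used to quantify dominant
#' frequency slowing in dementia with Lewy bodies (10-5 montage labels).
#' Synthetic layouts can map onto it positionally via \code{n}.
#'
#' @param n if given, return the first \code{n} generic labels
#'   (\code{Ch1..Chn}) instead — a positional stand-in for layouts without
#'   montage labels.
#' @return character vector of channel labels.
#' @export
occipitalChannels <- function(n = NULL) {
  if (!is.null(n)) {
    return(paste0("Ch", seq_len(n)))
  }
  c(
    "PO9", "PO7", "POO9h", "PO5", "O1", "PO3", "POO3h", "OI1h", "POz", "Oz",
    "PO4", "POO4h", "PO6", "O2", "OI2h", "PO8", "POO10h", "PO10"
  )
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is split into
#' \code{segLengthS}-second Hann-windowed segments with the stated overlap,
#' each segment is mean-detrended, and one-sided periodograms are averaged.
#' Density scaling: integrating the PSD over frequency recovers the signal
#' variance (Parseval).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param segLengthS segment length in seconds (default 2, the epoch grain).
#' @param overlap fractional segment overlap (default 0.5).
#' @return list with \code{freq} (Hz) and \code{psd} (power / Hz).
#' @export
welchPSD <- function(x, fs, segLengthS = 2, overlap = 0.5) {
  nSeg <- round(segLengthS * fs)
  if (nSeg < 8L) stop("segment too short")
  if (length(x) < nSeg) stop("series shorter than one Welch segment")
  step <- max(1L, round(nSeg * (1 - overlap)))
  starts <- seq(1L, length(x) - nSeg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nSeg - 1) / (nSeg - 1)) # Hann
  U <- sum(w^2)
  nFreq <- nSeg %/% 2 + 1L
  acc <- numeric(nFreq)
  for (s in starts) {
    seg <- x[s:(s + nSeg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nFreq)]
    P <- (Mod(X)^2) / (fs * U)
    # one-sided: double everything except DC (and Nyquist when nSeg even)
    P[-1] <- 2 * P[-1]
    if (nSeg %% 2 == 0) P[nFreq] <- P[nFreq] / 2
    acc <- acc + P
  }
  list(freq = (seq_len(nFreq) - 1L) * fs / nSeg, psd = acc / length(starts))
}

# average a channel subset of a Recording / EpochSet into series
.channelAverage <- function(obj, channels) {
  if (is(obj, "Recording")) {
    labs <- obj@channelLabels
    idx <- if (is.null(channels)) seq_along(labs) else match(channels, labs)
    if (any(is.na(idx))) {
      stop(sprintf(
        "channels not present: %s",
        paste(channels[is.na(idx)], collapse = ", ")
      ))
    }
    if (length(idx) == 0L) stop("empty channel subset")
    list(series = list(colMeans(obj@data[idx, , drop = FALSE])), fs = obj@fs)
  } else if (is(obj, "EpochSet")) {
    labs <- obj@channelLabels
    idx <- if (is.null(channels)) seq_along(labs) else match(channels, labs)
    if (any(is.na(idx))) {
      stop(sprintf(
        "channels not present: %s",
        paste(channels[is.na(idx)], collapse = ", ")
      ))
    }
    if (length(idx) == 0L) stop("empty channel subset")
    series <- lapply(seq_len(dim(obj@epochs)[1]), function(e) {
      m <- obj@epochs[e, idx, ]
      if (is.null(dim(m))) m else colMeans(m)
    })
    list(series = series, fs = obj@fs)
  } else {
    stop("expected a Recording or EpochSet")
  }
}

#' Dominant frequency of the channel-averaged signal
#'
#' Averages the chosen channels into one series, estimates the Welch PSD
#' (per epoch for an [EpochSet-class], per 2-s segment otherwise), takes the
#' frequency bin of maximal power within the search band, and averages the
#' per-epoch estimates — the mean dominant frequency across the recording.
#'
#' @param obj a [Recording-class] or [EpochSet-class].
#' @param channels channel labels to average; NULL = all channels.
#' @param band search band in Hz (default c(4, 15)).
#' @param segLengthS Welch segment length (s).
#' @return dominant frequency (Hz) within the band.
#' @export
dominantFrequency <- function(obj, channels = NULL, band = c(4, 15),
                              segLengthS = 2) {
  ca <- .channelAverage(obj, channels)
  fs <- ca$fs
  df <- 1 / segLengthS
  if (diff(band) < 2 * df) {
    stop(sprintf(
      "search band %g-%g Hz unresolvable at %.2f Hz resolution; need segments >= %.1f s",
      band[1], band[2], df, 2 / diff(band)
    ))
  }
  est <- vapply(ca$series, function(x) {
    sp <- welchPSD(x, fs, segLengthS = segLengthS)
    inBand <- sp$freq >= band[1] & sp$freq <= band[2]
    sp$freq[inBand][which.max(sp$psd[inBand])]
  }, numeric(1))
  mean(est)
}

#' Band powers averaged over electrodes
#'
#' Integrates the Welch PSD of every channel over each band and averages over
#' electrodes; with \code{relative = TRUE} powers are divided by the total
#' power over the union of the bands.
#'
#' @param rec a [Recording-class].
#' @param bands named list of c(low, high) Hz pairs (default [defaultBands()]);
#'   bands must not overlap and must lie below Nyquist.
#' @param relative report fractions of the union power (default FALSE).
#' @param segLengthS Welch segment length (s).
#' @return named numeric vector of band powers.
#' @export
bandPower <- function(rec, bands = defaultBands(), relative = FALSE,
                      segLengthS = 2) {
  stopifnot(is(rec, "Recording"))
  fs <- rec@fs
  edges <- do.call(rbind, bands)
  if (any(edges[, 2] > fs / 2)) stop("band edge above Nyquist frequency")
  o <- order(edges[, 1])
  if (any(edges[o, 1][-1] < edges[o, 2][-nrow(edges)] - 1e-9)) {
    stop("bands must be non-overlapping")
  }
  nCh <- nrow(rec@data)
  pows <- matrix(0, nCh, length(bands))
  for (ch in seq_len(nCh)) {
    sp <- welchPSD(rec@data[ch, ], fs, segLengthS = segLengthS)
    dfr <- sp$freq[2] - sp$freq[1]
    for (b in seq_along(bands)) {
      inB <- sp$freq >= bands[[b]][1] & sp$freq < bands[[b]][2]
      pows[ch, b] <- sum(sp$psd[inB]) * dfr
    }
  }
  out <- colMeans(pows)
  names(out) <- names(bands)
  if (relative) out <- out / sum(out)
  out
}
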