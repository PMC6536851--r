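#' Generate synthetic microstate template topographies
#'
#' Draws k spatially smooth scalp maps over a synthetic sensor layout
#' (sunflower arrangement on the unit disk, squared-exponential spatial
#' covariance), average-references each map and scales it to unit RMS.
#' Maps are redrawn until every pairwise absolute spatial correlation is
#' below \code{maxAbsCorrelation}, so the templates are mutually distinct —
#' the synthetic analogue of the distinct, stereotypical topographies that
#' microstate analysis assumes.
#'
#' @param nChannels number of channels (>= 8).
#' @param k number of templates (1 <= k <= nChannels - 1).
#' @param smoothness spatial correlation length on the unit-disk layout;
#'   larger values give smoother, more dipolar-looking maps.
#' @param seed integer seed; identical seeds give identical maps.
#' @param maxAbsCorrelation pairwise separation bound (default 0.5).
#' @param maxRetries redraw attempts before giving up.
#' @return channels x k matrix with column names A, B, C, ...; every column
#'   has channel mean 0 and unit root-mean-square.
#' @examples
#' tpl <- makeTopographies(64, 4, seed = 1)
#' round(crossprod(tpl) / 64, 2) # near-diagonal: separated maps
#' @export
makeTopographies <- function(nChannels, k, smoothness = 0.35, seed = NULL,
                             maxAbsCorrelation = 0.5, maxRetries = 200L) {
  if (nChannels < 8L) stop("nChannels must be >= 8")
  if (k < 1L || k > nChannels - 1L) stop("k must satisfy 1 <= k <= nChannels - 1")
  .assertScalarNumeric(smoothness, "smoothness", positive = TRUE)

  # sunflower layout on the unit disk: evenly spread synthetic sensors
  i <- seq_len(nChannels)
  r <- sqrt((i - 0.5) / nChannels)
  th <- i * pi * (3 - sqrt(5))
  xy <- cbind(r * cos(th), r * sin(th))
  d2 <- unname(as.matrix(stats::dist(xy)))^2
  K <- exp(-d2 / (2 * smoothness^2)) + diag(1e-8, nChannels)
  L <- chol(K)

  .withSeed(seed, {
    for (attempt in seq_len(maxRetries)) {
      maps <- crossprod(L, matrix(stats::rnorm(nChannels * k), nChannels, k))
      maps <- .avgRef(maps)
      rms <- sqrt(colMeans(maps^2))
      if (any(rms == 0)) next
      maps <- sweep(maps, 2L, rms, "/")
      if (k == 1L) {
        colnames(maps) <- .classLetters(k)
        return(maps)
      }
      cc <- .mapCorr(maps, maps)
      if (max(abs(cc[upper.tri(cc)])) < maxAbsCorrelation) {
        colnames(maps) <- .classLetters(k)
        return(maps)
      }
    }
    stop(sprintf(
      "could not draw %d maps with pairwise |correlation| < %.2f in %d attempts; relax the bound or increase smoothness",
      k, maxAbsCorrelation, maxRetries
    ))
  })
}

# Geometric-run label sequence: per-sample switch probability p, next state
# uniform over the other k-1 states. Returns integer vector in 1..k.
.labelSequence <- function(nSamples, k, switchProb) {
  if (k == 1L) {
    return(rep(1L, nSamples))
  }
  # draw run lengths until the total covers nSamples
  labels <- integer(nSamples)
  pos <- 1L
  state <- sample.int(k, 1L)
  while (pos <= nSamples) {
    len <- stats::rgeom(1L, switchProb) + 1L
    end <- min(pos + len - 1L, nSamples)
    labels[pos:end] <- state
    pos <- end + 1L
    nxt <- sample.int(k - 1L, 1L)
    state <- if (nxt >= state) nxt + 1L else nxt
  }
  labels
}

#' Simulate multichannel EEG with planted microstate dynamics
#'
#' The signal at sample t is the active template topography multiplied by an
#' oscillatory carrier \eqn{\sin(2\pi f t)} (so global field power peaks twice
#' per carrier cycle, as the microstate model assumes), plus spatially white
#' Gaussian noise that is average-referenced and scaled so the ratio of
#' template-signal RMS to noise RMS equals \code{snr}. State run lengths are
#' geometric with per-sample switch probability
#' \code{(1000 / fs) / dwellMeanMs}; the next state is drawn uniformly among
#' the other states.
#'
#' @param templates channels x k template matrix from [makeTopographies()]
#'   (average-referenced columns).
#' @param dwellMeanMs mean state dwell time in ms (>= 2 samples).
#' @param fs sampling rate (Hz).
#' @param durationS recording length (s).
#' @param carrierHz carrier frequency (Hz); 10 Hz emulates a posterior alpha
#'   rhythm.
#' @param snr template-signal RMS over noise RMS; \code{Inf} disables noise.
#' @param seed integer seed.
#' @return list with \code{recording} (a [Recording-class], average-referenced)
#'   and \code{groundTruth}: list(templates, labelSequence, dwellMeanMs, snr,
#'   seed).
#' @examples
#' tpl <- makeTopographies(32, 3, seed = 2)
#' sim <- simulateMicrostateEEG(tpl, dwellMeanMs = 80, fs = 256,
#'                              durationS = 2, seed = 2)
#' sim$recording
#' @export
simulateMicrostateEEG <- function(templates, dwellMeanMs = 80, fs = 256,
                                  durationS = 60, carrierHz = 10, snr = 2,
                                  seed = NULL) {
  .assertScalarNumeric(fs, "fs", positive = TRUE)
  .assertScalarNumeric(durationS, "durationS", positive = TRUE)
  if (snr < 0) stop("snr must be nonnegative")
  dtMs <- 1000 / fs
  if (dwellMeanMs < 2 * dtMs) {
    stop(sprintf("dwellMeanMs must be >= 2 samples (%.2f ms at fs = %g)", 2 * dtMs, fs))
  }
  templates <- as.matrix(templates)
  nCh <- nrow(templates)
  k <- ncol(templates)
  nS <- round(fs * durationS)

  .withSeed(seed, {
    labels <- .labelSequence(nS, k, dtMs / dwellMeanMs)
    tt <- (seq_len(nS) - 1L) / fs
    carrier <- sin(2 * pi * carrierHz * tt)
    signal <- templates[, labels, drop = FALSE] *
      matrix(carrier, nCh, nS, byrow = TRUE)
    if (is.finite(snr)) {
      noise <- matrix(stats::rnorm(nCh * nS), nCh, nS)
      noise <- .avgRef(noise) # keep the recording exactly average-referenced
      sigRMS <- sqrt(mean(signal^2))
      noiseRMS <- sqrt(mean(noise^2))
      if (snr == 0) {
        signal <- noise
      } else {
        signal <- signal + noise * (sigRMS / (snr * noiseRMS))
      }
    }
    rec <- newRecording(signal, fs,
      channelLabels = if (!is.null(rownames(templates))) {
        rownames(templates)
      } else {
        paste0("Ch", seq_len(nCh))
      },
      reference = "average"
    )
    list(
      recording = rec,
      groundTruth = list(
        templates = templates, labelSequence = labels,
        dwellMeanMs = dwellMeanMs, snr = snr, seed = seed
      )
    )
  })
}

#' Simulate a multi-group cohort with planted dwell-time differences
#'
#' All subjects share one template set (optionally with small per-subject
#' jitter); mean dwell time differs by group — the synthetic analogue of a
#' patient-vs-control contrast in microstate duration. Per-subject seeds are
#' derived deterministically from the master seed, so the whole cohort is
#' reproducible.
#'
#' @param nPerGroup integer vector, subjects per group (each >= 1; >= 2 for
#'   group statistics).
#' @param groupDwellMs numeric vector, mean dwell (ms) per group; same length
#'   as \code{nPerGroup}.
#' @param templates shared channels x k template matrix; generated with
#'   \code{nChannels}, \code{k} if NULL.
#' @param nChannels,k template generation parameters when \code{templates}
#'   is NULL.
#' @param fs,durationS,carrierHz,snr passed to [simulateMicrostateEEG()].
#' @param templateJitterSD per-subject Gaussian jitter added to templates
#'   (then re-referenced/renormalized); 0 disables.
#' @param seed master integer seed.
#' @return list with \code{subjects} (list of lists: id, group, recording,
#'   groundTruth), \code{templates}, and \code{table} (a subject data.frame).
#' @export
simulateCohort <- function(nPerGroup, groupDwellMs, templates = NULL,
                           nChannels = 64, k = 5, fs = 256, durationS = 60,
                           carrierHz = 10, snr = 2, templateJitterSD = 0,
                           seed = NULL) {
  if (length(nPerGroup) < 1L) stop("group list must not be empty")
  if (length(groupDwellMs) != length(nPerGroup)) {
    stop("groupDwellMs must have one entry per group")
  }
  if (any(nPerGroup < 1L)) stop("each group needs at least one subject")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  if (is.null(templates)) {
    templates <- makeTopographies(nChannels, k, seed = .deriveSeeds(seed, 1L))
  }
  nTotal <- sum(nPerGroup)
  subSeeds <- .deriveSeeds(seed + 1L, nTotal)
  groups <- rep(seq_along(nPerGroup), nPerGroup)
  subjects <- vector("list", nTotal)
  for (i in seq_len(nTotal)) {
    tpl <- templates
    if (templateJitterSD > 0) {
      tpl <- .withSeed(subSeeds[i] - 1L, {
        jit <- tpl + matrix(
          stats::rnorm(length(tpl), sd = templateJitterSD),
          nrow(tpl), ncol(tpl)
        )
        jit <- .avgRef(jit)
        sweep(jit, 2L, sqrt(colMeans(jit^2)), "/")
      })
    }
    sim <- simulateMicrostateEEG(tpl,
      dwellMeanMs = groupDwellMs[groups[i]],
      fs = fs, durationS = durationS, carrierHz = carrierHz, snr = snr,
      seed = subSeeds[i]
    )
    subjects[[i]] <- list(
      id = sprintf("S%03d", i),
      group = paste0("G", groups[i]),
      recording = sim$recording,
      groundTruth = sim$groundTruth
    )
  }
  tab <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    group = vapply(subjects, `[[`, "", "group"),
    plantedDwellMs = groupDwellMs[groups],
    stringsAsFactors = FALSE
  )
  list(subjects = subjects, templates = templates, table = tab)
}

#' Simulate network time courses with state-switching covariance
#'
#' Zero-mean Gaussian draws whose covariance is that of the currently active
#' state; state dwell times (in volumes) are geometric with the stated mean.
#' With a single state the series is stationary and windowed correlations
#' fluctuate only by sampling noise; with alternating states the windowed
#' connectivity genuinely varies over time.
#'
#' @param nNetworks number of networks.
#' @param nVolumes number of time points (> 0).
#' @param trS repetition time (s).
#' @param stateCovariances list of symmetric positive-definite
#'   nNetworks x nNetworks matrices, one per state.
#' @param dwellVolumes mean state dwell in volumes (>= 1).
#' @param seed integer seed.
#' @return list with \code{timecourses} (a [NetworkTimecourseSet-class]) and
#'   \code{stateSequence} (integer per volume).
#' @export
simulateNetworkTimecourses <- function(nNetworks, nVolumes, trS = 2,
                                       stateCovariances, dwellVolumes = 20,
                                       seed = NULL) {
  if (nVolumes < 1L) stop("nVolumes must be positive")
  if (!is.list(stateCovariances) || length(stateCovariances) < 1L) {
    stop("stateCovariances must be a non-empty list")
  }
  chols <- vector("list", length(stateCovariances))
  for (s in seq_along(stateCovariances)) {
    Sigma <- stateCovariances[[s]]
    if (!isTRUE(all.equal(Sigma, t(Sigma)))) {
      stop(sprintf("state %d covariance is not symmetric", s))
    }
    if (nrow(Sigma) != nNetworks) {
      stop(sprintf("state %d covariance has dimension %d, expected %d", s, nrow(Sigma), nNetworks))
    }
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) stop(sprintf("state %d covariance is not positive definite", s))
    chols[[s]] <- ch
  }
  nStates <- length(stateCovariances)
  .withSeed(seed, {
    states <- if (nStates == 1L) {
      rep(1L, nVolumes)
    } else {
      .labelSequence(nVolumes, nStates, 1 / dwellVolumes)
    }
    z <- matrix(stats::rnorm(nNetworks * nVolumes), nNetworks, nVolumes)
    x <- matrix(0, nNetworks, nVolumes)
    for (s in seq_len(nStates)) {
      idx <- which(states == s)
      if (length(idx)) x[, idx] <- crossprod(chols[[s]], z[, idx, drop = FALSE])
    }
    tcs <- new("NetworkTimecourseSet",
      data = x, trS = trS,
      networkNames = paste0("N", seq_len(nNetworks))
    )
    list(timecourses = tcs, stateSequence = states)
  })
}
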