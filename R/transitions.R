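# Microstate syntax: transition probabilities and a randomization test.

# Per-epoch sequences of non-truncated run classes, split at unassigned runs
# so transitions are never counted across gaps or epoch boundaries.
.runSequences <- function(seg) {
  out <- list()
  for (e in seq_len(nrow(seg@labels))) {
    lab <- seg@labels[e, ]
    tr <- seg@truncated[e, ]
    if (all(is.na(lab))) next
    r <- rle(lab)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- !is.na(r$values) &
      !vapply(seq_along(r$lengths), function(i) any(tr[starts[i]:ends[i]]), logical(1))
    # split at dropped runs: consecutive kept runs are true neighbours only
    # if nothing was removed between them
    grp <- cumsum(!keep)
    for (g in unique(grp[keep])) {
      sq <- r$values[keep & grp == g]
      if (length(sq) >= 1L) out[[length(out) + 1L]] <- sq
    }
  }
  out
}

.countTransitions <- function(seqs, k) {
  counts <- matrix(0L, k, k)
  for (sq in seqs) {
    if (length(sq) < 2L) next
    a <- sq[-length(sq)]
    b <- sq[-1]
    keep <- a != b
    if (any(keep)) {
      tab <- table(factor(a[keep], levels = seq_len(k)), factor(b[keep], levels = seq_len(k)))
      counts <- counts + matrix(as.integer(tab), k, k)
    }
  }
  counts
}

# expected transition probabilities under independent syntax:
# expected(i, j) = occ_j / sum_{l != i} occ_l
.expectedMatrix <- function(occ) {
  k <- length(occ)
  E <- matrix(occ, k, k, byrow = TRUE)
  diag(E) <- 0
  den <- sum(occ) - occ
  E <- sweep(E, 1L, ifelse(den > 0, den, NA_real_), "/")
  E
}

#' Observed and expected microstate transition probabilities
#'
#' Counts transitions between consecutive distinct, non-truncated runs within
#' each epoch (never across epochs or across unassigned gaps). The observed
#' matrix is row-stochastic with zero diagonal; the expected matrix is what an
#' independent (memoryless, occurrence-proportional) syntax would give:
#' expected(i, j) = occurrences_j / sum over l != i of occurrences_l.
#'
#' @param seg a [Segmentation-class].
#' @return a [TransitionResult-class].
#' @export
transitionMatrix <- function(seg) {
  stopifnot(is(seg, "Segmentation"))
  k <- seg@k
  seqs <- .runSequences(seg)
  present <- unique(unlist(seqs))
  if (length(present) < 2L) stop("fewer than 2 microstate classes present: transitions undefined")
  counts <- .countTransitions(seqs, k)
  rowTot <- rowSums(counts)
  observed <- sweep(counts, 1L, ifelse(rowTot > 0, rowTot, NA_real_), "/")
  occ <- tabulate(unlist(seqs), nbins = k)
  expected <- .expectedMatrix(occ)
  cn <- .classLetters(k)
  dimnames(observed) <- dimnames(expected) <- dimnames(counts) <- list(cn, cn)
  new("TransitionResult",
    observed = observed, expected = expected,
    counts = counts, nTransitions = as.integer(sum(counts))
  )
}

# test statistics given run sequences: chi-square-style global sum and the
# maximum cell deviation |observed - expected| over probability matrices
.transitionStats <- function(seqs, k) {
  counts <- .countTransitions(seqs, k)
  occ <- tabulate(unlist(seqs), nbins = k)
  E <- .expectedMatrix(occ)
  rowTot <- rowSums(counts)
  expCounts <- E * rowTot
  off <- !diag(k) & !is.na(expCounts) & expCounts > 0
  chi <- sum((counts[off] - expCounts[off])^2 / expCounts[off])
  obsP <- sweep(counts, 1L, ifelse(rowTot > 0, rowTot, NA_real_), "/")
  dev <- abs(obsP - E)
  maxDev <- if (all(is.na(dev[off]))) 0 else max(dev[off], na.rm = TRUE)
  c(chi = chi, maxDev = maxDev)
}

#' Randomization test for non-random microstate syntax
#'
#' Tests whether the observed transition structure departs from what the
#' class run counts alone would produce. The null is built by shuffling the
#' order of runs within each epoch (preserving every class's run count
#' exactly); consecutive same-class runs arising from a shuffle are merged
#' before counting. The global statistic is an independence chi-square sum
#' over off-diagonal cells; a max-cell |observed - expected| statistic is
#' reported alongside. P-values use the add-one permutation convention and
#' are therefore never exactly zero.
#'
#' @param seg a [Segmentation-class].
#' @param nShuffles number of run-order shuffles (>= 100).
#' @param seed integer seed.
#' @return list with \code{pGlobal}, \code{pMaxCell}, the observed
#'   \code{statistic} values, \code{nShuffles}, \code{seed}, and the
#'   [TransitionResult-class] under \code{transitions}.
#' @export
transitionRandomnessTest <- function(seg, nShuffles = 1000L, seed = NULL) {
  stopifnot(is(seg, "Segmentation"))
  if (nShuffles < 100L) stop("nShuffles must be >= 100")
  k <- seg@k
  seqs <- .runSequences(seg)
  nRuns <- sum(lengths(seqs))
  if (nRuns < 10L) stop(sprintf("too few runs (%d) for a shuffling null; need >= 10", nRuns))
  obs <- .transitionStats(seqs, k)
  .withSeed(seed, {
    geChi <- 0L
    geDev <- 0L
    for (b in seq_len(nShuffles)) {
      shuffled <- lapply(seqs, function(sq) {
        s <- if (length(sq) > 1L) sample(sq) else sq
        s[c(TRUE, s[-1] != s[-length(s)])] # merge consecutive duplicates
      })
      st <- .transitionStats(shuffled, k)
      if (st["chi"] >= obs["chi"]) geChi <- geChi + 1L
      if (st["maxDev"] >= obs["maxDev"]) geDev <- geDev + 1L
    }
    list(
      pGlobal = (1 + geChi) / (1 + nShuffles),
      pMaxCell = (1 + geDev) / (1 + nShuffles),
      statistic = obs,
      nShuffles = as.integer(nShuffles),
      seed = seed,
      transitions = transitionMatrix(seg)
    )
  })
}
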