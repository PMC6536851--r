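# Shared fixtures and independent oracles, all built in code at test time.

# Segmentation built directly from a run-class sequence (each run runLen
# samples); first and last runs flagged truncated.
makeRunSegmentation <- function(runs, k, fs = 256, runLen = 10L) {
  lab <- rep(as.integer(runs), each = runLen)
  n <- length(lab)
  tr <- matrix(FALSE, 1L, n)
  tr[1L, seq_len(runLen)] <- TRUE
  tr[1L, (n - runLen + 1L):n] <- TRUE
  new("Segmentation",
    labels = matrix(lab, 1L), truncated = tr, fs = fs, k = as.integer(k),
    source = "peaks_interpolated", nPeaks = length(runs)
  )
}

# run-class sequence with uniform random syntax (next class uniform among the
# other classes): the null of the transition randomization test
iidRunSequence <- function(nRuns, k) {
  runs <- integer(nRuns)
  runs[1] <- sample.int(k, 1L)
  for (i in 2:nRuns) {
    nxt <- sample.int(k - 1L, 1L)
    runs[i] <- if (nxt >= runs[i - 1L]) nxt + 1L else nxt
  }
  runs
}

# analytic magnitude response of the zero-phase Butterworth band-pass:
# |H(e^{iw})|^2 for the digital design that bandpassFilter() uses
butterZeroPhaseGain <- function(freqHz, lowHz, highHz, order, fs) {
  bf <- signal::butter(order, c(lowHz, highHz) / (fs / 2), type = "pass")
  w <- 2 * pi * freqHz / fs
  H <- sum(bf$b * exp(-1i * w * (seq_along(bf$b) - 1))) /
    sum(bf$a * exp(-1i * w * (seq_along(bf$a) - 1)))
  Mod(H)^2
}

# all partitions of n items into exactly nBlocks non-empty blocks,
# as canonical membership vectors (first item of a new block gets the next id)
allPartitions <- function(n, nBlocks) {
  out <- list()
  recur <- function(memb, i, used) {
    if (i > n) {
      if (used == nBlocks) out[[length(out) + 1L]] <<- memb
      return(invisible())
    }
    for (b in seq_len(min(used + 1L, nBlocks))) {
      memb[i] <- b
      recur(memb, i + 1L, max(used, b))
    }
  }
  recur(integer(n), 1L, 0L)
  out
}

# independent GEV oracle for a fixed partition of maps: per-block template is
# the first principal component of the member maps (polarity-invariant),
# GEV computed from the definition
partitionGEV <- function(maps, membership, gfp) {
  U <- sweep(maps, 2L, sqrt(colMeans(maps^2) - colMeans(maps)^2), "/")
  r <- numeric(ncol(maps))
  for (b in unique(membership)) {
    idx <- which(membership == b)
    M <- U[, idx, drop = FALSE]
    v <- if (length(idx) == 1L) M[, 1L] else M %*% eigen(crossprod(M), symmetric = TRUE)$vectors[, 1L]
    v <- v / sqrt(mean(v^2) - mean(v)^2)
    r[idx] <- abs(as.numeric(crossprod(M, v)) / nrow(M))
  }
  sum((gfp * r)^2) / sum(gfp^2)
}

# canonical form of a membership vector so partitions compare as set partitions
canonicalPartition <- function(memb) {
  match(memb, unique(memb))
}

# 9 maps in 3 planted, well-separated groups (within |corr| > 0.95,
# between < 0.3); returns maps, the planted membership, and per-map GFP
plantedThreeGroups <- function(nChannels = 32, seed = 1) {
  base <- makeTopographies(nChannels, 3, seed = seed, maxAbsCorrelation = 0.3)
  maps <- matrix(0, nChannels, 9)
  memb <- rep(1:3, each = 3)
  repeat {
    for (j in 1:9) {
      m <- base[, memb[j]] + rnorm(nChannels, sd = 0.08)
      m <- m - mean(m)
      maps[, j] <- m / sqrt(mean(m^2))
    }
    cc <- abs(crossprod(maps) / nChannels)
    within <- cc[outer(memb, memb, "==") & upper.tri(cc)]
    between <- cc[outer(memb, memb, "!=") & upper.tri(cc)]
    if (min(within) > 0.95 && max(between) < 0.3) break
  }
  list(maps = maps, membership = memb, gfp = rep(1, 9))
}

# covariance pair: two states whose (1,2) correlation is +rho / -rho
switchingStates <- function(nNetworks = 5, rho = 0.8) {
  S1 <- diag(nNetworks)
  S1[1, 2] <- S1[2, 1] <- rho
  S2 <- diag(nNetworks)
  S2[1, 2] <- S2[2, 1] <- -rho
  list(S1, S2)
}
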