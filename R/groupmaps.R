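# Permutation-based averaging of subject microstate maps into group maps.

# all permutations of 1..k (k! rows); k kept small by the caller
.permutations <- function(k) {
  if (k == 1L) {
    return(matrix(1L, 1L, 1L))
  }
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0L, k)
  for (pos in seq_len(k)) {
    block <- cbind(
      sub[, seq_len(pos - 1L), drop = FALSE],
      k,
      sub[, seq(pos, k - 1L)[seq_len(k - pos)], drop = FALSE]
    )
    out <- rbind(out, block)
  }
  out
}

# Best relabelling of subject classes against reference maps:
# maximizes total (polarity-invariant) correlation. Exhaustive for k <= 8,
# greedy otherwise. Returns perm p with p[j] = reference class matched by
# subject class j.
.bestPermutation <- function(corrMat, exhaustiveMax = 8L) {
  k <- nrow(corrMat)
  if (k <= exhaustiveMax) {
    perms <- .permutations(k)
    scores <- apply(perms, 1L, function(p) sum(corrMat[cbind(seq_len(k), p)]))
    perms[which.max(scores), ]
  } else {
    # greedy: repeatedly take the best remaining (subject, reference) pair
    p <- integer(k)
    free <- rep(TRUE, k)
    cm <- corrMat
    for (step in seq_len(k)) {
      idx <- which(cm == max(cm, na.rm = TRUE), arr.ind = TRUE)[1L, ]
      p[idx[1]] <- idx[2]
      cm[idx[1], ] <- -Inf
      cm[, idx[2]] <- -Inf
    }
    p
  }
}

#' Average subject microstate maps into group maps by permutation alignment
#'
#' Subjects' class labels are arbitrary, so before averaging, each subject's
#' classes are relabelled (and, under polarity invariance, sign-flipped) to
#' maximize the total spatial correlation with the current mean maps; the
#' means are then recomputed, and the procedure repeats until no relabelling
#' changes (or \code{maxIter}). The output maps are unit-GFP normalized.
#'
#' @param subjectMaps list of channels x k matrices (or
#'   [MicrostateModel-class] objects), all with the same k and channel count.
#' @param polarityInvariant align signs as well as labels (default TRUE).
#' @param maxIter maximum alignment sweeps.
#' @return list with \code{meanMaps} (channels x k, unit GFP, columns
#'   A, B, ...), \code{permutations} (per-subject relabelling applied),
#'   \code{signs} (per-subject, per-class sign flips), and \code{iterations}.
#' @export
groupMeanMaps <- function(subjectMaps, polarityInvariant = TRUE, maxIter = 50L) {
  mats <- lapply(subjectMaps, function(s) {
    if (is(s, "MicrostateModel")) s@templates else as.matrix(s)
  })
  ks <- vapply(mats, ncol, integer(1))
  if (length(unique(ks)) != 1L) {
    stop(sprintf("heterogeneous class counts across subjects: %s", paste(unique(ks), collapse = ", ")))
  }
  chs <- vapply(mats, nrow, integer(1))
  if (length(unique(chs)) != 1L) stop("heterogeneous channel counts across subjects")
  k <- ks[1]
  nSub <- length(mats)
  mats <- lapply(mats, function(m) .unitGFP(.avgRef(m)))

  perms <- matrix(rep(seq_len(k), nSub), nSub, k, byrow = TRUE)
  signs <- matrix(1, nSub, k)
  meanMaps <- mats[[1]]

  alignedMean <- function(perms, signs) {
    acc <- matrix(0, nrow(meanMaps), k)
    for (s in seq_len(nSub)) {
      m <- mats[[s]]
      aligned <- matrix(0, nrow(m), k)
      aligned[, perms[s, ]] <- sweep(m, 2L, signs[s, ], "*")
      acc <- acc + aligned
    }
    .unitGFP(acc / nSub)
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    changed <- FALSE
    for (s in seq_len(nSub)) {
      cc <- crossprod(mats[[s]], meanMaps) / nrow(meanMaps) # subject class x ref class
      score <- if (polarityInvariant) abs(cc) else cc
      p <- .bestPermutation(score)
      sg <- if (polarityInvariant) {
        sgn <- sign(cc[cbind(seq_len(k), p)])
        sgn[sgn == 0] <- 1
        sgn
      } else {
        rep(1, k)
      }
      if (any(p != perms[s, ]) || any(sg != signs[s, ])) changed <- TRUE
      perms[s, ] <- p
      signs[s, ] <- sg
    }
    meanMaps <- alignedMean(perms, signs)
    if (!changed || iter >= maxIter) break
  }
  colnames(meanMaps) <- .classLetters(k)
  list(meanMaps = meanMaps, permutations = perms, signs = signs, iterations = iter)
}
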