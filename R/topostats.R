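# Topographic randomization statistics (TANOVA) and correlation families.

# normalize columns of a matrix of average-referenced maps to unit GFP
.normCols <- function(M) {
  g <- sqrt(colMeans(M^2) - colMeans(M)^2)
  g[g == 0] <- 1
  sweep(M, 2L, g, "/")
}

# sum over columns of GMD(normalized column, grand)
.gmdSum <- function(M, grand) {
  Mn <- .normCols(M)
  sum(sqrt(colMeans((Mn - grand)^2)))
}

#' TANOVA: randomization test on global map dissimilarity
#'
#' Nonparametric two-factor randomization test on topographies with a
#' within-subject factor (microstate class) and a between-subject factor
#' (group). The effect size for a factor is the sum, over its levels, of the
#' global map dissimilarity between the level-mean map and the grand-mean
#' map (maps strength-normalized to unit GFP). Null distributions: the group
#' main effect permutes group labels across subjects; the class main effect
#' permutes class labels within subjects; the interaction permutes both on
#' the residual maps left after removing the two main effects (residuals are
#' compared by raw RMS without re-normalization, which would be unstable for
#' near-zero residuals). P-values use the add-one permutation convention.
#'
#' @param maps either a channels x classes x subjects array, or a list of
#'   channels x classes matrices (one per subject, classes aligned).
#' @param group factor (or vector) of group labels, one per subject.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed.
#' @param effects which effects to test (subset of
#'   \code{c("class", "group", "interaction")}).
#' @return list with \code{p} (named p-values), \code{statistic} (observed
#'   effect sizes), \code{nPerm}, \code{seed}.
#' @export
tanova <- function(maps, group, nPerm = 1000L, seed = NULL,
                   effects = c("class", "group", "interaction")) {
  effects <- match.arg(effects, c("class", "group", "interaction"), several.ok = TRUE)
  if (is.list(maps)) {
    dims <- vapply(maps, dim, integer(2))
    if (length(unique(dims[1, ])) != 1L || length(unique(dims[2, ])) != 1L) {
      bad <- which(dims[2, ] != dims[2, 1] | dims[1, ] != dims[1, 1])
      stop(sprintf(
        "subjects with mismatched map dimensions: %s",
        paste(bad, collapse = ", ")
      ))
    }
    maps <- array(unlist(maps), dim = c(dims[1, 1], dims[2, 1], length(maps)))
  }
  if (any(is.na(maps))) stop("missing maps: every subject must contribute one map per class")
  C <- dim(maps)[1]
  K <- dim(maps)[2]
  S <- dim(maps)[3]
  group <- factor(group)
  if (length(group) != S) stop("group must have one label per subject")
  G <- nlevels(group)

  # unit-GFP normalize every (average-referenced) map
  Xm <- matrix(maps, C, K * S) # column (s-1)*K + k
  Xm <- .normCols(.avgRef(Xm))

  grand <- .normCols(matrix(rowMeans(Xm), ncol = 1))[, 1]
  subjMean <- vapply(
    seq_len(S),
    function(s) rowMeans(Xm[, (s - 1L) * K + seq_len(K), drop = FALSE]),
    numeric(C)
  )

  classMeanOf <- function(classIdx) {
    # classIdx: K x S matrix; entry [k, s] = which stored class plays role k
    vapply(seq_len(K), function(k) {
      rowMeans(Xm[, (seq_len(S) - 1L) * K + classIdx[k, ], drop = FALSE])
    }, numeric(C))
  }

  p <- c()
  statistic <- c()

  .withSeed(seed, {
    if ("group" %in% effects) {
      # vectorized over permutations: one weights matrix, one product
      labs <- cbind(as.integer(group), replicate(nPerm, sample(as.integer(group))))
      Wt <- matrix(0, S, G * (nPerm + 1L))
      ng <- tabulate(as.integer(group), G)
      for (b in seq_len(nPerm + 1L)) {
        for (g in seq_len(G)) {
          Wt[labs[, b] == g, (b - 1L) * G + g] <- 1 / ng[g]
        }
      }
      GM <- .normCols(subjMean %*% Wt)
      gmds <- sqrt(colMeans((GM - grand)^2))
      stats <- colSums(matrix(gmds, G))
      statistic["group"] <- stats[1]
      p["group"] <- (1 + sum(stats[-1] >= stats[1])) / (1 + nPerm)
    }
    if ("class" %in% effects) {
      idIdx <- matrix(rep(seq_len(K), S), K, S)
      obs <- .gmdSum(classMeanOf(idIdx), grand)
      ge <- 0L
      for (b in seq_len(nPerm)) {
        permIdx <- vapply(seq_len(S), function(s) sample.int(K), integer(K))
        if (.gmdSum(classMeanOf(permIdx), grand) >= obs) ge <- ge + 1L
      }
      statistic["class"] <- obs
      p["class"] <- (1 + ge) / (1 + nPerm)
    }
    if ("interaction" %in% effects) {
      classMean <- vapply(seq_len(K), function(k) {
        rowMeans(Xm[, (seq_len(S) - 1L) * K + k, drop = FALSE])
      }, numeric(C))
      groupMeanSub <- vapply(seq_len(G), function(g) {
        rowMeans(subjMean[, as.integer(group) == g, drop = FALSE])
      }, numeric(C))
      grandRaw <- rowMeans(Xm)
      # residual maps after removing both main effects (additive model)
      Rm <- Xm
      for (s in seq_len(S)) {
        for (k in seq_len(K)) {
          Rm[, (s - 1L) * K + k] <- Xm[, (s - 1L) * K + k] - classMean[, k] -
            groupMeanSub[, as.integer(group)[s]] + grandRaw
        }
      }
      cellStat <- function(glab, classIdx) {
        tot <- 0
        for (g in seq_len(G)) {
          sIdx <- which(glab == g)
          for (k in seq_len(K)) {
            cols <- (sIdx - 1L) * K + classIdx[k, sIdx]
            cm <- rowMeans(Rm[, cols, drop = FALSE])
            tot <- tot + sqrt(mean(cm^2))
          }
        }
        tot
      }
      idIdx <- matrix(rep(seq_len(K), S), K, S)
      obs <- cellStat(as.integer(group), idIdx)
      ge <- 0L
      for (b in seq_len(nPerm)) {
        glab <- sample(as.integer(group))
        permIdx <- vapply(seq_len(S), function(s) sample.int(K), integer(K))
        if (cellStat(glab, permIdx) >= obs) ge <- ge + 1L
      }
      statistic["interaction"] <- obs
      p["interaction"] <- (1 + ge) / (1 + nPerm)
    }
    list(p = p, statistic = statistic, nPerm = as.integer(nPerm), seed = seed)
  })
}

#' Correlation family with false-discovery-rate control
#'
#' Pairwise-complete correlations between every (x, y) variable pair, with
#' Benjamini-Hochberg adjustment across the declared family. Pairs involving
#' a constant variable are reported with NA estimates and excluded from the
#' family with a warning.
#'
#' @param table data.frame of per-subject features.
#' @param xVars,yVars column names to correlate (every x against every y).
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @param minN minimum complete pairs per correlation (default 4).
#' @return data.frame with columns x, y, n, estimate, p, pAdj.
#' @export
correlateWithFDR <- function(table, xVars, yVars, method = c("spearman", "pearson"),
                             minN = 4L) {
  method <- match.arg(method)
  stopifnot(all(c(xVars, yVars) %in% names(table)))
  rows <- list()
  for (xv in xVars) {
    for (yv in yVars) {
      x <- table[[xv]]
      y <- table[[yv]]
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < minN) stop(sprintf("fewer than %d complete pairs for (%s, %s)", minN, xv, yv))
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning(sprintf("constant variable in (%s, %s); correlation undefined, excluded from family", xv, yv))
        rows[[length(rows) + 1L]] <- data.frame(
          x = xv, y = yv, n = n, estimate = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE
        )
        next
      }
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        x = xv, y = yv, n = n, estimate = unname(ct$estimate), p = ct$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$pAdj <- NA_real_
  ok <- !is.na(out$p)
  out$pAdj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}
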