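# Sliding-window dynamic functional connectivity and its variability.

# tapered window weights: rectangle of the window length convolved with a
# Gaussian of sd taperSigma (volumes), truncated to the window and normalized
.taperWeights <- function(windowVolumes, taperSigma) {
  if (taperSigma <= 0) {
    return(rep(1, windowVolumes) / windowVolumes)
  }
  half <- ceiling(3 * taperSigma)
  g <- stats::dnorm(seq(-half, half), sd = taperSigma)
  w <- stats::convolve(rep(1, windowVolumes), rev(g), type = "open")
  # take the central windowVolumes samples of the convolution
  start <- half + 1L
  w <- w[start:(start + windowVolumes - 1L)]
  w / sum(w)
}

# weighted Pearson correlation matrix of rows of X (networks x volumes)
.weightedCor <- function(X, w) {
  mu <- X %*% w
  Xc <- X - mu[, rep(1L, ncol(X))]
  Xw <- Xc * matrix(sqrt(w), nrow(X), ncol(X), byrow = TRUE)
  V <- tcrossprod(Xw)
  s <- sqrt(diag(V))
  # a numerically constant segment has no defined correlation: its "variance"
  # is rounding noise, so gate on the data range relative to the signal scale
  rng <- apply(X, 1L, function(r) diff(range(r)))
  s[rng <= 1e-10 * pmax(abs(mu[, 1L]), 1)] <- NA_real_
  R <- V / tcrossprod(s)
  R[!is.finite(R)] <- NA_real_
  R
}

#' Sliding-window dynamic connectivity
#'
#' Pearson correlation between every network pair within successive tapered
#' windows (rectangle convolved with a Gaussian), advancing by
#' \code{stepVolumes} until the window no longer fits: with n volumes there
#' are \code{floor((n - window) / step) + 1} windows. Windows where a network
#' has zero variance give NA for the affected pairs (never silently zero).
#'
#' @param tcs a [NetworkTimecourseSet-class].
#' @param windowVolumes window length in volumes (default 22).
#' @param stepVolumes step between window starts (default 1).
#' @param taperSigma Gaussian taper SD in volumes (default 3; 0 = rectangle).
#' @param fisherZ apply the Fisher z-transform to the windowed correlations.
#' @return object of class \code{"dfcWindows"}: list with \code{connectivity}
#'   (pairs x windows matrix, rownames "Ni~Nj"), \code{pairs} (2-column index
#'   matrix), \code{networkNames}, window parameters.
#' @export
slidingWindowDFC <- function(tcs, windowVolumes = 22L, stepVolumes = 1L,
                             taperSigma = 3, fisherZ = FALSE) {
  stopifnot(is(tcs, "NetworkTimecourseSet"))
  X <- tcs@data
  n <- ncol(X)
  if (windowVolumes > n) stop("window longer than the series")
  if (stepVolumes < 1L) stop("step must be >= 1")
  w <- .taperWeights(windowVolumes, taperSigma)
  starts <- seq(1L, n - windowVolumes + 1L, by = stepVolumes)
  nets <- nrow(X)
  pairs <- which(upper.tri(diag(nets)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  out <- matrix(NA_real_, nrow(pairs), length(starts))
  for (j in seq_along(starts)) {
    seg <- X[, starts[j]:(starts[j] + windowVolumes - 1L), drop = FALSE]
    R <- .weightedCor(seg, w)
    out[, j] <- R[pairs]
  }
  if (fisherZ) out <- atanh(pmin(pmax(out, -1 + 1e-12), 1 - 1e-12))
  nm <- tcs@networkNames
  rownames(out) <- paste0(nm[pairs[, 1]], "~", nm[pairs[, 2]])
  structure(
    list(
      connectivity = out, pairs = pairs, networkNames = nm,
      windowVolumes = as.integer(windowVolumes),
      stepVolumes = as.integer(stepVolumes), taperSigma = taperSigma
    ),
    class = "dfcWindows"
  )
}

#' @export
print.dfcWindows <- function(x, ...) {
  cat(sprintf(
    "dfcWindows: %d pairs x %d windows (window %d, step %d, taper sigma %g)\n",
    nrow(x$connectivity), ncol(x$connectivity), x$windowVolumes,
    x$stepVolumes, x$taperSigma
  ))
  invisible(x)
}

#' Variability of dynamic connectivity over time
#'
#' Standard deviation over windows of each pair's connectivity, plus the mean
#' pair SD per network (over all connections involving that network) — the
#' usual summary when asking whether a network's coupling to the rest of the
#' brain fluctuates.
#'
#' @param windowed a \code{"dfcWindows"} object from [slidingWindowDFC()].
#' @param maxUndefinedFrac tolerated fraction of NA windows per pair before
#'   failing (default 0.1).
#' @return a [DFCVariability-class].
#' @export
dfcVariability <- function(windowed, maxUndefinedFrac = 0.1) {
  stopifnot(inherits(windowed, "dfcWindows"))
  M <- windowed$connectivity
  if (ncol(M) < 3L) stop("need at least 3 windows to estimate variability")
  naFrac <- rowMeans(is.na(M))
  if (any(naFrac > maxUndefinedFrac)) {
    stop(sprintf(
      "pair(s) %s have > %.0f%% undefined windows",
      paste(rownames(M)[naFrac > maxUndefinedFrac], collapse = ", "),
      100 * maxUndefinedFrac
    ))
  }
  pairSD <- apply(M, 1L, stats::sd, na.rm = TRUE)
  nets <- windowed$networkNames
  networkMeanSD <- vapply(seq_along(nets), function(i) {
    mean(pairSD[windowed$pairs[, 1] == i | windowed$pairs[, 2] == i])
  }, numeric(1))
  names(networkMeanSD) <- nets
  new("DFCVariability",
    pairSD = pairSD, networkMeanSD = networkMeanSD,
    windowVolumes = windowed$windowVolumes,
    stepVolumes = windowed$stepVolumes
  )
}

#' Correlate microstate duration with dynamic-connectivity variability
#'
#' Pearson (or Spearman) correlation between the mean microstate duration and
#' each dynamic-connectivity variability column of a paired subject table,
#' with multiplicity correction across the per-connection family (FDR by
#' default, Bonferroni available).
#'
#' @param table data.frame with one row per subject (unique \code{id}).
#' @param durationCol name of the duration column.
#' @param variabilityCols names of the variability columns.
#' @param method correlation method.
#' @param adjust \code{"fdr"} (Benjamini-Hochberg) or \code{"bonferroni"}.
#' @return data.frame with columns variable, n, estimate, p, pAdj; constant
#'   variability columns give NA estimates and are excluded from the family.
#' @export
microstateDfcCorrelation <- function(table, durationCol = "meanDurationMs",
                                     variabilityCols,
                                     method = c("pearson", "spearman"),
                                     adjust = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  adjust <- match.arg(adjust)
  if (!"id" %in% names(table)) stop("table must have an 'id' column")
  if (anyDuplicated(table$id)) {
    stop(sprintf(
      "duplicated subject id(s): %s",
      paste(unique(table$id[duplicated(table$id)]), collapse = ", ")
    ))
  }
  stopifnot(durationCol %in% names(table), all(variabilityCols %in% names(table)))
  rows <- lapply(variabilityCols, function(vc) {
    x <- table[[durationCol]]
    y <- table[[vc]]
    ok <- stats::complete.cases(x, y)
    n <- sum(ok)
    if (n < 4L) stop(sprintf("fewer than 4 paired subjects for %s", vc))
    if (stats::sd(y[ok]) == 0 || stats::sd(x[ok]) == 0) {
      warning(sprintf("constant variable in (%s, %s); correlation undefined", durationCol, vc))
      return(data.frame(
        variable = vc, n = n, estimate = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE
      ))
    }
    ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = method, exact = FALSE))
    data.frame(
      variable = vc, n = n, estimate = unname(ct$estimate), p = ct$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$pAdj <- NA_real_
  ok <- !is.na(out$p)
  out$pAdj[ok] <- stats::p.adjust(out$p[ok],
    method = if (adjust == "fdr") "BH" else "bonferroni"
  )
  out
}
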