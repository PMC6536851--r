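#' Global field power of an epoch
#'
#' GFP at sample t is the spatial standard deviation (population SD, all
#' electrodes as the population) of the average-referenced signal across
#' channels at t. Its local maxima index moments of highest field strength,
#' where topographies have the best signal-to-noise ratio.
#'
#' @param epoch channels x samples numeric matrix, average-referenced.
#' @param tol tolerance on the per-sample channel mean before the input is
#'   rejected as not average-referenced.
#' @param autoReference if TRUE, re-reference silently-offending input with a
#'   warning instead of failing.
#' @return list with \code{values} (nonnegative per-sample GFP) and
#'   \code{peaks} (sorted indices of strict local maxima, see
#'   [findGFPPeaks()]).
#' @export
computeGFP <- function(epoch, tol = 1e-6, autoReference = FALSE) {
  epoch <- as.matrix(epoch)
  scale <- max(abs(epoch), 1)
  cm <- colMeans(epoch)
  if (max(abs(cm)) > tol * scale) {
    if (autoReference) {
      warning("input not average-referenced; re-referencing")
      epoch <- .avgRef(epoch)
    } else {
      stop("epoch is not average-referenced (per-sample channel means differ from 0)")
    }
  }
  v <- .colGFP(epoch)
  list(values = v, peaks = findGFPPeaks(v))
}

#' Strict local maxima of a GFP series
#'
#' Endpoints are never peaks. A flat plateau flanked by strictly lower values
#' on both sides contributes a single peak at its left-center sample
#' (index \code{start + floor((len - 1) / 2)}); plateaus touching a series
#' boundary are not peaks.
#'
#' @param values numeric vector (length >= 3 for any peak to exist).
#' @return sorted integer vector of peak indices (possibly empty).
#' @export
findGFPPeaks <- function(values) {
  n <- length(values)
  if (n < 3L) {
    return(integer(0))
  }
  r <- rle(values)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3L) {
    return(integer(0))
  }
  inner <- 2:(m - 1L)
  isPeak <- r$values[inner] > r$values[inner - 1L] &
    r$values[inner] > r$values[inner + 1L]
  idx <- inner[isPeak]
  as.integer(starts[idx] + (r$lengths[idx] - 1L) %/% 2L)
}

#' Spatial (topographic) correlation between two maps
#'
#' Pearson correlation across channels of two average-referenced maps; with
#' \code{polarityInvariant = TRUE} (the resting-state microstate convention)
#' the absolute value is returned, so a map and its negation are identical.
#'
#' @param mapA,mapB numeric vectors of equal length (channels),
#'   average-referenced.
#' @param polarityInvariant return |correlation|?
#' @return a correlation in [-1, 1] (or [0, 1] when polarity-invariant).
#' @export
spatialCorrelation <- function(mapA, mapB, polarityInvariant = TRUE) {
  if (length(mapA) != length(mapB)) stop("maps must have equal channel counts")
  if (stats::sd(mapA) == 0 || stats::sd(mapB) == 0) {
    stop("zero-variance map: spatial correlation undefined")
  }
  r <- stats::cor(mapA, mapB)
  if (polarityInvariant) abs(r) else r
}

#' Global map dissimilarity between two topographies
#'
#' Root-mean-square channel-wise difference after both maps are scaled to
#' unit GFP (strength-normalized): 0 for identical topographies, 2 for a map
#' and its negation. The effect-size measure used by topographic
#' randomization (TANOVA) testing.
#'
#' @param mapA,mapB average-referenced maps (equal length).
#' @param normalize scale both maps to unit GFP first (default TRUE).
#' @return nonnegative scalar.
#' @export
globalMapDissimilarity <- function(mapA, mapB, normalize = TRUE) {
  if (length(mapA) != length(mapB)) stop("maps must have equal channel counts")
  if (normalize) {
    ga <- sqrt(mean(mapA^2) - mean(mapA)^2)
    gb <- sqrt(mean(mapB^2) - mean(mapB)^2)
    if (ga == 0 || gb == 0) stop("zero-variance map: dissimilarity undefined under normalization")
    mapA <- mapA / ga
    mapB <- mapB / gb
  }
  sqrt(mean((mapA - mapB)^2))
}
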