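# Topographic atomize-and-agglomerate hierarchical clustering (TAAHC) and the
# criteria used to pick the optimal number of microstate classes.

# Unit-GFP centroid of member columns of U (unit-GFP maps).
# Polarity-invariant: first principal component of the member maps (sign
# aligned with the member majority); otherwise the plain mean.
.clusterCentroid <- function(U, members, polarityInvariant) {
  M <- U[, members, drop = FALSE]
  m <- length(members)
  if (m == 1L) {
    return(M[, 1L])
  }
  if (polarityInvariant) {
    # leading eigenvector via the smaller Gram matrix
    if (m <= nrow(M)) {
      G <- crossprod(M)
      ev <- eigen(G, symmetric = TRUE)
      v <- M %*% ev$vectors[, 1L]
    } else {
      G <- tcrossprod(M)
      v <- eigen(G, symmetric = TRUE)$vectors[, 1L]
    }
    if (sum(crossprod(M, v)) < 0) v <- -v
  } else {
    v <- rowMeans(M)
  }
  g <- sqrt(mean(v^2) - mean(v)^2)
  if (g == 0) {
    # pathological (perfectly cancelling members): fall back to first member
    return(M[, 1L])
  }
  v / g
}

# corr of unit-GFP columns of U against a single unit-GFP centroid
.corrToCentroid <- function(U, centroid) {
  as.numeric(crossprod(U, centroid)) / nrow(U)
}

#' TAAHC microstate clustering
#'
#' Bottom-up topographic atomize-and-agglomerate hierarchical clustering.
#' Every map starts as its own cluster; at each step the worst cluster — the
#' one with the lowest summed (polarity-invariant) spatial correlation of its
#' members to their centroid — is atomized and each freed map is reassigned to
#' the surviving cluster whose centroid it correlates with most strongly. A
#' solution is recorded at every cluster count in \code{[kMin, kMax]}.
#' Under polarity invariance the cluster template is the first principal
#' component of the member maps (sign-aligned with the members); otherwise the
#' sign-sensitive mean. Templates are unit-GFP normalized.
#'
#' @param maps channels x n matrix of average-referenced maps (typically the
#'   topographies at GFP peaks). Need not be normalized; each map's GFP is
#'   used as its weight in global explained variance.
#' @param kMin,kMax range of cluster counts to record (kMax <= n).
#' @param polarityInvariant treat a map and its negation as the same state
#'   (default TRUE, the resting-state convention).
#' @param gfpValues optional per-map GFP weights; computed from \code{maps}
#'   if NULL.
#' @return an object of class \code{"taahcFit"}: a list with
#'   \code{solutions} (named by k; each holding a [MicrostateModel-class],
#'   the integer \code{assignment} of every map, and each map's
#'   \code{corrToTemplate}), plus \code{gfp}, \code{nMaps},
#'   \code{polarityInvariant}.
#' @export
taahc <- function(maps, kMin = 1L, kMax, polarityInvariant = TRUE,
                  gfpValues = NULL) {
  maps <- as.matrix(maps)
  n <- ncol(maps)
  nCh <- nrow(maps)
  if (missing(kMax)) kMax <- min(12L, n)
  if (kMax > n) stop(sprintf("kMax (%d) exceeds the number of maps (%d)", kMax, n))
  if (kMin < 1L || kMin > kMax) stop("need 1 <= kMin <= kMax")
  if (is.null(gfpValues)) gfpValues <- .colGFP(maps)
  if (any(gfpValues <= 0)) stop("maps with zero GFP cannot be clustered")
  U <- .unitGFP(.avgRef(maps))

  membership <- seq_len(n)
  centroids <- U # singleton centroids are the maps themselves
  quality <- rep(1, n) # singleton |corr| to own centroid
  active <- rep(TRUE, n)
  nClusters <- n

  solutions <- vector("list", kMax - kMin + 1L)
  names(solutions) <- as.character(seq(kMax, kMin))

  recordSolution <- function(k) {
    ids <- which(active)
    relabel <- integer(n)
    relabel[ids] <- seq_along(ids)
    assignment <- relabel[membership]
    tpl <- centroids[, ids, drop = FALSE]
    corrs <- colSums(U * tpl[, assignment, drop = FALSE]) / nCh
    g <- sum((gfpValues * corrs)^2) / sum(gfpValues^2)
    tplOut <- tpl
    colnames(tplOut) <- .classLetters(k)
    rownames(tplOut) <- rownames(maps)
    model <- new("MicrostateModel",
      templates = tplOut, k = as.integer(k),
      polarityInvariant = polarityInvariant, gev = min(max(g, 0), 1)
    )
    list(model = model, assignment = assignment, corrToTemplate = corrs)
  }

  repeat {
    if (nClusters <= kMax) {
      solutions[[as.character(nClusters)]] <- recordSolution(nClusters)
    }
    if (nClusters <= kMin) break
    ids <- which(active)
    worst <- ids[which.min(quality[ids])]
    freed <- which(membership == worst)
    active[worst] <- FALSE
    nClusters <- nClusters - 1L
    ids <- which(active)
    cc <- crossprod(centroids[, ids, drop = FALSE], U[, freed, drop = FALSE]) / nCh
    if (polarityInvariant) cc <- abs(cc)
    dest <- ids[max.col(t(cc), ties.method = "first")]
    membership[freed] <- dest
    for (cl in unique(dest)) {
      mem <- which(membership == cl)
      centroids[, cl] <- .clusterCentroid(U, mem, polarityInvariant)
      cr <- .corrToCentroid(U[, mem, drop = FALSE], centroids[, cl])
      if (polarityInvariant) cr <- abs(cr)
      quality[cl] <- sum(cr)
    }
  }

  structure(
    list(
      solutions = solutions, gfp = gfpValues, nMaps = n,
      nChannels = nCh, polarityInvariant = polarityInvariant
    ),
    class = "taahcFit"
  )
}

#' @export
print.taahcFit <- function(x, ...) {
  ks <- sort(as.integer(names(x$solutions)))
  gev <- vapply(
    x$solutions[as.character(ks)],
    function(s) s$model@gev, numeric(1)
  )
  cat(sprintf("TAAHC fit on %d maps (%d channels)\n", x$nMaps, x$nChannels))
  print(data.frame(k = ks, GEV = round(gev, 4)), row.names = FALSE)
  invisible(x)
}

#' Global explained variance of a microstate model
#'
#' GEV is the GFP-weighted fraction of topographic variance explained when
#' each map is represented by its (assigned or best-correlated) template:
#' \deqn{GEV = \sum_t (GFP_t \, r_t)^2 / \sum_t GFP_t^2}
#' where \eqn{r_t} is the spatial correlation between map t and its template.
#'
#' @param model a [MicrostateModel-class] (or channels x k template matrix).
#' @param maps channels x n matrix of maps.
#' @param gfpValues per-map GFP; computed from \code{maps} if NULL.
#' @param assignment optional integer vector assigning each map to a template;
#'   if NULL each map uses its best-correlated template.
#' @param polarityInvariant used when \code{model} is a bare matrix.
#' @return GEV fraction in [0, 1].
#' @export
globalExplainedVariance <- function(model, maps, gfpValues = NULL,
                                    assignment = NULL,
                                    polarityInvariant = TRUE) {
  if (is(model, "MicrostateModel")) {
    tpl <- model@templates
    polarityInvariant <- model@polarityInvariant
  } else {
    tpl <- as.matrix(model)
  }
  maps <- as.matrix(maps)
  if (ncol(maps) < 1L) stop("empty map set")
  if (is.null(gfpValues)) gfpValues <- .colGFP(maps)
  U <- .unitGFP(.avgRef(maps))
  Tn <- .unitGFP(.avgRef(tpl))
  cc <- crossprod(Tn, U) / nrow(U) # k x n correlations
  if (polarityInvariant) cc <- abs(cc)
  r <- if (is.null(assignment)) {
    apply(cc, 2L, max)
  } else {
    cc[cbind(assignment, seq_len(ncol(U)))]
  }
  sum((gfpValues * r)^2) / sum(gfpValues^2)
}

#' Pick the optimal number of microstate classes by a criterion-bank vote
#'
#' Computes a bank of cluster-validity criteria on the nested TAAHC solutions
#' and returns the median of their votes (ties broken toward the smaller k).
#' The within-cluster dispersion used throughout is the GFP-weighted
#' unexplained variance \eqn{W(k) = \sum_t GFP_t^2 (1 - r_t^2)}.
#'
#' Criteria available:
#' \describe{
#'   \item{kl}{normalized Krzanowski–Lai ratio on
#'     \eqn{DIFF(k) = (k-1)^{2/C} W(k-1) - k^{2/C} W(k)}; votes
#'     \eqn{\arg\max_k |DIFF(k)| / |DIFF(k+1)|} over k with positive DIFF.}
#'   \item{cv}{Pascual-Marqui cross-validation criterion
#'     \eqn{\hat\sigma^2_k ((C-1)/(C-1-k))^2}; votes its minimum.}
#'   \item{dispersion}{elbow of the dispersion curve: votes
#'     \eqn{\arg\max_k (W(k-1) - W(k)) - (W(k) - W(k+1))}.}
#' }
#'
#' @param fit a \code{"taahcFit"} from [taahc()] covering the whole range.
#' @param kRange integer vector \code{c(min, max)} of admissible k
#'   (default 1–12).
#' @param criteria character vector naming at least two criteria from the
#'   bank above.
#' @return the selected k (integer), with the per-criterion votes attached as
#'   attribute \code{"votes"}.
#' @export
selectOptimalK <- function(fit, kRange = c(1L, 12L),
                           criteria = c("kl", "cv", "dispersion")) {
  stopifnot(inherits(fit, "taahcFit"))
  criteria <- match.arg(criteria, c("kl", "cv", "dispersion"), several.ok = TRUE)
  if (length(unique(criteria)) < 2L) {
    stop("the meta-criterion needs at least 2 enabled criteria")
  }
  kMin <- as.integer(kRange[1])
  kMax <- as.integer(kRange[2])
  ks <- kMin:kMax
  have <- as.character(ks) %in% names(fit$solutions) &
    !vapply(fit$solutions[as.character(ks)], is.null, logical(1))
  if (!all(have)) stop("fit does not cover the full k range requested")
  C <- fit$nChannels
  g2 <- fit$gfp^2
  total <- sum(g2)
  W <- vapply(as.character(ks), function(kk) {
    s <- fit$solutions[[kk]]
    sum(g2 * (1 - s$corrToTemplate^2))
  }, numeric(1))
  names(W) <- as.character(ks)

  # no structure at all: dispersion already (near) zero with one class
  if (W[1] <= 1e-12 * total) {
    return(structure(kMin, votes = stats::setNames(rep(kMin, length(criteria)), criteria)))
  }

  nK <- length(ks)
  votes <- integer(0)
  for (cr in criteria) {
    v <- switch(cr,
      cv = {
        nT <- fit$nMaps
        sigma2 <- C * W / (nT * (C - 1))
        cv <- sigma2 * ((C - 1) / (C - 1 - ks))^2
        ks[which.min(cv)]
      },
      kl = {
        if (nK < 3L) {
          ks[1]
        } else {
          kk <- ks[2:(nK - 1L)] # interior k with both neighbours
          diffk <- function(k) {
            (k - 1)^(2 / C) * W[as.character(k - 1)] - k^(2 / C) * W[as.character(k)]
          }
          d0 <- vapply(kk, diffk, numeric(1))
          d1 <- vapply(kk + 1L, diffk, numeric(1))
          kl <- ifelse(d0 <= 0, 0, abs(d0) / pmax(abs(d1), 1e-300))
          kk[which.max(kl)]
        }
      },
      dispersion = {
        if (nK < 3L) {
          ks[1]
        } else {
          kk <- ks[2:(nK - 1L)]
          d2 <- (W[as.character(kk - 1L)] - W[as.character(kk)]) -
            (W[as.character(kk)] - W[as.character(kk + 1L)])
          kk[which.max(d2)]
        }
      }
    )
    votes[cr] <- v
  }
  sv <- sort(votes)
  pick <- sv[[floor((length(sv) + 1) / 2)]] # lower median: ties toward smaller k
  structure(as.integer(pick), votes = votes)
}
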