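# End-to-end orchestration: preprocessing -> per-subject clustering ->
# cohort-level k -> group maps -> back-fitting -> feature table.

#' Topographies at GFP peaks of an epoch set
#'
#' Collects the instantaneous maps at every GFP peak of every epoch — the
#' high signal-to-noise moments microstate clustering is restricted to.
#'
#' @param epochs an [EpochSet-class] (average-referenced).
#' @param maxMaps optional cap: evenly subsample to at most this many maps
#'   (deterministic).
#' @return list with \code{maps} (channels x nPeaks), \code{gfp} (per-map
#'   GFP) and \code{peaksPerEpoch}.
#' @export
gfpPeakMaps <- function(epochs, maxMaps = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  arr <- epochs@epochs
  mapsL <- list()
  gfpL <- list()
  ppe <- integer(dim(arr)[1])
  for (e in seq_len(dim(arr)[1])) {
    ep <- arr[e, , ]
    g <- computeGFP(ep)
    ppe[e] <- length(g$peaks)
    if (length(g$peaks)) {
      mapsL[[length(mapsL) + 1L]] <- ep[, g$peaks, drop = FALSE]
      gfpL[[length(gfpL) + 1L]] <- g$values[g$peaks]
    }
  }
  maps <- do.call(cbind, mapsL)
  gfp <- unlist(gfpL)
  if (!is.null(maxMaps) && ncol(maps) > maxMaps) {
    idx <- round(seq(1L, ncol(maps), length.out = maxMaps))
    maps <- maps[, idx, drop = FALSE]
    gfp <- gfp[idx]
  }
  list(maps = maps, gfp = gfp, peaksPerEpoch = ppe)
}

#' Pipeline configuration
#'
#' Validated bag of the tunable parameters of the full analysis.
#'
#' @param bandHz band-pass edges before segmentation (Hz); NULL skips
#'   filtering (synthetic inputs are already band-limited).
#' @param filterOrder Butterworth order.
#' @param epochS epoch length (s).
#' @param nEpochs epochs required per subject.
#' @param rejectThresholdUv epoch amplitude rejection threshold.
#' @param kMode \code{"auto"} (meta-criterion per subject, cohort median) or
#'   \code{"fixed"}.
#' @param k class count when \code{kMode = "fixed"}.
#' @param kRange search range for the meta-criterion.
#' @param fitMode back-fitting mode, \code{"peaks_interpolated"} or
#'   \code{"all_samples"}.
#' @param polarityInvariant polarity-invariant matching throughout.
#' @param maxMapsForClustering optional cap on GFP-peak maps per subject.
#' @param seed master seed recorded with outputs.
#' @return a validated list of class \code{"microdynConfig"}.
#' @export
microdynConfig <- function(bandHz = NULL, filterOrder = 2L, epochS = 2,
                           nEpochs = 30L, rejectThresholdUv = Inf,
                           kMode = c("auto", "fixed"), k = 5L,
                           kRange = c(1L, 12L),
                           fitMode = c("peaks_interpolated", "all_samples"),
                           polarityInvariant = TRUE,
                           maxMapsForClustering = NULL, seed = 1L) {
  kMode <- match.arg(kMode)
  fitMode <- match.arg(fitMode)
  if (!is.null(bandHz) && (length(bandHz) != 2L || bandHz[1] >= bandHz[2])) {
    stop("bandHz must be c(low, high) with low < high")
  }
  .assertScalarNumeric(epochS, "epochS", positive = TRUE)
  if (nEpochs < 1L) stop("nEpochs must be >= 1")
  if (kMode == "fixed" && (k < 1L)) stop("k must be >= 1")
  if (length(kRange) != 2L || kRange[1] < 1L || kRange[1] > kRange[2]) {
    stop("kRange must be c(min, max) with 1 <= min <= max")
  }
  structure(
    list(
      bandHz = bandHz, filterOrder = as.integer(filterOrder), epochS = epochS,
      nEpochs = as.integer(nEpochs), rejectThresholdUv = rejectThresholdUv,
      kMode = kMode, k = as.integer(k), kRange = as.integer(kRange),
      fitMode = fitMode, polarityInvariant = polarityInvariant,
      maxMapsForClustering = maxMapsForClustering, seed = as.integer(seed)
    ),
    class = "microdynConfig"
  )
}

#' Run the full microstate pipeline on a cohort
#'
#' Stages, per the standard microstate workflow: (1) optional band-pass,
#' average reference, epoching with amplitude-based selection; (2) TAAHC on
#' each subject's GFP-peak maps; (3) cohort-level class count — the median of
#' per-subject meta-criterion optima in \code{"auto"} mode, or the fixed k;
#' (4) permutation-aligned group mean maps per group; (5) group maps fit back
#' to every subject of that group; (6) temporal metrics and transition
#' matrices, assembled into a per-subject feature table. A stage failure for
#' a subject is reported with the subject id and stage name.
#'
#' @param cohort list with a \code{subjects} element (each subject a list
#'   with \code{id}, \code{group}, \code{recording}), as returned by
#'   [simulateCohort()]; a bare list of subjects is also accepted.
#' @param config a [microdynConfig()].
#' @param outDir optional directory; when given, the feature table, group
#'   maps, segmentations and the resolved config are written there.
#' @return list with \code{table} (feature data.frame), \code{groupMaps},
#'   \code{models}, \code{segmentations}, \code{metrics}, \code{transitions},
#'   \code{subjectK}, \code{cohortK}, \code{config}.
#' @export
runPipeline <- function(cohort, config = microdynConfig(), outDir = NULL) {
  stopifnot(inherits(config, "microdynConfig"))
  subjects <- if (!is.null(cohort$subjects)) cohort$subjects else cohort
  if (length(subjects) < 1L) stop("empty cohort")
  ids <- vapply(subjects, `[[`, "", "id")
  groups <- vapply(subjects, `[[`, "", "group")

  stage <- function(id, name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("subject %s, stage %s: %s", id, name, conditionMessage(e)), call. = FALSE)
    })
  }

  # 1) preprocessing
  epochSets <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    rec <- subjects[[i]]$recording
    if (!is.null(config$bandHz)) {
      rec <- stage(ids[i], "bandpass", bandpassFilter(
        rec, config$bandHz[1], config$bandHz[2], config$filterOrder
      ))
    }
    rec <- stage(ids[i], "reference", averageReference(rec))
    epochSets[[i]] <- stage(ids[i], "epoching", epochAndSelect(
      rec, config$epochS, config$nEpochs, config$rejectThresholdUv
    ))
  }

  # 2) per-subject clustering
  kMaxFit <- max(config$kRange[2], config$k)
  fits <- vector("list", length(subjects))
  subjectK <- integer(length(subjects))
  for (i in seq_along(subjects)) {
    pm <- stage(ids[i], "gfp_peaks", gfpPeakMaps(epochSets[[i]], config$maxMapsForClustering))
    fits[[i]] <- stage(ids[i], "taahc", taahc(
      pm$maps,
      kMin = 1L, kMax = kMaxFit,
      polarityInvariant = config$polarityInvariant, gfpValues = pm$gfp
    ))
    subjectK[i] <- if (config$kMode == "auto") {
      as.integer(stage(ids[i], "select_k", selectOptimalK(fits[[i]], config$kRange)))
    } else {
      config$k
    }
  }

  # 3) cohort-level k (lower median, matching the meta-criterion tie rule)
  cohortK <- if (config$kMode == "auto") {
    sk <- sort(subjectK)
    as.integer(sk[[floor((length(sk) + 1) / 2)]])
  } else {
    config$k
  }

  models <- lapply(seq_along(subjects), function(i) {
    fits[[i]]$solutions[[as.character(cohortK)]]$model
  })

  # 4) group mean maps
  groupLevels <- unique(groups)
  groupMaps <- lapply(groupLevels, function(g) {
    groupMeanMaps(models[groups == g], polarityInvariant = config$polarityInvariant)$meanMaps
  })
  names(groupMaps) <- groupLevels

  # 5) back-fit group maps; 6) metrics
  segmentations <- vector("list", length(subjects))
  metrics <- vector("list", length(subjects))
  transitions <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    segmentations[[i]] <- stage(ids[i], "backfit", backfit(
      groupMaps[[groups[i]]], epochSets[[i]],
      mode = config$fitMode,
      polarityInvariant = config$polarityInvariant
    ))
    metrics[[i]] <- stage(ids[i], "metrics", temporalMetrics(segmentations[[i]]))
    transitions[[i]] <- stage(ids[i], "transitions", tryCatch(
      transitionMatrix(segmentations[[i]]),
      error = function(e) NULL # a one-class segmentation has no transitions
    ))
  }

  gevAtK <- vapply(models, function(m) m@gev, numeric(1))
  table <- cbind(
    data.frame(
      id = ids, group = groups, k = subjectK, cohortK = cohortK,
      gev = gevAtK, stringsAsFactors = FALSE
    ),
    do.call(rbind, lapply(metrics, as.data.frame))
  )

  result <- list(
    table = table, groupMaps = groupMaps, models = models,
    segmentations = segmentations, metrics = metrics,
    transitions = transitions, subjectK = subjectK, cohortK = cohortK,
    config = config
  )

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(table, file.path(outDir, "features.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
    for (g in groupLevels) {
      m <- groupMaps[[g]]
      utils::write.table(m, file.path(outDir, sprintf("groupmaps_%s.tsv", g)),
        sep = "\t", row.names = FALSE, quote = FALSE
      )
    }
    for (i in seq_along(subjects)) {
      writeSegmentation(
        segmentations[[i]],
        file.path(outDir, sprintf("segmentation_%s.tsv", ids[i]))
      )
    }
    cfg <- config
    cfg$maxMapsForClustering <- if (is.null(cfg$maxMapsForClustering)) NA else cfg$maxMapsForClustering
    cfg$bandHz <- if (is.null(cfg$bandHz)) NA else cfg$bandHz
    cfg$rejectThresholdUv <- if (is.infinite(cfg$rejectThresholdUv)) "Inf" else cfg$rejectThresholdUv
    jsonlite::write_json(
      c(unclass(cfg), list(cohortK = cohortK)),
      file.path(outDir, "config.json"),
      auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  result
}
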