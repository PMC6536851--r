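# Readers and writers: delimited matrices with JSON sidecars, and a minimal
# EDF (European Data Format, 16-bit) implementation for EEG round-trips.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write a Recording to disk
#'
#' \code{"delimited"} writes a tab-separated matrix with a header row of
#' channel labels and one row per sample (columns = channels), plus a JSON
#' sidecar (\code{<path>.json}) holding the sampling rate and reference
#' state. \code{"edf"} writes a minimal single-record EDF file (16-bit).
#'
#' @param rec a [Recording-class].
#' @param path output file path.
#' @param format \code{"delimited"} or \code{"edf"}.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("delimited", "edf")) {
  format <- match.arg(format)
  stopifnot(is(rec, "Recording"))
  if (format == "delimited") {
    m <- t(rec@data)
    colnames(m) <- rec@channelLabels
    utils::write.table(m, path,
      sep = "\t", row.names = FALSE,
      col.names = TRUE, quote = FALSE
    )
    jsonlite::write_json(
      list(fs = rec@fs, reference = rec@reference, unit = "uV"),
      .sidecarPath(path),
      auto_unbox = TRUE, digits = NA
    )
  } else {
    .writeEDF(rec, path)
  }
  invisible(path)
}

#' Read a Recording from disk
#'
#' @param path file path (delimited matrix with a \code{.json} sidecar, or
#'   EDF).
#' @param format \code{"auto"} (by extension), \code{"delimited"} or
#'   \code{"edf"}.
#' @param fs sampling rate override for delimited files without a sidecar.
#' @return a [Recording-class].
#' @export
readRecording <- function(path, format = c("auto", "delimited", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  }
  if (format == "edf") {
    return(.readEDF(path))
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  m <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (ncol(m) != length(header)) {
    stop(sprintf(
      "header/payload mismatch: %d labels vs %d data columns",
      length(header), ncol(m)
    ))
  }
  reference <- "original"
  if (file.exists(.sidecarPath(path))) {
    side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
    if (is.null(fs)) fs <- side$fs
    if (!is.null(side$reference)) reference <- side$reference
  }
  if (is.null(fs)) stop("sampling rate unknown: no sidecar and no fs argument")
  data <- unname(t(as.matrix(m)))
  newRecording(data, fs, channelLabels = header, reference = reference)
}

# ---- minimal EDF (16-bit) ----

.padField <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

.writeEDF <- function(rec, path) {
  x <- rec@data
  nCh <- nrow(x)
  nS <- ncol(x)
  durS <- nS / rec@fs
  physMin <- apply(x, 1L, min)
  physMax <- apply(x, 1L, max)
  flat <- physMax - physMin < 1e-12
  physMax[flat] <- physMin[flat] + 1
  digMin <- -32768
  digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(.padField(s, width), con, nchars = width, eos = NULL)
  wr("0", 8)
  wr("synthetic", 80)
  wr("microdyn recording", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256L + 256L * nCh), 8)
  wr("", 44)
  wr("1", 8) # one data record holding the whole signal
  wr(format(durS, digits = 10), 8)
  wr(as.character(nCh), 4)
  for (f in list(
    list(rec@channelLabels, 16), list(rep("", nCh), 80),
    list(rep("uV", nCh), 8),
    list(format(physMin, digits = 7), 8), list(format(physMax, digits = 7), 8),
    list(rep(as.character(digMin), nCh), 8), list(rep(as.character(digMax), nCh), 8),
    list(rep("", nCh), 80), list(rep(as.character(nS), nCh), 8),
    list(rep("", nCh), 32)
  )) {
    for (v in f[[1]]) wr(v, f[[2]])
  }
  for (ch in seq_len(nCh)) {
    scl <- (digMax - digMin) / (physMax[ch] - physMin[ch])
    dig <- as.integer(round((x[ch, ] - physMin[ch]) * scl + digMin))
    writeBin(dig, con, size = 2L, endian = "little")
  }
  invisible(path)
}

.readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)
  rd(80)
  rd(80)
  rd(8)
  rd(8)
  rd(8)
  rd(44)
  nRec <- as.integer(rd(8))
  durS <- as.numeric(rd(8))
  nCh <- as.integer(rd(4))
  labels <- vapply(seq_len(nCh), function(i) rd(16), "")
  for (i in seq_len(nCh)) rd(80)
  for (i in seq_len(nCh)) rd(8)
  physMin <- vapply(seq_len(nCh), function(i) as.numeric(rd(8)), 0)
  physMax <- vapply(seq_len(nCh), function(i) as.numeric(rd(8)), 0)
  digMin <- vapply(seq_len(nCh), function(i) as.numeric(rd(8)), 0)
  digMax <- vapply(seq_len(nCh), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(nCh)) rd(80)
  spr <- vapply(seq_len(nCh), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(nCh)) rd(32)
  data <- matrix(0, nCh, spr[1] * nRec)
  for (r in seq_len(nRec)) {
    for (ch in seq_len(nCh)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, endian = "little")
      phys <- (dig - digMin[ch]) * (physMax[ch] - physMin[ch]) /
        (digMax[ch] - digMin[ch]) + physMin[ch]
      data[ch, (r - 1L) * spr[ch] + seq_len(spr[ch])] <- phys
    }
  }
  fs <- spr[1] / durS
  newRecording(data, fs, channelLabels = labels, reference = "original")
}

# ---- segmentation / model / ground-truth / network I/O ----

#' Write / read a segmentation as a delimited table
#'
#' Columns: epoch, sample, label (class letter, NA for unassigned),
#' truncated (0/1). A JSON sidecar stores fs, k and the fit mode.
#'
#' @param seg a [Segmentation-class].
#' @param path output path.
#' @return \code{path} invisibly (writer); a [Segmentation-class] (reader).
#' @export
writeSegmentation <- function(seg, path) {
  stopifnot(is(seg, "Segmentation"))
  cn <- .classLetters(seg@k)
  df <- data.frame(
    epoch = rep(seq_len(nrow(seg@labels)), each = ncol(seg@labels)),
    sample = rep(seq_len(ncol(seg@labels)), nrow(seg@labels)),
    label = cn[t(seg@labels)],
    truncated = as.integer(t(seg@truncated))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = seg@fs, k = seg@k, source = seg@source, nPeaks = seg@nPeaks),
    .sidecarPath(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeSegmentation
#' @export
readSegmentation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  k <- as.integer(side$k)
  nEp <- max(df$epoch)
  spe <- max(df$sample)
  lab <- matrix(match(df$label, .classLetters(k)), nEp, spe, byrow = TRUE)
  tr <- matrix(df$truncated == 1L, nEp, spe, byrow = TRUE)
  new("Segmentation",
    labels = lab, truncated = tr, fs = as.numeric(side$fs), k = k,
    source = side$source, nPeaks = as.integer(side$nPeaks)
  )
}

#' Write / read a microstate model
#'
#' Templates as a delimited channels x k matrix (header = class names) plus a
#' JSON sidecar (k, polarity flag, GEV).
#'
#' @param model a [MicrostateModel-class].
#' @param path output path.
#' @return \code{path} invisibly (writer); a [MicrostateModel-class] (reader).
#' @export
writeMicrostateModel <- function(model, path) {
  stopifnot(is(model, "MicrostateModel"))
  tpl <- model@templates
  if (is.null(colnames(tpl))) colnames(tpl) <- .classLetters(model@k)
  utils::write.table(tpl, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      k = model@k, polarityInvariant = model@polarityInvariant,
      gev = model@gev
    ),
    .sidecarPath(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeMicrostateModel
#' @export
readMicrostateModel <- function(path) {
  tpl <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE))
  rownames(tpl) <- NULL
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  new("MicrostateModel",
    templates = tpl, k = as.integer(side$k),
    polarityInvariant = isTRUE(side$polarityInvariant),
    gev = as.numeric(side$gev)
  )
}

#' Write simulated ground truth as a delimited label table
#'
#' One row per sample with epoch, sample and class columns, plus a JSON
#' sidecar of the generator parameters.
#'
#' @param groundTruth the groundTruth list from [simulateMicrostateEEG()].
#' @param path output path.
#' @param fs sampling rate (for the sidecar).
#' @param epochS epoch length used to assign epoch numbers (NULL = single
#'   epoch).
#' @return \code{path}, invisibly.
#' @export
writeGroundTruth <- function(groundTruth, path, fs, epochS = NULL) {
  lab <- groundTruth$labelSequence
  n <- length(lab)
  epoch <- if (is.null(epochS)) rep(1L, n) else (seq_len(n) - 1L) %/% round(fs * epochS) + 1L
  df <- data.frame(epoch = epoch, sample = seq_len(n), class = .classLetters(max(lab))[lab])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      dwellMeanMs = groundTruth$dwellMeanMs, snr = groundTruth$snr,
      seed = groundTruth$seed, fs = fs,
      k = ncol(groundTruth$templates), nChannels = nrow(groundTruth$templates)
    ),
    .sidecarPath(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read network time courses
#'
#' Delimited matrix (header = network names, one row per volume) with the
#' repetition time in a JSON sidecar.
#'
#' @param tcs a [NetworkTimecourseSet-class].
#' @param path output path.
#' @return \code{path} invisibly (writer); a [NetworkTimecourseSet-class]
#'   (reader).
#' @export
writeNetworkTimecourses <- function(tcs, path) {
  stopifnot(is(tcs, "NetworkTimecourseSet"))
  m <- t(tcs@data)
  colnames(m) <- tcs@networkNames
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(tr_s = tcs@trS), .sidecarPath(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname writeNetworkTimecourses
#' @export
readNetworkTimecourses <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  side <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  new("NetworkTimecourseSet",
    data = unname(t(as.matrix(m))), trS = as.numeric(side$tr_s),
    networkNames = colnames(m)
  )
}
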