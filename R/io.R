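# Readers and writers: EEG (EDF/BDF and a plain-text array container),
# audio (WAV), the standard montage, and result objects (CSV for tabular,
# JSON for structured outputs; lossless round-trip).

#' Read the standard 64-channel montage
#'
#' 2-D (azimuthal equidistant) electrode positions for the BioSemi-64
#' layout with 10-20-equivalent labels, shipped with the package.
#'
#' @return data.frame with channel, x, y.
#' @export
readMontage <- function() {
  if (!is.null(.envtrack_cache$montage)) return(.envtrack_cache$montage)
  path <- system.file("extdata", "biosemi64_montage.csv",
                      package = "envtrack", mustWork = TRUE)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  .envtrack_cache$montage <- m
  m
}

# ---- EEG -----------------------------------------------------------------

.read_edf_header_str <- function(con, nchars) {
  trimws(rawToChar(readBin(con, "raw", nchars)))
}

# minimal EDF (16-bit) / BDF (24-bit) reader; continuous recordings only
.read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8L)
  bdf <- magic[1] == as.raw(255)
  fmt <- if (bdf) rawToChar(magic[2:8]) else trimws(rawToChar(magic))
  if (bdf && fmt != "BIOSEMI") stop("unknown format: not EDF/BDF")
  if (!bdf && fmt != "0") stop("unknown format: not EDF/BDF")
  invisible(.read_edf_header_str(con, 160L))       # patient + recording
  invisible(.read_edf_header_str(con, 16L))        # start date + time
  invisible(.read_edf_header_str(con, 8L))         # header bytes
  invisible(.read_edf_header_str(con, 44L))        # reserved
  nRec <- as.integer(.read_edf_header_str(con, 8L))
  recDur <- as.numeric(.read_edf_header_str(con, 8L))
  ns <- as.integer(.read_edf_header_str(con, 4L))
  rd <- function(w) vapply(seq_len(ns), function(i)
    .read_edf_header_str(con, w), character(1))
  labels <- rd(16L)
  invisible(rd(80L)); invisible(rd(8L))            # transducer, dimension
  physMin <- as.numeric(rd(8L)); physMax <- as.numeric(rd(8L))
  digMin <- as.numeric(rd(8L)); digMax <- as.numeric(rd(8L))
  invisible(rd(80L))                               # prefiltering
  spr <- as.integer(rd(8L))                        # samples per record
  invisible(rd(32L))                               # reserved
  if (anyDuplicated(labels)) stop("duplicated channel name in EEG file")
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel rates are not supported")
  scale <- (physMax - physMin) / (digMax - digMin)
  data <- matrix(0, ns, nRec * spr[1])
  for (r in seq_len(nRec)) {
    for (s in seq_len(ns)) {
      if (bdf) {
        b <- readBin(con, "integer", spr[s] * 3L, size = 1L, signed = FALSE)
        b <- matrix(b, 3L)
        v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
        v <- ifelse(v >= 8388608, v - 16777216, v)
      } else {
        v <- readBin(con, "integer", spr[s], size = 2L, endian = "little")
      }
      data[s, (r - 1L) * spr[s] + seq_len(spr[s])] <-
        (v - digMin[s]) * scale[s] + physMin[s]
    }
  }
  list(data = data, channelNames = labels, rate = spr[1] / recDur)
}

# minimal EDF/BDF writer (whole seconds only); used to build test fixtures
.write_edf <- function(data, channelNames, rate, path, bdf = FALSE) {
  ns <- nrow(data)
  stopifnot(ns == length(channelNames), ncol(data) %% rate == 0)
  nRec <- ncol(data) / rate
  pad <- function(x, w) {
    s <- substr(format(x, width = w), 1L, w)
    formatC(s, width = w, flag = "-")
  }
  con <- file(path, "wb")
  on.exit(close(con))
  if (bdf) writeBin(c(as.raw(255), charToRaw("BIOSEMI")), con)
  else writeBin(charToRaw(pad("0", 8L)), con)
  writeBin(charToRaw(paste0(pad("synthetic", 80L), pad("synthetic", 80L),
                            pad("01.01.26", 8L), pad("00.00.00", 8L),
                            pad(256L + ns * 256L, 8L), pad("", 44L),
                            pad(nRec, 8L), pad(1L, 8L), pad(ns, 4L))), con)
  lim <- if (bdf) 8388607 else 32767
  # round the physical range to 4 significant digits so it is stored
  # exactly in the 8-character header field
  pk <- signif(max(abs(data), 1e-12) * 1.001, 4)
  wr <- function(v, w) writeBin(charToRaw(paste0(vapply(
    v, pad, character(1), w = w), collapse = "")), con)
  wr(channelNames, 16L); wr(rep("", ns), 80L); wr(rep("uV", ns), 8L)
  wr(rep(sprintf("%g", -pk), ns), 8L); wr(rep(sprintf("%g", pk), ns), 8L)
  wr(rep(-lim, ns), 8L); wr(rep(lim, ns), 8L)
  wr(rep("", ns), 80L); wr(rep(rate, ns), 8L); wr(rep("", ns), 32L)
  dig <- round(data / pk * lim)
  for (r in seq_len(nRec)) for (s in seq_len(ns)) {
    v <- dig[s, (r - 1L) * rate + seq_len(rate)]
    if (bdf) {
      u <- ifelse(v < 0, v + 16777216, v)
      b <- rbind(u %% 256, (u %/% 256) %% 256, u %/% 65536)
      writeBin(as.integer(b), con, size = 1L)
    } else writeBin(as.integer(v), con, size = 2L, endian = "little")
  }
  invisible(path)
}

# plain-text array container: <path> is a TSV (samples x channels, header
# = channel names) with a JSON sidecar <path>.json holding the rate
.read_eeg_container <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (anyDuplicated(names(dt))) stop("duplicated channel name in EEG file")
  list(data = t(as.matrix(dt)), channelNames = names(dt),
       rate = as.numeric(meta$rate))
}

#' Write EEG to the plain-text array container
#'
#' @param data channels x samples matrix.
#' @param channelNames one name per row.
#' @param rate sampling rate in Hz.
#' @param path output path (a TSV; a .json sidecar is written next to it).
#' @return path, invisibly.
#' @export
writeEEGContainer <- function(data, channelNames, rate, path) {
  stopifnot(nrow(data) == length(channelNames))
  dt <- data.table::as.data.table(t(data))
  data.table::setnames(dt, channelNames)
  data.table::fwrite(dt, path, sep = "\t")
  jsonlite::write_json(list(rate = rate), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multichannel EEG recording
#'
#' Supports EDF (.edf), BDF (.bdf) and the package's plain-text array
#' container (TSV + JSON sidecar). Channel names are preserved in file
#' order; an optional subset is matched case-insensitively and returned in
#' the requested order.
#'
#' @param path file path.
#' @param channelSubset optional channel names to keep.
#' @return list with data (channels x samples), channelNames, rate.
#' @export
readEEG <- function(path, channelSubset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  rec <- if (ext %in% c("edf", "bdf")) .read_edf(path)
         else .read_eeg_container(path)
  if (!is.null(channelSubset)) {
    pos <- match(tolower(channelSubset), tolower(rec$channelNames))
    if (anyNA(pos))
      stop("channel(s) not present: ",
           paste(channelSubset[is.na(pos)], collapse = ", "))
    rec$data <- rec$data[pos, , drop = FALSE]
    rec$channelNames <- rec$channelNames[pos]
  }
  rec
}

#' Align a recording to stimulus onset
#'
#' Drops the samples preceding the stimulus so that stimulus onset is
#' sample 0 of both streams: the subject's \code{alignment_offset} is the
#' recording time (seconds, >= 0) at which the stimulus started.
#'
#' @param eeg channels x samples matrix.
#' @param rate sampling rate in Hz.
#' @param offsetSeconds nonnegative onset time in seconds.
#' @return the trimmed channels x samples matrix.
#' @export
alignToStimulus <- function(eeg, rate, offsetSeconds) {
  if (offsetSeconds < 0) stop("alignment offset must be >= 0")
  drop0 <- round(offsetSeconds * rate)
  if (drop0 >= ncol(eeg)) stop("alignment offset beyond recording end")
  eeg[, (drop0 + 1L):ncol(eeg), drop = FALSE]
}

# ---- audio ---------------------------------------------------------------

#' Read a WAV file
#'
#' PCM-16 and IEEE-float WAV. Multichannel audio is rejected unless
#' \code{mixdown = TRUE}, in which case the channel mean is returned.
#'
#' @param path file path.
#' @param mixdown average channels instead of rejecting multichannel input.
#' @return list with wave (numeric in [-1, 1]) and rate.
#' @export
readAudio <- function(path, mixdown = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- rawToChar(readBin(con, "raw", 4L))
  invisible(readBin(con, "integer", 1L, endian = "little"))
  wave <- rawToChar(readBin(con, "raw", 4L))
  if (riff != "RIFF" || wave != "WAVE") stop("not a WAV file")
  fmt <- NULL; data <- NULL
  repeat {
    id <- readBin(con, "raw", 4L)
    if (length(id) < 4L) break
    sz <- readBin(con, "integer", 1L, endian = "little")
    tag <- rawToChar(id)
    if (tag == "fmt ") {
      fmt <- list(code = readBin(con, "integer", 1L, size = 2L,
                                 endian = "little"),
                  nch = readBin(con, "integer", 1L, size = 2L,
                                endian = "little"),
                  rate = readBin(con, "integer", 1L, endian = "little"))
      invisible(readBin(con, "integer", 1L, endian = "little"))  # byte rate
      invisible(readBin(con, "integer", 1L, size = 2L, endian = "little"))
      fmt$bits <- readBin(con, "integer", 1L, size = 2L, endian = "little")
      if (sz > 16L) invisible(readBin(con, "raw", sz - 16L))
    } else if (tag == "data") {
      data <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz + sz %% 2L))
    }
    if (!is.null(fmt) && !is.null(data)) break
  }
  if (is.null(fmt) || is.null(data)) stop("malformed WAV file")
  x <- if (fmt$code == 1L && fmt$bits == 16L) {
    readBin(data, "integer", length(data) / 2L, size = 2L,
            endian = "little") / 32768
  } else if (fmt$code == 3L && fmt$bits == 32L) {
    readBin(data, "double", length(data) / 4L, size = 4L,
            endian = "little")
  } else stop("unsupported WAV encoding")
  if (fmt$nch > 1L) {
    if (!mixdown)
      stop("multichannel audio; pass mixdown = TRUE to average channels")
    x <- colMeans(matrix(x, fmt$nch))
  }
  list(wave = x, rate = fmt$rate)
}

#' Write a mono/stereo WAV file (PCM-16)
#'
#' @param wave numeric vector in [-1, 1], or a samples x channels matrix.
#' @param rate sampling rate in Hz.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeAudio <- function(wave, rate, path) {
  wm <- as.matrix(wave)
  nch <- ncol(wm)
  pcm <- as.integer(round(pmax(pmin(t(wm), 1), -1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  dataSz <- length(pcm) * 2L
  writeBin(charToRaw("RIFF"), con)
  writeBin(36L + dataSz, con, endian = "little")
  writeBin(charToRaw("WAVEfmt "), con)
  writeBin(16L, con, endian = "little")
  writeBin(c(1L, nch), con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, endian = "little")
  writeBin(as.integer(rate) * nch * 2L, con, endian = "little")
  writeBin(c(nch * 2L, 16L), con, size = 2L, endian = "little")
  writeBin(charToRaw("data"), con)
  writeBin(dataSz, con, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}

# ---- results -------------------------------------------------------------

#' Write a result object to disk
#'
#' Tabular objects (TMIF, StabilityCurve, SplitHalfReport) are written as
#' CSV with a header; structured objects (NullDistribution, ClusterResult,
#' ClassifierReport, AttributionReport) as JSON. All numeric fields
#' round-trip through \code{readResults} within floating tolerance.
#'
#' @param object a supported result object.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeResults <- function(object, path) {
  wjson <- function(x) jsonlite::write_json(
    x, path, auto_unbox = TRUE, digits = NA, null = "null")
  if (is(object, "TMIF")) {
    df <- data.frame(lag_ms = object@lagsMs, object@mi)
    names(df) <- c("lag_ms", if (object@variant == "multivariate") "mi"
                   else object@channelNames)
    utils::write.csv(df, path, row.names = FALSE)
    meta <- list(class = "TMIF", rate = object@rate, band = object@band,
                 variant = object@variant, smoothed = object@smoothed)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else if (is(object, "StabilityCurve")) {
    df <- data.frame(minutes = object@minutes, object@values,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    meta <- list(class = "StabilityCurve", kind = object@kind,
                 knee_minutes = object@kneeMinutes,
                 knee_found = object@kneeFound)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  } else if (is(object, "SplitHalfReport")) {
    utils::write.csv(object@table, path, row.names = FALSE)
    jsonlite::write_json(list(class = "SplitHalfReport",
                              correction = object@correction),
                         paste0(path, ".json"), auto_unbox = TRUE)
  } else if (is(object, "NullDistribution")) {
    wjson(list(class = "NullDistribution", samples = object@samples,
               level = object@level, n_permutations = object@nPermutations,
               band = object@band, subject_id = object@subjectId,
               statistic = object@statistic))
  } else if (is(object, "ClusterResult")) {
    wjson(list(class = "ClusterResult", clusters = object@clusters,
               stat_map = object@statMap, lags_ms = object@lagsMs,
               channel_names = object@channelNames,
               n_permutations = object@nPermutations,
               threshold_alpha = object@thresholdAlpha,
               perm_max = object@permMax))
  } else if (is(object, "ClassifierReport")) {
    wjson(list(class = "ClassifierReport", metrics = object@metrics,
               roc = object@roc, predictions = object@predictions,
               hyperparameters = object@hyperparameters))
  } else if (is(object, "AttributionReport")) {
    wjson(list(class = "AttributionReport",
               values = as.data.frame(object@values),
               baseline = object@baseline, decision = object@decision,
               ranking = object@ranking))
  } else stop("unsupported object of class ", class(object)[1])
  invisible(path)
}

#' Read back a result object written by writeResults
#'
#' @param path file path.
#' @return the reconstructed object.
#' @export
readResults <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    df <- utils::read.csv(path, check.names = FALSE)
    switch(meta$class,
      TMIF = {
        mi <- as.matrix(df[, -1, drop = FALSE])
        chn <- if (meta$variant == "single_channel") colnames(mi)
               else character()
        new("TMIF", mi = mi, lagsMs = df$lag_ms, rate = meta$rate,
            variant = meta$variant, band = meta$band,
            smoothed = meta$smoothed, channelNames = chn)
      },
      StabilityCurve = new("StabilityCurve", minutes = df$minutes,
        values = as.matrix(df[, -1, drop = FALSE]), kind = meta$kind,
        kneeMinutes = meta$knee_minutes, kneeFound = meta$knee_found),
      SplitHalfReport = new("SplitHalfReport", table = df,
                            correction = meta$correction),
      stop("unknown CSV result class: ", meta$class))
  } else {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    switch(x$class,
      NullDistribution = new("NullDistribution", samples = x$samples,
        level = x$level, nPermutations = as.integer(x$n_permutations),
        band = x$band, subjectId = x$subject_id, statistic = x$statistic),
      ClusterResult = new("ClusterResult",
        clusters = as.data.frame(x$clusters),
        statMap = as.matrix(x$stat_map), lagsMs = x$lags_ms,
        channelNames = x$channel_names,
        nPermutations = as.integer(x$n_permutations),
        thresholdAlpha = x$threshold_alpha, permMax = x$perm_max),
      ClassifierReport = new("ClassifierReport", metrics = x$metrics,
        roc = as.data.frame(x$roc),
        predictions = as.data.frame(x$predictions),
        hyperparameters = as.data.frame(x$hyperparameters)),
      AttributionReport = new("AttributionReport",
        values = as.matrix(x$values), baseline = x$baseline,
        decision = x$decision, ranking = x$ranking),
      stop("unknown JSON result class: ", x$class))
  }
}
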