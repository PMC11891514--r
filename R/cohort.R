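# Cohort-level containers: per-subject, per-band TMIFs on a shared lag
# axis, held in a SummarizedExperiment (rows = lags, columns = subjects,
# one assay per band, subject metadata in colData).

#' TMIFCohort: per-subject TMIFs across bands
#'
#' A \linkS4class{SummarizedExperiment} with one assay per frequency band
#' (lags x subjects matrices of multivariate-TMIF values in bits), lag
#' times in rowData (lag_ms), and subject metadata (subject_id, group,
#' age) in colData.
#'
#' @exportClass TMIFCohort
setClass("TMIFCohort", contains = "SummarizedExperiment")

#' Construct a TMIFCohort
#'
#' @param assays named list (band -> lags x subjects matrix).
#' @param lagsMs shared lag grid in ms.
#' @param subjects data.frame with subject_id, group, age.
#' @param variant TMIF variant the assays hold.
#' @param smoothed whether the TMIFs were smoothed.
#' @return a \linkS4class{TMIFCohort}.
#' @export
tmifCohort <- function(assays, lagsMs, subjects, variant = "multivariate",
                       smoothed = TRUE) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(lag_ms = lagsMs),
    colData = S4Vectors::DataFrame(subjects))
  S4Vectors::metadata(se) <- list(variant = variant, smoothed = smoothed)
  new("TMIFCohort", se)
}

#' @describeIn lagTimes TMIFCohort method
setMethod("lagTimes", "TMIFCohort", function(x)
  SummarizedExperiment::rowData(x)$lag_ms)

#' Subject metadata of a TMIFCohort
#' @param cohortTmif a \linkS4class{TMIFCohort}.
#' @return data.frame with subject_id, group, age.
#' @export
subjectInfo <- function(cohortTmif) {
  as.data.frame(SummarizedExperiment::colData(cohortTmif))
}

#' Compute per-subject TMIFs for a synthetic cohort
#'
#' Runs the full subject pipeline per band: leading crop (optional),
#' common-average reference, band filtering, z-scoring, downsampling to
#' the analysis rate, channel selection, TMIF, smoothing.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param bands band names (default: the five narrow bands).
#' @param variant "multivariate" or "single_channel".
#' @param selection channel names for the multivariate TMIF; by default
#'   the intersection of the standard 22-channel selection with the
#'   cohort's channels (all channels when the intersection is empty).
#' @param lagWindowMs lag window in ms.
#' @param analysisRate analysis rate in Hz.
#' @param smooth apply the 9-sample Gaussian lag smoother.
#' @param cropMin leading crop in minutes (NULL = full recording).
#' @return for "multivariate", a \linkS4class{TMIFCohort}; for
#'   "single_channel", a list with fields tmif (per-band list of
#'   lags x channels x subjects arrays), lagsMs, channelNames, subjects.
#' @export
computeCohortTMIFs <- function(cohort,
                               bands = setdiff(names(defaultBands()), "broad"),
                               variant = c("multivariate", "single_channel"),
                               selection = NULL,
                               lagWindowMs = c(-200, 500),
                               analysisRate = 128,
                               smooth = TRUE, cropMin = NULL) {
  variant <- match.arg(variant)
  stopifnot(is(cohort, "SyntheticCohort"))
  rate <- cohort@rate
  env <- cohort@envelope
  eegs <- cohort@eeg
  if (!is.null(cropMin)) {
    nKeep <- round(cropMin * 60 * rate)
    if (nKeep > length(env)) stop("crop longer than recording")
    env <- env[seq_len(nKeep)]
    eegs <- lapply(eegs, function(e) e[, seq_len(nKeep), drop = FALSE])
  }
  if (is.null(selection))
    selection <- intersect(tolower(defaultChannelSelection()),
                           tolower(cohort@channelNames))
  if (!length(selection)) selection <- cohort@channelNames
  nSub <- nrow(cohort@subjects)
  assays <- list()
  scList <- list()
  chnOut <- NULL
  # reference once, then band-filter + z-score + downsample all subjects'
  # channels in one batched FFT pass per band
  nch <- length(cohort@channelNames)
  refAll <- do.call(rbind, lapply(eegs, commonAverageReference))
  for (b in bands) {
    envB <- bandEnvelope(env, b, rate, analysisRate)
    filt <- designBandFilter(defaultBands()[[b]], rate)
    ordMax <- max(filt$highpass$order,
                  if (is.null(filt$lowpass)) 0L else filt$lowpass$order)
    if (ncol(refAll) < 3L * ordMax)
      stop("signal too short for filter order")
    y <- applyBandFilter(t(refAll), filt)
    y <- scale(y)
    y <- fftResample(y, rate, analysisRate)
    mats <- vector("list", nSub)
    for (i in seq_len(nSub)) {
      eb <- new("EEGBand",
                matrix = t(y[, (i - 1L) * nch + seq_len(nch), drop = FALSE]),
                rate = analysisRate, band = b,
                channelNames = cohort@channelNames)
      if (variant == "multivariate") eb <- selectChannels(eb, selection)
      tm <- computeTMIF(eb, envB, lagWindowMs, variant)
      if (smooth) tm <- smoothTMIF(tm)
      mats[[i]] <- tm@mi
      if (is.null(chnOut)) chnOut <- tm@channelNames
      lagsMs <- tm@lagsMs
    }
    if (variant == "multivariate") {
      assays[[b]] <- do.call(cbind, lapply(mats, drop))
      colnames(assays[[b]]) <- cohort@subjects$subject_id
    } else {
      scList[[b]] <- array(
        unlist(mats), dim = c(length(lagsMs), length(chnOut), nSub),
        dimnames = list(NULL, chnOut, cohort@subjects$subject_id))
    }
  }
  if (variant == "multivariate")
    return(tmifCohort(assays, lagsMs, cohort@subjects,
                      variant = variant, smoothed = smooth))
  list(tmif = scList, lagsMs = lagsMs, channelNames = chnOut,
       subjects = cohort@subjects)
}

#' Group-difference cluster test on a TMIFCohort band
#'
#' Convenience wrapper running the temporal cluster-based permutation
#' test on one band's assay.
#'
#' @param cohortTmif a \linkS4class{TMIFCohort}.
#' @param band assay name.
#' @param ... passed to \code{clusterPermutationTest}.
#' @return a \linkS4class{ClusterResult}.
#' @export
cohortClusterTest <- function(cohortTmif, band, ...) {
  x <- SummarizedExperiment::assay(cohortTmif, band)
  clusterPermutationTest(x, subjectInfo(cohortTmif)$group,
                         lagTimes(cohortTmif), ...)
}
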