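#' @import methods
#' @importFrom stats sd
NULL

# Moment tolerance for z-scored containers. Signals are z-scored at the
# intermediate rate and then anti-alias downsampled, so the stored moments
# drift slightly from (0, 1); 0.02 bounds that drift for any signal long
# enough to satisfy the filtering preconditions.
.MOMENT_TOL <- 0.02

#' BandEnvelope: band-filtered, z-scored stimulus envelope
#'
#' Holds the speech envelope after band filtering, z-scoring and
#' downsampling to the analysis rate. This is the stimulus-side variable of
#' the mutual-information analysis.
#'
#' @slot samples numeric vector of z-scored envelope samples (unitless).
#' @slot rate sampling rate in Hz (analysis rate, 128 by default).
#' @slot band band name (e.g. "delta").
#' @slot bandLimits numeric length-2, passband edges in Hz.
#' @exportClass BandEnvelope
setClass("BandEnvelope",
  representation(samples = "numeric", rate = "numeric",
                 band = "character", bandLimits = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) < 2L) msg <- c(msg, "envelope too short")
    if (!all(is.finite(object@samples))) msg <- c(msg, "non-finite samples")
    if (length(object@rate) != 1L || object@rate <= 0)
      msg <- c(msg, "rate must be a positive scalar")
    if (length(object@bandLimits) != 2L ||
        !(object@bandLimits[1] < object@bandLimits[2]))
      msg <- c(msg, "bandLimits must be increasing [low, high]")
    if (all(is.finite(object@samples)) && length(object@samples) >= 2L) {
      if (abs(mean(object@samples)) > .MOMENT_TOL)
        msg <- c(msg, "envelope mean not ~0 (not z-scored?)")
      if (abs(sd(object@samples) - 1) > .MOMENT_TOL)
        msg <- c(msg, "envelope SD not ~1 (not z-scored?)")
    }
    if (length(msg)) msg else TRUE
  })

#' EEGBand: band-filtered, referenced, z-scored EEG
#'
#' Channels-by-samples EEG matrix after common-average referencing, band
#' filtering, per-channel z-scoring and downsampling to the analysis rate.
#'
#' @slot matrix numeric matrix, channels x samples.
#' @slot rate sampling rate in Hz.
#' @slot band band name.
#' @slot channelNames character vector, one name per row.
#' @exportClass EEGBand
setClass("EEGBand",
  representation(matrix = "matrix", rate = "numeric",
                 band = "character", channelNames = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@matrix) != length(object@channelNames))
      msg <- c(msg, "row count must equal number of channel names")
    if (anyDuplicated(tolower(object@channelNames)))
      msg <- c(msg, "duplicated channel names")
    if (!all(is.finite(object@matrix))) msg <- c(msg, "non-finite samples")
    else {
      m <- rowMeans(object@matrix)
      s <- apply(object@matrix, 1L, sd)
      if (any(abs(m) > .MOMENT_TOL) || any(abs(s - 1) > .MOMENT_TOL))
        msg <- c(msg, "per-channel moments not ~(0, 1) (not z-scored?)")
    }
    if (length(msg)) msg else TRUE
  })

#' TMIF: temporal mutual information function
#'
#' Mutual information in bits between the speech envelope and the EEG as a
#' function of the lag between them, over the integration window
#' (-200..500 ms by default). The single-channel variant stores one MI trace
#' per channel (columns); the multivariate variant a single trace computed
#' from all selected channels jointly.
#'
#' @slot mi numeric matrix, lags x channels (one column for multivariate).
#' @slot lagsMs lag grid in milliseconds.
#' @slot rate analysis rate in Hz.
#' @slot variant "single_channel" or "multivariate".
#' @slot band band name.
#' @slot smoothed logical, whether the along-lag Gaussian smoother was applied.
#' @slot channelNames channel names (length 0 for multivariate).
#' @exportClass TMIF
setClass("TMIF",
  representation(mi = "matrix", lagsMs = "numeric", rate = "numeric",
                 variant = "character", band = "character",
                 smoothed = "logical", channelNames = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@mi) != length(object@lagsMs))
      msg <- c(msg, "mi rows must match lag grid")
    if (!object@variant %in% c("single_channel", "multivariate"))
      msg <- c(msg, "unknown variant")
    if (any(object@mi < -1e-9)) msg <- c(msg, "negative MI")
    if (is.unsorted(object@lagsMs, strictly = TRUE))
      msg <- c(msg, "lag grid must be strictly increasing")
    if (length(msg)) msg else TRUE
  })

#' NullDistribution: surrogate-based per-subject significance level
#'
#' Summary statistics of TMIFs computed against spectrum-matched surrogate
#' envelopes, and the derived 95th-percentile significance level.
#'
#' @slot samples surrogate statistic values in bits.
#' @slot level significance level in bits (nearest-rank 95th percentile).
#' @slot nPermutations number of surrogates.
#' @slot band band name.
#' @slot subjectId subject identifier.
#' @slot statistic summary statistic used ("mean_mi" or "max_mi").
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(samples = "numeric", level = "numeric",
                 nPermutations = "integer", band = "character",
                 subjectId = "character", statistic = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@samples) != object@nPermutations)
      msg <- c(msg, "sample count must equal nPermutations")
    k <- ceiling(0.95 * object@nPermutations)
    if (length(object@samples) &&
        abs(object@level - sort(object@samples)[k]) > 1e-12)
      msg <- c(msg, "level must be the nearest-rank 95th percentile")
    if (length(msg)) msg else TRUE
  })

#' ClusterResult: cluster-based permutation test outcome
#'
#' @slot clusters data.frame with one row per candidate cluster: sign,
#'   lag extent (ms), mass, p-value, and (spatio-temporal only) member
#'   channels as a comma-separated string.
#' @slot statMap observed samplewise statistic map (lags x channels).
#' @slot lagsMs lag grid.
#' @slot channelNames channel names ("" for temporal-only tests).
#' @slot nPermutations number of relabelings.
#' @slot thresholdAlpha cluster-forming alpha.
#' @slot permMax permutation distribution of the max |cluster mass|.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(clusters = "data.frame", statMap = "matrix",
                 lagsMs = "numeric", channelNames = "character",
                 nPermutations = "integer", thresholdAlpha = "numeric",
                 permMax = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@clusters)) {
      lo <- 1 / (object@nPermutations + 1)
      if (any(object@clusters$p < lo - 1e-12 | object@clusters$p > 1 + 1e-12))
        msg <- c(msg, "cluster p-values outside [1/(n+1), 1]")
    }
    if (length(msg)) msg else TRUE
  })

#' ClassifierReport: nested cross-validated SVM performance
#'
#' @slot metrics named list: accuracy, f1, auc, sensitivity, specificity.
#' @slot roc data.frame with fpr and tpr columns (monotone nondecreasing).
#' @slot predictions data.frame: subject_id, label, predicted, decision.
#' @slot hyperparameters data.frame: per outer fold the chosen C and
#'   pruning length.
#' @exportClass ClassifierReport
setClass("ClassifierReport",
  representation(metrics = "list", roc = "data.frame",
                 predictions = "data.frame", hyperparameters = "data.frame"),
  validity = function(object) {
    msg <- character()
    pr <- unlist(object@metrics[c("accuracy", "f1", "auc",
                                  "sensitivity", "specificity")])
    if (any(!is.na(pr) & (pr < 0 | pr > 1)))
      msg <- c(msg, "metrics must lie in [0, 1]")
    if (nrow(object@roc) &&
        (is.unsorted(object@roc$fpr) || is.unsorted(object@roc$tpr)))
      msg <- c(msg, "ROC must be monotone nondecreasing")
    if (length(msg)) msg else TRUE
  })

#' AttributionReport: grouped Shapley feature attribution
#'
#' @slot values subjects x feature-group matrix of signed Shapley values
#'   (positive pushes toward the aphasia class).
#' @slot baseline expected decision value over the background sample.
#' @slot decision per-subject decision values being explained.
#' @slot ranking feature groups ordered by mean absolute attribution.
#' @exportClass AttributionReport
setClass("AttributionReport",
  representation(values = "matrix", baseline = "numeric",
                 decision = "numeric", ranking = "character"))

#' StabilityCurve: value of a metric as a function of recording length
#'
#' @slot minutes strictly increasing duration grid in minutes.
#' @slot values matrix durations x series (bands, or performance metrics).
#' @slot kind one of "svm_performance", "within_subject", "between_subject".
#' @slot kneeMinutes knee-point location on the (averaged) curve.
#' @slot kneeFound FALSE when no knee exists (e.g. linear curve); in that
#'   case kneeMinutes is the last grid value.
#' @exportClass StabilityCurve
setClass("StabilityCurve",
  representation(minutes = "numeric", values = "matrix", kind = "character",
                 kneeMinutes = "numeric", kneeFound = "logical"),
  validity = function(object) {
    msg <- character()
    if (is.unsorted(object@minutes, strictly = TRUE))
      msg <- c(msg, "minutes grid must be strictly increasing")
    if (nrow(object@values) != length(object@minutes))
      msg <- c(msg, "values rows must match minutes grid")
    if (!object@kind %in% c("svm_performance", "within_subject",
                            "between_subject"))
      msg <- c(msg, "unknown curve kind")
    if (!object@kneeMinutes %in% object@minutes)
      msg <- c(msg, "kneeMinutes must be a grid value")
    if (length(msg)) msg else TRUE
  })

#' SplitHalfReport: split-half reliability table
#'
#' One row per band x group with the one-way random-effects ICC between the
#' two recording halves, its F-based 95% CI, corrected p-value, and the
#' per-band Fisher-z comparison of the two groups' ICCs.
#'
#' @slot table data.frame: band, group, n, icc, ci_lower, ci_upper, p,
#'   p_corrected, fisher_z_p.
#' @slot correction multiple-comparison correction method used.
#' @exportClass SplitHalfReport
setClass("SplitHalfReport",
  representation(table = "data.frame", correction = "character"),
  validity = function(object) {
    msg <- character()
    tb <- object@table
    if (nrow(tb)) {
      if (any(tb$icc < -1 - 1e-9 | tb$icc > 1 + 1e-9))
        msg <- c(msg, "ICC outside [-1, 1]")
      if (any(tb$ci_lower > tb$icc + 1e-9 | tb$ci_upper < tb$icc - 1e-9))
        msg <- c(msg, "CI must bracket the estimate")
    }
    if (length(msg)) msg else TRUE
  })

# ---- show methods --------------------------------------------------------

setMethod("show", "BandEnvelope", function(object) {
  cat(sprintf("BandEnvelope '%s' [%g-%g Hz], %d samples @ %g Hz (%.1f s)\n",
              object@band, object@bandLimits[1], object@bandLimits[2],
              length(object@samples), object@rate,
              length(object@samples) / object@rate))
})

setMethod("show", "EEGBand", function(object) {
  cat(sprintf("EEGBand '%s': %d channels x %d samples @ %g Hz\n",
              object@band, nrow(object@matrix), ncol(object@matrix),
              object@rate))
})

setMethod("show", "TMIF", function(object) {
  cat(sprintf("TMIF (%s, band '%s'%s): %d lags [%g..%g ms]",
              object@variant, object@band,
              if (object@smoothed) ", smoothed" else "",
              length(object@lagsMs), min(object@lagsMs), max(object@lagsMs)))
  if (object@variant == "single_channel")
    cat(sprintf(" x %d channels", ncol(object@mi)))
  cat(sprintf("; peak %.4g bits @ %g ms\n", max(object@mi),
              object@lagsMs[which.max(rowSums(object@mi))]))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution (%s, band '%s', subject '%s'): %d surrogates, 95th pct level = %.4g bits\n",
    object@statistic, object@band, object@subjectId,
    object@nPermutations, object@level))
})

setMethod("show", "ClusterResult", function(object) {
  sig <- sum(object@clusters$p < 0.05)
  cat(sprintf("ClusterResult: %d candidate cluster(s), %d with p < 0.05 (%d permutations)\n",
              nrow(object@clusters), sig, object@nPermutations))
  if (nrow(object@clusters)) print(object@clusters[, setdiff(
    names(object@clusters), "channels"), drop = FALSE])
})

setMethod("show", "ClassifierReport", function(object) {
  m <- object@metrics
  cat(sprintf(
    "ClassifierReport: accuracy %.2f%%, F1 %.2f%%, AUC %.2f%%, sensitivity %.2f%%, specificity %.2f%%\n",
    100 * m$accuracy, 100 * m$f1, 100 * m$auc,
    100 * m$sensitivity, 100 * m$specificity))
})

setMethod("show", "AttributionReport", function(object) {
  cat("AttributionReport; feature groups by mean |Shapley|:\n  ")
  cat(paste(object@ranking, collapse = " > "), "\n")
})

setMethod("show", "StabilityCurve", function(object) {
  cat(sprintf("StabilityCurve (%s): %d durations [%g..%g min], knee at %g min%s\n",
              object@kind, length(object@minutes), min(object@minutes),
              max(object@minutes), object@kneeMinutes,
              if (object@kneeFound) "" else " (no knee found)"))
})

setMethod("show", "SplitHalfReport", function(object) {
  cat(sprintf("SplitHalfReport (%s-corrected):\n", object@correction))
  print(object@table)
})
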