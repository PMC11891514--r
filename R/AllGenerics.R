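# Accessor generics. Slot access from user code goes through these.

#' Mutual information values
#'
#' @param x a TMIF or NullDistribution.
#' @return numeric matrix (lags x channels) for a TMIF; numeric vector of
#'   surrogate statistics for a NullDistribution.
#' @export
setGeneric("miValues", function(x) standardGeneric("miValues"))

#' Lag grid in milliseconds
#' @param x a TMIF or ClusterResult.
#' @return numeric vector of lags in ms.
#' @export
setGeneric("lagTimes", function(x) standardGeneric("lagTimes"))

#' Sampling rate in Hz
#' @param x a BandEnvelope, EEGBand or TMIF.
#' @return numeric scalar.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Band name
#' @param x a BandEnvelope, EEGBand, TMIF or NullDistribution.
#' @return character scalar.
#' @export
setGeneric("bandName", function(x) standardGeneric("bandName"))

#' Channel names
#' @param x an EEGBand or TMIF.
#' @return character vector.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Signal samples
#' @param x a BandEnvelope (vector) or EEGBand (channels x samples matrix).
#' @return numeric vector or matrix.
#' @export
setGeneric("signalSamples", function(x) standardGeneric("signalSamples"))

#' Significance level (bits)
#' @param x a NullDistribution.
#' @return numeric scalar, the nearest-rank 95th percentile.
#' @export
setGeneric("significanceLevel", function(x) standardGeneric("significanceLevel"))

#' Cluster table
#' @param x a ClusterResult.
#' @return data.frame of candidate clusters with masses and p-values.
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Performance metrics
#' @param x a ClassifierReport.
#' @return named list with accuracy, f1, auc, sensitivity, specificity.
#' @export
setGeneric("performanceMetrics", function(x) standardGeneric("performanceMetrics"))

#' Knee point of a stability/performance curve
#' @param x a StabilityCurve.
#' @return numeric scalar in minutes.
#' @export
setGeneric("kneeMinutes", function(x) standardGeneric("kneeMinutes"))

#' @describeIn miValues TMIF method
setMethod("miValues", "TMIF", function(x) x@mi)
#' @describeIn miValues NullDistribution method (surrogate samples)
setMethod("miValues", "NullDistribution", function(x) x@samples)

#' @describeIn lagTimes TMIF method
setMethod("lagTimes", "TMIF", function(x) x@lagsMs)
#' @describeIn lagTimes ClusterResult method
setMethod("lagTimes", "ClusterResult", function(x) x@lagsMs)

#' @describeIn samplingRate BandEnvelope method
setMethod("samplingRate", "BandEnvelope", function(x) x@rate)
#' @describeIn samplingRate EEGBand method
setMethod("samplingRate", "EEGBand", function(x) x@rate)
#' @describeIn samplingRate TMIF method
setMethod("samplingRate", "TMIF", function(x) x@rate)

#' @describeIn bandName BandEnvelope method
setMethod("bandName", "BandEnvelope", function(x) x@band)
#' @describeIn bandName EEGBand method
setMethod("bandName", "EEGBand", function(x) x@band)
#' @describeIn bandName TMIF method
setMethod("bandName", "TMIF", function(x) x@band)
#' @describeIn bandName NullDistribution method
setMethod("bandName", "NullDistribution", function(x) x@band)

#' @describeIn channelNames EEGBand method
setMethod("channelNames", "EEGBand", function(x) x@channelNames)
#' @describeIn channelNames TMIF method
setMethod("channelNames", "TMIF", function(x) x@channelNames)

#' @describeIn signalSamples BandEnvelope method
setMethod("signalSamples", "BandEnvelope", function(x) x@samples)
#' @describeIn signalSamples EEGBand method
setMethod("signalSamples", "EEGBand", function(x) x@matrix)

#' @describeIn significanceLevel NullDistribution method
setMethod("significanceLevel", "NullDistribution", function(x) x@level)

#' @describeIn clusterTable ClusterResult method
setMethod("clusterTable", "ClusterResult", function(x) x@clusters)

#' @describeIn performanceMetrics ClassifierReport method
setMethod("performanceMetrics", "ClassifierReport", function(x) x@metrics)

#' @describeIn kneeMinutes StabilityCurve method
setMethod("kneeMinutes", "StabilityCurve", function(x) x@kneeMinutes)
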