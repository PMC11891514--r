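# EEG conditioning from the filtering step onward: common-average
# reference, band filtering with the shared least-squares filters,
# z-scoring, downsampling, channel selection. Input EEG is assumed
# artefact-cleaned.

#' Common-average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, so
#' the channel mean is zero at every sample.
#'
#' @param eeg channels x samples numeric matrix.
#' @return re-referenced matrix of the same shape.
#' @export
commonAverageReference <- function(eeg) {
  if (!is.matrix(eeg) || nrow(eeg) < 2L)
    stop("common-average reference needs at least 2 channels")
  sweep(eeg, 2L, colMeans(eeg))
}

#' Condition referenced EEG into a frequency band
#'
#' Applies the band's least-squares FIR filters (shared with the envelope
#' path) per channel, z-scores each channel, and anti-alias downsamples to
#' the analysis rate.
#'
#' @param eeg channels x samples matrix at the intermediate rate, already
#'   common-average referenced.
#' @param band band name or [low, high] Hz.
#' @param channelNames one name per row of \code{eeg}.
#' @param rate input rate in Hz (default 512).
#' @param analysisRate output rate in Hz (default 128).
#' @return an \linkS4class{EEGBand}.
#' @export
conditionEEG <- function(eeg, band, channelNames, rate = 512,
                         analysisRate = 128) {
  stopifnot(is.matrix(eeg), nrow(eeg) == length(channelNames))
  bandName <- if (is.character(band)) band else
    sprintf("%g-%gHz", band[1], band[2])
  limits <- if (is.character(band)) defaultBands()[[band]] else band
  if (is.null(limits)) stop("unknown band name: ", bandName)
  filt <- designBandFilter(limits, rate)
  ordMax <- max(filt$highpass$order,
                if (is.null(filt$lowpass)) 0L else filt$lowpass$order)
  if (ncol(eeg) < 3L * ordMax)
    stop("signal too short for filter order")
  y <- applyBandFilter(t(eeg), filt)          # samples x channels
  y <- scale(y)                               # per-channel z-score
  y <- fftResample(y, rate, analysisRate)
  new("EEGBand", matrix = t(y), rate = analysisRate, band = bandName,
      channelNames = channelNames)
}

#' Subset and reorder channels of an EEGBand
#'
#' Names are matched case-insensitively; rows are returned in selection
#' order.
#'
#' @param eegBand an \linkS4class{EEGBand}.
#' @param selection character vector of channel names.
#' @return an \linkS4class{EEGBand} with the selected rows.
#' @export
selectChannels <- function(eegBand, selection) {
  stopifnot(is(eegBand, "EEGBand"))
  pos <- match(tolower(selection), tolower(eegBand@channelNames))
  if (anyNA(pos))
    stop("channel(s) not present: ",
         paste(selection[is.na(pos)], collapse = ", "))
  initialize(eegBand,
             matrix = eegBand@matrix[pos, , drop = FALSE],
             channelNames = eegBand@channelNames[pos])
}
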