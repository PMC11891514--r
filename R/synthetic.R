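# Synthetic study generator: speech-like envelopes, single-subject EEG
# formed by convolving band-filtered envelopes with a two-peaked response
# kernel projected onto a fronto-central topography plus 1/f noise, and
# two-group cohorts with an aphasia-like attenuation of the second
# response peak in delta, theta and gamma.

.AFFECTED_BANDS <- c("delta", "theta", "gamma")

#' ResponseKernel: two-peaked envelope-response kernel
#'
#' The impulse response linking the speech envelope to the EEG, with peaks
#' at the canonical latencies of the envelope-tracking response (50 and
#' 170 ms). The second peak is scaled by \code{peak2Scale} to model the
#' group effect (1 = intact, 0 = absent).
#'
#' @slot lagsMs lag grid in ms (support within [0, 500]).
#' @slot amplitudes lags x bands matrix of kernel amplitudes.
#' @slot bands band names (columns).
#' @slot peak1Ms,peak2Ms peak latencies in ms.
#' @slot peak2Scale attenuation factor applied to the second peak.
#' @exportClass ResponseKernel
setClass("ResponseKernel",
  representation(lagsMs = "numeric", amplitudes = "matrix",
                 bands = "character", peak1Ms = "numeric",
                 peak2Ms = "numeric", peak2Scale = "numeric"),
  validity = function(object) {
    msg <- character()
    if (min(object@lagsMs) < 0 || max(object@lagsMs) > 500)
      msg <- c(msg, "kernel support must lie within [0, 500] ms")
    if (object@peak1Ms >= object@peak2Ms)
      msg <- c(msg, "peak1 latency must precede peak2 latency")
    if (object@peak2Scale < 0 || object@peak2Scale > 1)
      msg <- c(msg, "peak2Scale must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Build a response kernel
#'
#' Two Gaussian bumps at \code{peak1Ms} and \code{peak2Ms} (SDs 12 and
#' 30 ms), the second carrying most of the energy and scaled by
#' \code{peak2Scale}. The same shape is used for every band.
#'
#' @param rate sampling rate of the kernel in Hz.
#' @param bands band names the kernel applies to.
#' @param peak1Ms,peak2Ms peak latencies in ms.
#' @param peak2Scale second-peak attenuation in [0, 1].
#' @param scaledBands bands whose second peak receives the attenuation
#'   (others keep scale 1).
#' @return a \linkS4class{ResponseKernel}.
#' @export
responseKernel <- function(rate, bands = names(defaultBands()),
                           peak1Ms = 50, peak2Ms = 170, peak2Scale = 1,
                           scaledBands = .AFFECTED_BANDS) {
  lagsMs <- seq(0, 400, by = 1000 / rate)
  p1 <- 0.6 * exp(-(lagsMs - peak1Ms)^2 / (2 * 12^2))
  p2 <- exp(-(lagsMs - peak2Ms)^2 / (2 * 30^2))
  amps <- sapply(bands, function(b) {
    s <- if (b %in% scaledBands) peak2Scale else 1
    p1 + s * p2
  })
  new("ResponseKernel", lagsMs = lagsMs,
      amplitudes = matrix(amps, ncol = length(bands),
                          dimnames = list(NULL, bands)),
      bands = bands, peak1Ms = peak1Ms, peak2Ms = peak2Ms,
      peak2Scale = peak2Scale)
}

#' CohortSpec: synthetic two-group study conditions
#'
#' @slot nControl,nAphasia subjects per group.
#' @slot snrDb per-band in-band SNR of the envelope response relative to
#'   the 1/f noise, in dB (named vector or one value for all bands).
#' @slot effect per-band second-peak scale for the aphasia group (named
#'   vector or one value; applied to delta, theta and gamma only).
#' @slot durationMin recording length in minutes.
#' @slot nChannels number of EEG channels.
#' @slot seed cohort seed; per-subject seeds derive from it by counter.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nControl = "integer", nAphasia = "integer",
                 snrDb = "numeric", effect = "numeric",
                 durationMin = "numeric", nChannels = "integer",
                 seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nControl < 1L || object@nAphasia < 1L)
      msg <- c(msg, "need at least one subject per group")
    if (object@durationMin <= 0) msg <- c(msg, "durationMin must be > 0")
    if (any(object@effect < 0 | object@effect > 1))
      msg <- c(msg, "effect values must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  })

#' Construct a CohortSpec
#'
#' Defaults mirror the study conditions the analysis is designed for: a
#' 25-minute narrated story, 64 channels, a modest in-band SNR of -5 dB,
#' and a 50% attenuation of the second response peak in the affected bands
#' for the aphasia group.
#'
#' @param nControl,nAphasia subjects per group.
#' @param snrDb in-band SNR in dB (scalar or named per band). Inf
#'   disables the noise entirely; -Inf gives a no-response subject whose
#'   EEG is 1/f noise only.
#' @param effect aphasia-group second-peak scale (scalar or named per
#'   band); 1 means no group difference.
#' @param durationMin recording length in minutes.
#' @param nChannels number of channels (taken from the standard montage,
#'   fronto-central and parieto-occipital first).
#' @param seed cohort seed.
#' @return a \linkS4class{CohortSpec}.
#' @export
cohortSpec <- function(nControl, nAphasia, snrDb = -5, effect = 0.5,
                       durationMin = 25, nChannels = 64L, seed = 1L) {
  new("CohortSpec", nControl = as.integer(nControl),
      nAphasia = as.integer(nAphasia), snrDb = snrDb, effect = effect,
      durationMin = durationMin, nChannels = as.integer(nChannels),
      seed = as.integer(seed))
}

#' Generate a speech-like envelope
#'
#' Rectified spectrally shaped Gaussian noise: the modulation spectrum is
#' low-pass with a bump at the syllable rate (~4 Hz), which places the
#' spectral peak of the z-scored envelope in the 1-8 Hz region as for
#' narrated speech.
#'
#' @param durationS duration in seconds.
#' @param rate sampling rate in Hz.
#' @param seed RNG seed (the global RNG state is modified).
#' @return nonnegative numeric envelope of length durationS * rate.
#' @export
genEnvelope <- function(durationS, rate, seed = 1L) {
  stopifnot(durationS > 0)
  set.seed(seed)
  n <- round(durationS * rate)
  noise <- stats::rnorm(n)
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f)                      # two-sided frequency axis
  W <- 1 / (1 + (f / 4)^1.5) + 1.5 * exp(-(f - 4)^2 / (2 * 1.5^2))
  x <- Re(stats::fft(stats::fft(noise) * W, inverse = TRUE)) / n
  pmax(x, 0)
}

# two-sided 1/f (power ~ 1/f) amplitude weights on the length-n FFT grid
.pink_weights <- function(n, rate) {
  f <- seq(0, rate, length.out = n + 1L)[seq_len(n)]
  f <- pmin(f, rate - f)
  1 / sqrt(pmax(f, 0.1))
}

# amplitude response of a designed band filter on the length-n FFT grid
.band_filter_amp <- function(filt, n) {
  resp <- function(h) Mod(stats::fft(c(h, numeric(n - length(h)))))
  a <- resp(filt$highpass$h)
  if (!is.null(filt$lowpass)) a <- a * resp(filt$lowpass$h)
  a
}

# group-shared pieces of the subject generator: clean signals per group
# and the spectral noise weights that realize the per-band SNR
.subject_prep <- function(envelope, kernel, spec, channelNames,
                          rate = 512) {
  n <- length(envelope)
  gain <- .topography_gain(channelNames)
  bands <- setdiff(names(defaultBands()), "broad")
  snr <- .per_band(spec@snrDb, bands)
  effect <- .per_band(spec@effect, bands)
  pinkA <- .pink_weights(n, rate)
  sig <- list(control = numeric(n), aphasia = numeric(n))
  Wn <- list(control = numeric(n), aphasia = numeric(n))
  for (b in bands) {
    filt <- designBandFilter(b, rate)
    envB <- applyBandFilter(envelope, filt)
    p1 <- 0.6 * exp(-(kernel@lagsMs - kernel@peak1Ms)^2 / (2 * 12^2))
    p2 <- exp(-(kernel@lagsMs - kernel@peak2Ms)^2 / (2 * 30^2))
    noiseFree <- is.infinite(snr[b]) && snr[b] > 0
    noResponse <- is.infinite(snr[b]) && snr[b] < 0
    ampB <- if (noiseFree) 0 else {
      a <- pinkA * .band_filter_amp(filt, n)
      sqrt(mean(a^2))               # unit-white input -> band noise RMS
    }
    for (g in c("control", "aphasia")) {
      s <- if (g == "aphasia") effect[b] else 1
      sigB <- fftConvolve(envB, p1 + s * p2)[seq_len(n)]
      if (noResponse) {
        # snr of -Inf: a no-response subject -- 1/f noise only, scaled to
        # the power the response would have had
        pSig <- mean(sigB^2) * mean(gain^2)
        Wn[[g]] <- Wn[[g]] + sqrt(pSig) / ampB * pinkA *
          .band_filter_amp(filt, n)
      } else {
        sig[[g]] <- sig[[g]] + sigB
        if (!noiseFree) {
          pSig <- mean(sigB^2) * mean(gain^2)
          scl <- sqrt(pSig / (ampB^2 * 10^(snr[b] / 10)))
          Wn[[g]] <- Wn[[g]] + scl * pinkA * .band_filter_amp(filt, n)
        }
      }
    }
  }
  list(signal = sig, noiseWeights = Wn, gain = gain, n = n)
}

# raised-cosine topography gain centred on the fronto-central channels
.topography_gain <- function(channelNames, montage = readMontage()) {
  pos <- montage[match(tolower(channelNames), tolower(montage$channel)), ]
  if (anyNA(pos$x))
    stop("channel(s) absent from montage: ",
         paste(channelNames[is.na(pos$x)], collapse = ", "))
  centre <- colMeans(montage[tolower(montage$channel) %in%
                               tolower(c("FCz", "FC1", "FC2", "Cz")),
                             c("x", "y")])
  d <- sqrt((pos$x - centre[1])^2 + (pos$y - centre[2])^2)
  r0 <- 1.6
  0.15 + 0.85 * 0.5 * (1 + cos(pi * pmin(d / r0, 1)))
}

#' Generate one subject's multichannel EEG
#'
#' The clean signal is the sum over narrow bands of (band-filtered
#' envelope convolved with the band's kernel), with the second kernel peak
#' attenuated by the per-band effect when the subject belongs to the
#' aphasia group. The signal is projected to channels by a smooth
#' fronto-central topography gain and 1/f Gaussian noise is added per
#' channel, scaled so the in-band SNR matches the cohort specification.
#'
#' @param envelope raw (nonnegative) envelope at \code{rate}.
#' @param kernel a \linkS4class{ResponseKernel} at \code{rate} (its
#'   peak2Scale is ignored; the per-band scale comes from \code{spec}).
#' @param spec a \linkS4class{CohortSpec}.
#' @param group "control" or "aphasia".
#' @param seed subject RNG seed.
#' @param channelNames channel labels (must exist in the montage).
#' @param rate sampling rate in Hz (default 512).
#' @param prep group-shared precomputation from an earlier call for the
#'   same envelope/kernel/spec (built automatically when NULL; cohort
#'   generation reuses it across subjects).
#' @return channels x samples numeric matrix.
#' @export
genSubjectEEG <- function(envelope, kernel, spec, group, seed,
                          channelNames, rate = 512, prep = NULL) {
  stopifnot(is(kernel, "ResponseKernel"), is(spec, "CohortSpec"),
            group %in% c("control", "aphasia"))
  n <- length(envelope)
  if (length(kernel@lagsMs) >= n) stop("kernel longer than envelope")
  if (is.null(prep))
    prep <- .subject_prep(envelope, kernel, spec, channelNames, rate)
  set.seed(seed)
  nch <- length(channelNames)
  eeg <- outer(prep$gain, prep$signal[[group]])
  W <- prep$noiseWeights[[group]]
  if (any(W > 0)) {
    white <- matrix(stats::rnorm(n * nch), n, nch)
    noise <- Re(stats::mvfft(stats::mvfft(white) * W, inverse = TRUE)) / n
    eeg <- eeg + t(noise)
  }
  eeg
}

.per_band <- function(x, bands) {
  if (length(x) == 1L && is.null(names(x)))
    return(stats::setNames(rep(x, length(bands)), bands))
  if (!all(bands %in% names(x)))
    stop("per-band value must name all of: ", paste(bands, collapse = ", "))
  x[bands]
}

#' SyntheticCohort: generated two-group study
#'
#' @slot subjects data.frame: subject_id, group, age, seed.
#' @slot eeg list of channels x samples matrices, one per subject.
#' @slot envelope the shared raw story envelope.
#' @slot rate sampling rate of eeg and envelope (Hz).
#' @slot channelNames channel labels.
#' @slot spec the generating \linkS4class{CohortSpec}.
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(subjects = "data.frame", eeg = "list",
                 envelope = "numeric", rate = "numeric",
                 channelNames = "character", spec = "CohortSpec"))

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d control + %d aphasia, %d channels, %.1f min @ %g Hz\n",
    sum(object@subjects$group == "control"),
    sum(object@subjects$group == "aphasia"),
    length(object@channelNames),
    length(object@envelope) / object@rate / 60, object@rate))
})

# channel layout for reduced montages: spread picks across the
# topography-gain range so the common-average reference behaves as it
# does on the full cap (a same-gain subset would cancel the shared
# response)
.cohort_channels <- function(nChannels) {
  montage <- readMontage()
  if (nChannels > nrow(montage))
    stop("at most ", nrow(montage), " channels available")
  if (nChannels == nrow(montage)) return(montage$channel)
  g <- .topography_gain(montage$channel, montage)
  ordered <- montage$channel[order(-g)]
  ordered[round(seq(1, length(ordered), length.out = nChannels))]
}

#' Generate a synthetic two-group cohort
#'
#' All subjects share one story envelope (as in a single-story experiment);
#' per-subject EEG and ages use seeds derived from the cohort seed by
#' counter. Ages are drawn from N(72, 10) truncated to [40, 95] for both
#' groups.
#'
#' @param spec a \linkS4class{CohortSpec}.
#' @param rate generation rate in Hz (default 512, the intermediate rate).
#' @return a \linkS4class{SyntheticCohort}.
#' @export
genCohort <- function(spec, rate = 512) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  channels <- .cohort_channels(spec@nChannels)
  env <- genEnvelope(spec@durationMin * 60, rate,
                     deriveSeed(spec@seed, "envelope"))
  kern <- responseKernel(rate)
  groups <- rep(c("control", "aphasia"), c(spec@nControl, spec@nAphasia))
  nTot <- length(groups)
  set.seed(deriveSeed(spec@seed, "ages"))
  ages <- numeric(nTot)
  for (i in seq_len(nTot)) {
    repeat {
      a <- stats::rnorm(1, 72, 10)
      if (a >= 40 && a <= 95) break
    }
    ages[i] <- a
  }
  subjects <- data.frame(
    subject_id = sprintf("sub-%03d", seq_len(nTot)),
    group = groups, age = round(ages, 1),
    seed = vapply(seq_len(nTot), function(i)
      deriveSeed(spec@seed, "subject", i), integer(1)))
  prep <- .subject_prep(env, kern, spec, channels, rate)
  eeg <- lapply(seq_len(nTot), function(i)
    genSubjectEEG(env, kern, spec, groups[i], subjects$seed[i],
                  channels, rate, prep = prep))
  names(eeg) <- subjects$subject_id
  new("SyntheticCohort", subjects = subjects, eeg = eeg, envelope = env,
      rate = rate, channelNames = channels, spec = spec)
}
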