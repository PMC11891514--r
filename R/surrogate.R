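# Surrogate-based per-subject significance: stationary spectrum-matched
# noise envelopes (phase randomization) and the 95th-percentile null
# level.

# phase-randomized surrogates of x, one per column; exact amplitude
# spectrum by construction
.phase_surrogates <- function(x, nPerm, seed) {
  set.seed(seed)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor((n - 1) / 2)
  out <- matrix(0, n, nPerm)
  for (p in seq_len(nPerm)) {
    Y <- X
    if (half >= 1) {
      ph <- stats::runif(half, 0, 2 * pi)
      idx <- 2:(half + 1)
      Y[idx] <- Mod(X[idx]) * exp(1i * ph)
      Y[n - idx + 2] <- Conj(Y[idx])
    }
    if (n %% 2 == 0)                       # Nyquist bin: random sign
      Y[n / 2 + 1] <- Mod(X[n / 2 + 1]) * sample(c(-1, 1), 1)
    out[, p] <- Re(stats::fft(Y, inverse = TRUE)) / n
  }
  out
}

#' Spectrum-matched stationary noise envelope
#'
#' Phase randomization: the surrogate keeps the envelope's Fourier
#' amplitude spectrum exactly while drawing phases i.i.d. uniform, then is
#' re-z-scored. Used to build the per-subject MI null.
#'
#' @param env a \linkS4class{BandEnvelope} (or numeric vector).
#' @param seed RNG seed.
#' @param nPerm number of surrogates.
#' @return for a BandEnvelope input, a list of BandEnvelope surrogates
#'   (or a single object when nPerm = 1); for a numeric input, a matrix
#'   with one surrogate per column.
#' @export
spectrumMatchedNoise <- function(env, seed = 1L, nPerm = 1L) {
  if (is.numeric(env)) {
    if (length(env) < 2L) stop("envelope too short")
    return(.phase_surrogates(env, nPerm, seed))
  }
  stopifnot(is(env, "BandEnvelope"))
  s <- .phase_surrogates(env@samples, nPerm, seed)
  out <- lapply(seq_len(nPerm), function(p)
    initialize(env, samples = .zscore(s[, p])))
  if (nPerm == 1L) out[[1]] else out
}

#' Surrogate null distribution of the tracking statistic
#'
#' Computes the multivariate-TMIF summary statistic (mean MI over the
#' integration window by default, per-lag max optionally) between the
#' subject's EEG and each of \code{nPerm} spectrum-matched surrogate
#' envelopes, and derives the per-subject significance level as the
#' nearest-rank 95th percentile.
#'
#' @param eegBand an \linkS4class{EEGBand} (already channel-selected).
#' @param env the subject's \linkS4class{BandEnvelope}.
#' @param nPerm number of surrogates (1000 by default).
#' @param statistic "mean_mi" or "max_mi".
#' @param windowMs integration window for the statistic, ms.
#' @param seed RNG seed.
#' @param subjectId label stored in the result.
#' @return a \linkS4class{NullDistribution}.
#' @export
nullDistribution <- function(eegBand, env, nPerm = 1000L,
                             statistic = c("mean_mi", "max_mi"),
                             windowMs = c(0, 400), seed = 1L,
                             subjectId = "") {
  statistic <- match.arg(statistic)
  stopifnot(is(eegBand, "EEGBand"), is(env, "BandEnvelope"),
            eegBand@rate == env@rate)
  n <- length(env@samples)
  if (ncol(eegBand@matrix) != n)
    stop("EEG and envelope must have equal durations")
  lags <- lagGrid(windowMs, env@rate)
  lagMs <- lags * 1000 / env@rate
  lags <- lags[lagMs >= windowMs[1] & lagMs <= windowMs[2]]
  surr <- .phase_surrogates(env@samples, nPerm, seed)
  surr <- scale(surr)                      # re-z-score each surrogate
  mi <- cpp_null_mi(t(eegBand@matrix), surr, as.integer(lags))
  samples <- if (statistic == "mean_mi") rowMeans(mi) else
    apply(mi, 1L, max)
  lev <- sort(samples)[ceiling(0.95 * nPerm)]
  new("NullDistribution", samples = samples, level = lev,
      nPermutations = as.integer(nPerm), band = env@band,
      subjectId = subjectId, statistic = statistic)
}

#' Pooled group-level significance level
#'
#' The 95th percentile (nearest rank) of the surrogate statistics pooled
#' across subjects, giving a single significance level for the group.
#'
#' @param nulls list of \linkS4class{NullDistribution} objects.
#' @return numeric scalar, bits.
#' @export
pooledNullLevel <- function(nulls) {
  samples <- unlist(lapply(nulls, miValues))
  sort(samples)[ceiling(0.95 * length(samples))]
}
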