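# Gaussian-copula mutual information and the temporal mutual information
# function (TMIF).

#' Copula-gaussianize a data matrix
#'
#' Columnwise rank transform: ranks 1..n are mapped to r/(n+1) (the
#' empirical CDF on a 0-1 scale) and through the inverse standard-normal
#' CDF, so each column acquires a standard-normal marginal while its rank
#' ordering is preserved exactly.
#'
#' @param x numeric vector or matrix (variables in columns).
#' @return matrix of the same shape with gaussianized columns.
#' @export
copulaGaussianize <- function(x) {
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop("input must be numeric")
  out <- cpp_gaussianize(xm)
  dimnames(out) <- dimnames(xm)
  if (is.matrix(x)) out else drop(out)
}

#' Gaussian mutual information between two multivariate samples
#'
#' The parametric Gaussian MI computed from covariance determinants:
#' I(X;Y) = (1 / (2 ln 2)) * ln(|Sx| |Sy| / |Sxy|), in bits. With
#' \code{gaussianized = FALSE} the copula transform is applied first,
#' giving the Gaussian-copula MI estimate.
#'
#' @param x n x dx matrix (or vector).
#' @param y n x dy matrix (or vector).
#' @param gaussianized set TRUE when x and y already have standard-normal
#'   marginals.
#' @return MI in bits (nonnegative).
#' @export
gaussianMI <- function(x, y, gaussianized = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y must have the same sample count")
  if (nrow(x) <= ncol(x) + ncol(y) + 2L)
    stop("need n_samples > d + 2")
  if (!gaussianized) {
    x <- cpp_gaussianize(x)
    y <- cpp_gaussianize(y)
  }
  S <- stats::cov(cbind(x, y))
  dx <- ncol(x)
  ridge <- 1e-12 * sum(diag(S)) / ncol(S)
  diag(S) <- diag(S) + ridge
  ld <- function(M) {
    ch <- tryCatch(chol(M), error = function(e) {
      diag(M) <- diag(M) + 1e-8 * sum(diag(M)) / ncol(M)
      tryCatch(chol(M), error = function(e2)
        stop("singular joint covariance after regularization"))
    })
    2 * sum(log(diag(ch)))
  }
  mi <- (ld(S[seq_len(dx), seq_len(dx), drop = FALSE]) +
           ld(S[-seq_len(dx), -seq_len(dx), drop = FALSE]) - ld(S)) /
    (2 * log(2))
  max(mi, 0)
}

#' Lag grid in samples for a lag window
#'
#' Covers the window: floor at the lower edge, ceiling at the upper, so
#' [-200, 500] ms at 128 Hz gives sample shifts -26..64 (91 lags).
#'
#' @param lagWindowMs numeric length-2 window in ms.
#' @param rate analysis rate in Hz.
#' @return integer vector of sample shifts.
#' @export
lagGrid <- function(lagWindowMs, rate) {
  seq.int(floor(lagWindowMs[1] * rate / 1000),
          ceiling(lagWindowMs[2] * rate / 1000))
}

#' Compute the temporal mutual information function
#'
#' For each lag tau, the envelope at time t is paired with the EEG at time
#' t + tau over the overlapping samples (positive lag: neural response
#' follows the stimulus), both are copula-gaussianized on that overlap, and
#' the Gaussian MI is evaluated. The single-channel variant yields one MI
#' trace per channel; the multivariate variant treats all channels as one
#' joint variable.
#'
#' @param eeg an \linkS4class{EEGBand}.
#' @param env a \linkS4class{BandEnvelope} at the same rate and duration.
#' @param lagWindowMs lag window in ms (default -200..500).
#' @param variant "multivariate" (default) or "single_channel".
#' @return an (unsmoothed) \linkS4class{TMIF}.
#' @export
computeTMIF <- function(eeg, env, lagWindowMs = c(-200, 500),
                        variant = c("multivariate", "single_channel")) {
  variant <- match.arg(variant)
  stopifnot(is(eeg, "EEGBand"), is(env, "BandEnvelope"))
  if (eeg@rate != env@rate)
    stop("EEG and envelope must share the analysis rate")
  n <- length(env@samples)
  if (ncol(eeg@matrix) != n)
    stop("EEG and envelope must have equal durations")
  lags <- lagGrid(lagWindowMs, env@rate)
  if (max(abs(lags)) >= n) stop("lag exceeds signal length")
  d <- if (variant == "multivariate") nrow(eeg@matrix) else 1L
  if (n - max(abs(lags)) < 10L * (d + 1L))
    stop("fewer samples than 10 * (n_channels + 1) in the lag overlap")
  mi <- cpp_tmif(t(eeg@matrix), env@samples, as.integer(lags),
                 variant == "multivariate")
  chn <- if (variant == "single_channel") eeg@channelNames else character()
  if (variant == "single_channel") colnames(mi) <- chn
  new("TMIF", mi = mi, lagsMs = lags * 1000 / env@rate, rate = env@rate,
      variant = variant, band = env@band, smoothed = FALSE,
      channelNames = chn)
}

# 9-tap Gaussian smoothing kernel, SD = 2 samples, unit sum
.tmif_kernel <- function() {
  k <- exp(-((-4):4)^2 / (2 * 2^2))
  k / sum(k)
}

#' Smooth a TMIF along the lag axis
#'
#' Convolution with a 9-sample Gaussian kernel (SD = 2 samples, normalized
#' to unit sum), reflect-padded at the ends; applied independently per
#' channel.
#'
#' @param tmif an unsmoothed \linkS4class{TMIF}.
#' @return the smoothed \linkS4class{TMIF}.
#' @export
smoothTMIF <- function(tmif) {
  stopifnot(is(tmif, "TMIF"))
  if (tmif@smoothed) return(tmif)
  k <- .tmif_kernel()
  pad <- (length(k) - 1L) %/% 2L
  sm <- apply(tmif@mi, 2L, function(v) {
    vp <- c(v[seq(pad + 1L, 2L)], v, v[seq(length(v) - 1L, length(v) - pad)])
    stats::convolve(vp, rev(k), type = "filter")
  })
  sm <- matrix(sm, nrow = nrow(tmif@mi), dimnames = dimnames(tmif@mi))
  initialize(tmif, mi = pmax(sm, 0), smoothed = TRUE)
}

#' Mean MI of a TMIF over an integration window
#'
#' Arithmetic mean of the MI over lag bins inside the window (0-400 ms by
#' default). For the single-channel variant the channel average is taken
#' first.
#'
#' @param tmif a \linkS4class{TMIF}.
#' @param windowMs numeric length-2 window in ms.
#' @return mean MI in bits.
#' @export
meanMI <- function(tmif, windowMs = c(0, 400)) {
  stopifnot(is(tmif, "TMIF"))
  inside <- tmif@lagsMs >= windowMs[1] & tmif@lagsMs <= windowMs[2]
  if (!any(inside)) stop("empty integration window")
  mean(rowMeans(tmif@mi)[inside])
}
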