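# Signal-processing primitives: FFT convolution, zero-phase FIR
# application, FFT-domain resampling, and linear-phase least-squares FIR
# design with measured compliance checking.

# package-level cache for filter designs (keyed by edges/rate/order)
.envtrack_cache <- new.env(parent = emptyenv())

.next_fast <- function(n) stats::nextn(n, c(2L, 3L, 5L))

#' Linear convolution via FFT
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param h numeric filter coefficients.
#' @return full linear convolution, length nrow(x) + length(h) - 1.
#' @keywords internal
fftConvolve <- function(x, h) {
  xm <- as.matrix(x)
  n <- nrow(xm) + length(h) - 1L
  nfft <- .next_fast(n)
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  # process wide inputs in column chunks to bound the size of the complex
  # temporaries (keeps the garbage collector out of the hot path)
  chunk <- max(1L, as.integer(4e6 %/% nfft))
  y <- matrix(0, n, ncol(xm))
  pad <- matrix(0, nfft - nrow(xm), min(chunk, ncol(xm)))
  for (j0 in seq(1L, ncol(xm), by = chunk)) {
    j1 <- min(j0 + chunk - 1L, ncol(xm))
    X <- stats::mvfft(rbind(xm[, j0:j1, drop = FALSE],
                            pad[, seq_len(j1 - j0 + 1L), drop = FALSE]))
    y[, j0:j1] <- Re(stats::mvfft(X * H, inverse = TRUE))[seq_len(n), ] / nfft
  }
  if (is.matrix(x)) y else drop(y)
}

# odd (antisymmetric) reflection padding of `pad` samples on both ends:
# 2*x[1] - x[k] / 2*x[n] - x[n-k]. Keeps both the value and the slope
# continuous at the joins (as filtfilt implementations do), so highpass
# filters see no edge kink.
.reflect_pad <- function(x, pad) {
  xm <- as.matrix(x)
  n <- nrow(xm)
  if (pad >= n) stop("signal too short for requested reflection padding")
  head <- 2 * xm[rep(1L, pad), , drop = FALSE] -
    xm[seq(pad + 1L, 2L), , drop = FALSE]
  tail <- 2 * xm[rep(n, pad), , drop = FALSE] -
    xm[seq(n - 1L, n - pad), , drop = FALSE]
  rbind(head, xm, tail)
}

#' Zero-phase application of a symmetric (linear-phase) FIR filter
#'
#' The filter is applied once by FFT convolution and the symmetric group
#' delay is removed, so the output is time-aligned with the input. Edges
#' are reflection-padded by one filter order to suppress startup
#' transients.
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param h symmetric FIR coefficients (odd length).
#' @return filtered signal, same shape as x.
#' @keywords internal
applyZeroPhase <- function(x, h) {
  ord <- length(h) - 1L
  if (ord %% 2L != 0L) stop("filter must have even order (odd length)")
  xm <- as.matrix(x)
  if (nrow(xm) < 3L * ord / 2L)
    stop("signal too short for filter order")
  pad <- min(ord, nrow(xm) - 1L)
  xp <- .reflect_pad(xm, pad)
  y <- fftConvolve(xp, h)
  keep <- seq(ord / 2L + pad + 1L, length.out = nrow(xm))
  y <- y[keep, , drop = FALSE]
  if (is.matrix(x)) y else drop(y)
}

#' FFT-domain resampling
#'
#' Resamples by spectral truncation (downsampling) or zero-padding
#' (upsampling) of the Fourier transform, with reflection padding so edge
#' discontinuities do not leak in. Acts as an ideal anti-aliasing filter:
#' all content above the new Nyquist is removed exactly.
#'
#' @param x numeric vector or matrix (signals in columns).
#' @param from original rate in Hz.
#' @param to target rate in Hz.
#' @return resampled signal of length round(n * to / from).
#' @export
fftResample <- function(x, from, to) {
  stopifnot(from > 0, to > 0)
  if (from == to) return(x)
  xm <- as.matrix(x)
  n <- nrow(xm)
  nOut <- round(n * to / from)
  # reflect-pad by a multiple of from/gcd so both sample grids align, and
  # aim for a 2/3/5-smooth total length so the FFTs stay fast
  g <- .gcd(round(from), round(to))
  blk <- round(from) / g
  padL <- blk * min(floor((n - 1L) / blk), max(1L, ceiling(256L / blk)))
  xp <- if (padL > 0L) .reflect_pad(xm, padL) else xm
  P0 <- nrow(xp)
  smooth_blk <- { b <- blk; for (f in c(2L, 3L, 5L)) while (b %% f == 0L) b <- b %/% f; b == 1L }
  P <- if (smooth_blk) blk * .next_fast(as.integer(ceiling(P0 / blk)))
       else P0 + (blk - P0 %% blk) %% blk
  add <- P - P0
  if (add > 0L) {
    ext <- if (add < P0)
      2 * xp[rep(P0, add), , drop = FALSE] -
        xp[P0 - seq_len(add), , drop = FALSE]
    else xp[rep(P0, add), , drop = FALSE]
    xp <- rbind(xp, ext)
  }
  Pout <- P %/% blk * (round(to) / g)
  X <- stats::mvfft(xp)
  Y <- matrix(0 + 0i, Pout, ncol(xp))
  # brick-wall: keep only bins strictly below the smaller Nyquist
  half <- ceiling(min(P, Pout) / 2) - 1L
  Y[seq_len(half + 1L), ] <- X[seq_len(half + 1L), , drop = FALSE]
  if (half >= 1L)
    Y[Pout - seq_len(half) + 1L, ] <- X[P - seq_len(half) + 1L, , drop = FALSE]
  y <- Re(stats::mvfft(Y, inverse = TRUE)) / P
  start <- round(padL * to / from)
  out <- y[start + seq_len(nOut), , drop = FALSE]
  if (is.matrix(x)) out else drop(out)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# ---- least-squares linear-phase FIR design ------------------------------

# Closed-form normal equations for the weighted least-squares design of a
# type-I (even-order, symmetric) FIR filter. The amplitude response is
# A(w) = sum_k a_k cos(k w); minimizing the weighted integrated squared
# error over the union of pass/stop bands gives Q a = b with
# Q = (T + H)/2 built from band integrals of cos(j w).
.band_integral <- function(j, bands) {
  # integral of cos(j*w) over the union of bands (w in radians), per j
  out <- numeric(length(j))
  for (b in seq_len(nrow(bands))) {
    w1 <- bands[b, 1L]; w2 <- bands[b, 2L]; wt <- bands[b, 3L]
    v <- ifelse(j == 0, w2 - w1, (sin(j * w2) - sin(j * w1)) / ifelse(j == 0, 1, j))
    out <- out + wt * v
  }
  out
}

#' Least-squares linear-phase FIR design
#'
#' @param order filter order (even); length is order + 1.
#' @param bands matrix with columns (low Hz, high Hz, desired, weight).
#' @param rate sampling rate in Hz.
#' @return numeric coefficient vector of length order + 1 (symmetric).
#' @keywords internal
firLeastSquares <- function(order, bands, rate) {
  stopifnot(order %% 2L == 0L)
  M <- order / 2L
  wb <- cbind(2 * pi * bands[, 1L] / rate, 2 * pi * bands[, 2L] / rate,
              bands[, 4L])
  j <- 0:(2L * M)
  I <- .band_integral(j, wb)                       # I[j+1] = integral cos(jw)
  # Toeplitz part T[k,m] = I(|k-m|); Hankel part H[k,m] = I(k+m)
  idx <- 0:M
  Tm <- matrix(I[abs(outer(idx, idx, "-")) + 1L], M + 1L, M + 1L)
  Hm <- matrix(I[outer(idx, idx, "+") + 1L], M + 1L, M + 1L)
  Q <- (Tm + Hm) / 2
  # rhs: only bands with desired == 1 contribute
  des <- wb[bands[, 3L] == 1, , drop = FALSE]
  b <- if (nrow(des)) .band_integral(idx, des) else numeric(M + 1L)
  a <- solve(Q, b)
  h <- numeric(order + 1L)
  h[M + 1L] <- a[1L]
  if (M >= 1L) {
    h[M + 1L + idx[-1L]] <- a[-1L] / 2
    h[M + 1L - idx[-1L]] <- a[-1L] / 2
  }
  h
}

#' Amplitude response of a FIR filter on a dense grid
#'
#' @param h coefficients.
#' @param rate sampling rate Hz.
#' @param nfft FFT length (resolution rate/nfft).
#' @return data.frame with freq (Hz) and amp (linear amplitude).
#' @keywords internal
firResponse <- function(h, rate, nfft = 2^17) {
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  k <- seq_len(nfft / 2 + 1L)
  data.frame(freq = (k - 1L) * rate / nfft, amp = Mod(H[k]))
}
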