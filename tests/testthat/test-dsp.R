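# FFT primitives: convolution, zero-phase application, resampling.

test_that("fftConvolve matches direct convolution", {
  set.seed(1)
  x <- rnorm(200)
  h <- rnorm(31)
  direct <- convolve(x, rev(h), type = "open")
  expect_equal(envtrack:::fftConvolve(x, h), direct, tolerance = 1e-10)
  # matrix input convolves each column
  xm <- cbind(x, 2 * x)
  ym <- envtrack:::fftConvolve(xm, h)
  expect_equal(ym[, 2], 2 * ym[, 1], tolerance = 1e-10)
})

test_that("zero-phase application is symmetric and delay-free", {
  filt <- designBandFilter("theta", 512)
  n <- 15000
  x <- numeric(n); x[n / 2] <- 1
  y <- applyZeroPhase(x, filt$highpass$h)
  # impulse response around the impulse position is time-symmetric
  w <- 900
  seg <- y[(n / 2 - w):(n / 2 + w)]
  expect_lt(max(abs(seg - rev(seg))), 1e-9)
  # the peak stays at the impulse position (group delay compensated)
  expect_equal(which.max(abs(y)), n / 2)
})

test_that("fftResample preserves in-band content and rejects aliases", {
  t512 <- (0:20479) / 512
  x <- sin(2 * pi * 5 * t512) + 0.5 * sin(2 * pi * 40 * t512) +
    0.2 * sin(2 * pi * 100 * t512)          # 100 Hz must vanish at 128 Hz
  y <- fftResample(x, 512, 128)
  expect_length(y, 20480 / 4)
  t128 <- (0:(length(y) - 1)) / 128
  ideal <- sin(2 * pi * 5 * t128) + 0.5 * sin(2 * pi * 40 * t128)
  expect_gt(cor(y, ideal), 0.9999)
  # alias suppression: residual energy at the aliased frequency is tiny
  sp <- Mod(fft(y - ideal))^2
  expect_lt(sum(sp) / sum(Mod(fft(ideal))^2), 1e-4)
})

test_that("least-squares FIR design solves the stated approximation problem", {
  # an independently computed dense-grid least-squares fit must agree
  rate <- 512
  bands <- rbind(c(0, 40, 1, 1), c(60, 256, 0, 1))
  h <- envtrack:::firLeastSquares(80L, bands, rate)
  M <- 40L
  w <- seq(0, pi, length.out = 4096)
  keep <- (w <= 2 * pi * 40 / rate) | (w >= 2 * pi * 60 / rate)
  D <- as.numeric(w[keep] <= 2 * pi * 40 / rate)
  A <- cos(outer(w[keep], 0:M))
  aRef <- qr.solve(A, D)           # grid least squares oracle
  aPkg <- c(h[M + 1L], 2 * h[(M + 2L):(2L * M + 1L)])
  expect_equal(aPkg, aRef, tolerance = 1e-3)
})
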