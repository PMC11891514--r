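# Envelope extraction: gammatone filterbank, band filters, band envelopes.

test_that("gammatone envelope: silence, power-law scaling, tone flatness", {
  rate <- 16384
  expect_true(all(gammatoneEnvelope(numeric(2 * rate), rate) == 0))

  set.seed(2)
  x <- rnorm(2 * rate) * 0.1
  e1 <- gammatoneEnvelope(x, rate)
  e3 <- gammatoneEnvelope(3 * x, rate)
  # |k x|^0.6 = k^0.6 |x|^0.6 propagates through the linear stages
  expect_equal(e3, 3^0.6 * e1, tolerance = 1e-6)

  tone <- sin(2 * pi * 1000 * (0:(2 * rate)) / rate)
  ge <- gammatoneEnvelope(tone, rate)
  trimmed <- ge[200:(length(ge) - 200)]      # discard startup transient
  expect_lt(sd(trimmed) / mean(trimmed), 0.1)
})

test_that("gammatone centre frequencies follow ERB-rate spacing", {
  cf <- envtrack:::gammatoneCentreFreqs()
  expect_length(cf, 28L)
  expect_equal(cf[1], 50, tolerance = 1e-6)
  expect_equal(cf[28], 5000, tolerance = 1e-6)
  erb <- 21.4 * log10(1 + 0.00437 * cf)
  expect_equal(diff(erb), rep(diff(erb)[1], 27), tolerance = 1e-9)
})

test_that("band filters meet their design point checks", {
  th <- designBandFilter("theta", 512)
  r <- envtrack:::firResponse(th$highpass$h, 512)
  at <- function(resp, f) 20 * log10(resp$amp[which.min(abs(resp$freq - f))])
  expect_lt(abs(at(r, 6)), 0.25)             # mid-passband within 0.25 dB
  expect_lt(at(r, 3.6), -10)                 # stopband edge at 10% below

  de <- designBandFilter("delta", 512)
  rl <- envtrack:::firResponse(de$lowpass$h, 512)
  expect_lt(at(rl, 4.4), -10)                # 10% above the lowpass edge
  # order rule: 2000 below 30 Hz, 500 at or above
  expect_equal(th$highpass$order, 2000L)
  expect_equal(de$lowpass$order, 2000L)
  expect_equal(designBandFilter("gamma", 512)$highpass$order, 500L)
})

test_that("band envelopes concentrate power in band and are z-scored", {
  set.seed(6)
  env <- abs(rnorm(60 * 512))                # white-ish raw envelope
  for (b in c("delta", "theta", "beta")) {
    be <- bandEnvelope(env, b, 512)
    x <- signalSamples(be)
    expect_lt(abs(mean(x)), 0.02)
    expect_lt(abs(sd(x) - 1), 0.02)
    lim <- defaultBands()[[b]]
    n <- length(x)
    f <- (0:(n - 1)) * 128 / n
    sp <- Mod(fft(x))^2
    half <- f <= 64
    inBand <- half & f >= 0.9 * lim[1] & f <= 1.1 * lim[2]
    frac <- sum(sp[inBand]) / sum(sp[half & f > 0])
    expect_gt(frac, 0.9)
    if (b == "delta") expect_gt(frac, 0.95)  # >= 95% below 4.4 Hz
  }
  # determinism
  expect_identical(signalSamples(bandEnvelope(env, "theta", 512)),
                   signalSamples(bandEnvelope(env, "theta", 512)))
  # too-short input is rejected
  expect_error(bandEnvelope(env[1:3000], "delta", 512), "too short")
})
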