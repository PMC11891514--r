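# Synthetic envelope, subject EEG and cohort generation.

test_that("generated envelopes are nonnegative, speech-paced, deterministic", {
  e <- genEnvelope(60, 512, seed = 1)
  expect_length(e, 60 * 512)
  expect_true(all(e >= 0))
  expect_identical(e, genEnvelope(60, 512, seed = 1))
  expect_false(identical(e, genEnvelope(60, 512, seed = 2)))
  # spectral peak of the z-scored envelope sits in the syllable range
  for (s in 1:2) {
    z <- as.numeric(scale(genEnvelope(60, 512, seed = s)))
    n <- length(z)
    f <- (0:(n - 1)) * 512 / n
    sp <- Mod(fft(z))^2
    keep <- f > 0.2 & f < 64
    expect_true(f[keep][which.max(sp[keep])] >= 1 &&
                  f[keep][which.max(sp[keep])] <= 8)
  }
})

test_that("response kernel invariants hold", {
  k <- responseKernel(512)
  expect_true(min(k@lagsMs) >= 0 && max(k@lagsMs) <= 500)
  expect_lt(k@peak1Ms, k@peak2Ms)
  expect_error(responseKernel(512, peak2Scale = 1.5), "peak2Scale")
  ka <- responseKernel(512, peak2Scale = 0.3)
  # attenuation applies to the listed bands only
  expect_lt(max(ka@amplitudes[, "theta"]), max(ka@amplitudes[, "alpha"]))
  expect_equal(ka@amplitudes[, "alpha"], ka@amplitudes[, "beta"])
})

test_that("noise-free EEG cross-correlates with the envelope at the second peak", {
  sp <- cohortSpec(1, 1, snrDb = Inf, effect = 1, durationMin = 1,
                   nChannels = 4, seed = 2)
  co <- genCohort(sp)
  filt <- designBandFilter("broad", co@rate)
  envF <- applyBandFilter(co@envelope, filt)
  for (ch in 1:2) {
    cc <- ccf(co@eeg[[1]][ch, ], envF, lag.max = 150, plot = FALSE)
    peakMs <- cc$lag[which.max(cc$acf)] / co@rate * 1000
    expect_lt(abs(peakMs - 170), 1000 / co@rate + 1e-9)  # within 1 sample
  }
  # channels share the response up to the topography gain
  r <- cor(co@eeg[[1]][1, ], co@eeg[[1]][4, ])
  expect_gt(r, 0.999)
})

test_that("cohorts are balanced, deterministic, with plausible ages", {
  sp <- cohortSpec(2, 2, durationMin = 0.5, nChannels = 4, seed = 5)
  co <- genCohort(sp)
  expect_equal(nrow(co@subjects), 4L)
  expect_equal(sum(co@subjects$group == "control"), 2L)
  expect_equal(sum(co@subjects$group == "aphasia"), 2L)
  expect_true(all(co@subjects$age >= 40 & co@subjects$age <= 95))
  expect_identical(genCohort(sp)@subjects, co@subjects)
  # effect = 1 makes the two group generators identical
  sp1 <- cohortSpec(1, 1, effect = 1, durationMin = 0.5, nChannels = 4,
                    seed = 6)
  co1 <- genCohort(sp1)
  kern <- responseKernel(co1@rate)
  eegC <- genSubjectEEG(co1@envelope, kern, sp1, "control", 99,
                        co1@channelNames, co1@rate)
  eegA <- genSubjectEEG(co1@envelope, kern, sp1, "aphasia", 99,
                        co1@channelNames, co1@rate)
  expect_identical(eegC, eegA)
})

test_that("tracking strength is nondecreasing in SNR", {
  mis <- vapply(c(-10, 0, 10), function(snr) {
    sp <- cohortSpec(1, 1, snrDb = snr, durationMin = 1, nChannels = 4,
                     seed = 77)
    co <- genCohort(sp)
    envB <- bandEnvelope(co@envelope, "theta", co@rate)
    eb <- conditionEEG(commonAverageReference(co@eeg[[1]]), "theta",
                       co@channelNames, co@rate)
    meanMI(smoothTMIF(computeTMIF(eb, envB)))
  }, numeric(1))
  expect_true(all(diff(mis) > 0))
})
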