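# Spectrum-matched surrogates and the per-subject null.

test_that("surrogates keep the amplitude spectrum and lose the phase", {
  set.seed(20)
  # AR(0.9) signal: red like an envelope but with enough effective
  # degrees of freedom for a stable correlation estimate
  x <- as.numeric(scale(stats::filter(rnorm(18000), 0.9, "recursive")))
  s2 <- envtrack:::.phase_surrogates(x, 2L, seed = 1)
  for (p in 1:2)
    expect_equal(Mod(fft(s2[, p])), Mod(fft(x)), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(s2[, 1], s2[, 2])))
  # long-signal surrogate decorrelates from the original
  expect_lt(abs(cor(s2[, 1], x)), 0.1)
  expect_lt(abs(cor(s2[, 2], x)), 0.1)
  # BandEnvelope interface returns re-z-scored envelopes
  env <- mk_env(x)
  su <- spectrumMatchedNoise(env, seed = 2)
  expect_s4_class(su, "BandEnvelope")
  expect_lt(abs(mean(signalSamples(su))), 1e-9)
})

test_that("tiny null distributions follow the nearest-rank rule", {
  set.seed(21)
  eeg <- mk_eeg(matrix(rnorm(2 * 2000), 2, 2000))
  env <- mk_env(rnorm(2000))
  nd <- nullDistribution(eeg, env, nPerm = 4L, seed = 5, subjectId = "s1")
  expect_length(miValues(nd), 4L)
  # ceil(0.95 * 4) = 4: the level is the maximum sample
  expect_equal(significanceLevel(nd), max(miValues(nd)))
  nd2 <- nullDistribution(eeg, env, nPerm = 4L, seed = 5, subjectId = "s1")
  expect_identical(miValues(nd2), miValues(nd))   # seeded determinism
  nd3 <- nullDistribution(eeg, env, nPerm = 4L, seed = 6)
  expect_false(identical(miValues(nd3), miValues(nd)))
})

test_that("a strong tracking response exceeds its surrogate level", {
  co <- cached_cohort()                       # snr +5 dB, 1 min
  envB <- bandEnvelope(co@envelope, "theta", co@rate)
  eb <- conditionEEG(commonAverageReference(co@eeg[[1]]), "theta",
                     co@channelNames, co@rate)
  nd <- nullDistribution(eb, envB, nPerm = 100L, seed = 3,
                         subjectId = co@subjects$subject_id[1])
  tm <- smoothTMIF(computeTMIF(eb, envB))
  expect_gt(meanMI(tm), significanceLevel(nd))
  # pooled level sits within the range of per-subject samples
  eb2 <- conditionEEG(commonAverageReference(co@eeg[[2]]), "theta",
                      co@channelNames, co@rate)
  nd2 <- nullDistribution(eb2, envB, nPerm = 100L, seed = 4)
  pooled <- pooledNullLevel(list(nd, nd2))
  expect_gte(pooled, min(significanceLevel(nd), significanceLevel(nd2)))
  expect_lte(pooled, max(significanceLevel(nd), significanceLevel(nd2)))
})

test_that("second-peak removal collapses the 170 ms response", {
  sp0 <- cohortSpec(1, 1, snrDb = 5, effect = 0, durationMin = 1,
                    nChannels = 4, seed = 3)
  co0 <- genCohort(sp0)
  envB <- bandEnvelope(co0@envelope, "broad", co0@rate)
  mi170 <- vapply(1:2, function(i) {
    eb <- conditionEEG(commonAverageReference(co0@eeg[[i]]), "broad",
                       co0@channelNames, co0@rate)
    tm <- smoothTMIF(computeTMIF(eb, envB))
    miValues(tm)[which.min(abs(lagTimes(tm) - 170)), 1]
  }, numeric(1))
  ctrl <- mi170[co0@subjects$group == "control"]
  apha <- mi170[co0@subjects$group == "aphasia"]
  expect_lt(apha, 0.25 * ctrl)
})
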