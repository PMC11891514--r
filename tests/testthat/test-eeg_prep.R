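# EEG conditioning: referencing, band filtering, channel selection.

test_that("common-average reference: closed form, idempotence, common mode", {
  a <- rnorm(100); b <- rnorm(100)
  m <- rbind(a, b)
  ref <- commonAverageReference(m)
  expect_equal(ref[1, ], (a - b) / 2, ignore_attr = TRUE)
  expect_equal(ref[2, ], (b - a) / 2, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(ref))), 1e-9)
  expect_equal(commonAverageReference(ref), ref, tolerance = 1e-12)
  expect_equal(commonAverageReference(m + 5), ref, tolerance = 1e-12)
  expect_error(commonAverageReference(m[1, , drop = FALSE]), "2 channels")
})

test_that("conditioned EEG is band-limited with unit moments", {
  set.seed(7)
  eeg <- matrix(rnorm(3 * 30720), 3, 30720)
  eeg[3, ] <- eeg[2, ]                       # identical channels
  ref <- eeg                                 # reference separately below
  eb <- conditionEEG(eeg, "theta", c("Fz", "Cz", "Pz"), 512)
  x <- signalSamples(eb)
  expect_equal(dim(x), c(3L, 30720L / 4L))
  for (i in 1:3) {
    expect_lt(abs(mean(x[i, ])), 0.02)
    expect_lt(abs(sd(x[i, ]) - 1), 0.02)
    n <- ncol(x); f <- (0:(n - 1)) * 128 / n
    sp <- Mod(fft(x[i, ]))^2
    inBand <- f >= 3.6 & f <= 8.8
    expect_gt(sum(sp[inBand]) / sum(sp[f > 0 & f <= 64]), 0.9)
  }
  expect_equal(x[2, ], x[3, ], tolerance = 1e-12)
})

test_that("conditioning commutes with channel permutation and referencing", {
  set.seed(8)
  eeg <- matrix(rnorm(4 * 30720), 4, 30720)
  nm <- c("Fz", "Cz", "Pz", "Oz")
  perm <- c(3, 1, 4, 2)
  a <- conditionEEG(eeg, "alpha", nm, 512)
  b <- conditionEEG(eeg[perm, ], "alpha", nm[perm], 512)
  expect_equal(signalSamples(a)[perm, ], signalSamples(b),
               tolerance = 1e-12)
  # referencing before vs after band filtering (both linear)
  filt <- designBandFilter("alpha", 512)
  y1 <- commonAverageReference(t(applyBandFilter(t(eeg), filt)))
  y2 <- t(applyBandFilter(t(commonAverageReference(eeg)), filt))
  expect_lt(max(abs(y1 - y2)), 1e-9)
})

test_that("channel selection subsets, reorders, and names offenders", {
  eb <- mk_eeg(matrix(rnorm(4 * 500), 4, 500),
               channelNames = c("Fz", "Cz", "Pz", "Oz"))
  expect_equal(selectChannels(eb, channelNames(eb)), eb)
  sub <- selectChannels(eb, c("pz", "FZ"))   # case-insensitive, reordered
  expect_identical(channelNames(sub), c("Pz", "Fz"))
  expect_equal(signalSamples(sub),
               signalSamples(eb)[c(3, 1), ], ignore_attr = TRUE)
  expect_error(selectChannels(eb, c("Cz", "XX")), "XX")
})
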