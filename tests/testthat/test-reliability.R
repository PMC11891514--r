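# Stability curves, knee points, split-half reliability.

test_that("ICC(1,1) matches the hand-computed ANOVA oracle", {
  x <- c(9, 8, 7, 8, 9, 6)
  y <- c(8, 7, 8, 9, 8, 7)
  r <- icc11(x, y)
  expect_equal(r$icc, oracle_icc11(x, y), tolerance = 1e-12)
  # frozen from the one-way ANOVA table computed by hand:
  # MSB = 2 * var(rowmeans), MSW = within-pair scatter
  expect_equal(r$icc, (2 * var((x + y) / 2) - sum((x - y)^2 / 2) / 6) /
                       (2 * var((x + y) / 2) + sum((x - y)^2 / 2) / 6),
               tolerance = 1e-12)
  expect_true(r$ci[1] <= r$icc && r$icc <= r$ci[2])
  # identical halves give a perfect ICC
  r1 <- icc11(x, x)
  expect_equal(r1$icc, 1)
  expect_equal(r1$ci[2], 1)
  # independent data hover near zero
  set.seed(50)
  z <- replicate(100, icc11(rnorm(20), rnorm(20))$icc)
  expect_lt(abs(mean(z)), 0.1)
})

test_that("knee point agrees with the independent Kneedle oracle", {
  grid <- seq(1, 25, by = 2)
  for (curve in list(1 - exp(-grid / 4),
                     pmin(grid / 7, 1),
                     log(grid + 1))) {
    got <- kneePoint(grid, curve)
    ref <- oracle_kneedle(grid, curve)
    expect_equal(got$minutes, ref)
    expect_true(got$found)
  }
  lin <- kneePoint(grid, 0.5 + 0.02 * grid)  # strictly linear: no knee
  expect_false(lin$found)
  expect_equal(lin$minutes, 25)
  step <- kneePoint(grid, c(0, 0, rep(1, 11)))
  expect_true(step$found)
  expect_equal(step$minutes, grid[3])        # knee at the step
})

test_that("cropped TMIFs reproduce the full computation at full duration", {
  co <- cached_cohort()
  sel <- co@channelNames
  tms <- cropTMIFs(co@eeg[[1]], co@envelope, co@channelNames,
                   minutesGrid = c(0.5, 1), band = "theta",
                   rate = co@rate, selection = sel)
  expect_length(tms, 2L)
  envB <- bandEnvelope(co@envelope, "theta", co@rate)
  eb <- selectChannels(conditionEEG(commonAverageReference(co@eeg[[1]]),
                                    "theta", co@channelNames, co@rate), sel)
  full <- smoothTMIF(computeTMIF(eb, envB))
  expect_equal(miValues(tms[["1"]]), miValues(full), tolerance = 1e-9)
  expect_error(cropTMIFs(co@eeg[[1]], co@envelope, co@channelNames,
                         minutesGrid = 5, band = "theta", rate = co@rate),
               "crop longer")
})

test_that("within-subject stability is exactly 1 at full duration", {
  set.seed(51)
  lags <- (0:40) * 1000 / 128
  mkT <- function(v) new("TMIF", mi = matrix(pmax(v, 0), ncol = 1),
                         lagsMs = lags, rate = 128,
                         variant = "multivariate", band = "b",
                         smoothed = TRUE, channelNames = character())
  full1 <- exp(-(lags - 170)^2 / 3000)
  byS <- list(
    s1 = list(theta = list(`1` = mkT(full1 + 0.3 * rnorm(41)),
                           `3` = mkT(full1 + 0.1 * rnorm(41)),
                           `5` = mkT(full1))),
    s2 = list(theta = list(`1` = mkT(full1 + 0.4 * rnorm(41)),
                           `3` = mkT(full1 + 0.15 * rnorm(41)),
                           `5` = mkT(full1))))
  sc <- withinSubjectStability(byS, c(1, 3, 5))
  expect_equal(unname(sc@values[3, "theta"]), 1, tolerance = 1e-12)
  expect_true(all(diff(sc@values[, "theta"]) > 0))  # noisier when shorter
})

test_that("between-subject stability: identity at full, ruined by permutation", {
  set.seed(52)
  full <- seq(0.02, 0.4, length.out = 12)          # well-separated subjects
  m5 <- full + 0.005 * rnorm(12)
  m1 <- full + 0.05 * rnorm(12)
  sc <- betweenSubjectStability(list(theta = cbind(m1, m5, full)),
                                c(1, 5, 9))
  expect_equal(unname(sc@values[3, "theta"]), 1, tolerance = 1e-12)
  expect_gt(sc@values[2, "theta"], 0.9)
  # permuting subject identities destroys the correlation
  perm <- sample(12)
  iccPerm <- icc11(m5[perm], full)$icc
  expect_lt(iccPerm, icc11(m5, full)$icc)
  expect_lt(abs(iccPerm), 0.6)
  expect_error(betweenSubjectStability(list(theta = cbind(m1[1:2],
                                                          full[1:2])),
                                       c(1, 5)), "3 subjects")
})

test_that("SVM performance curves track recording length", {
  co <- genCohort(cohortSpec(3, 3, snrDb = 10, effect = 0.3,
                             durationMin = 1, nChannels = 3, seed = 9))
  sc <- performanceVsTime(co, c(0.5, 1), cGrid = 1, pruneGridMs = 300,
                          seed = 4)
  expect_s4_class(sc, "StabilityCurve")
  expect_equal(dim(sc@values), c(2L, 3L))
  expect_true(all(sc@values >= 0 & sc@values <= 1))
  expect_true(sc@kneeMinutes %in% c(0.5, 1))
})

test_that("split-half report matches hand ICC and corrects its p-values", {
  half <- data.frame(
    subject_id = rep(sprintf("s%d", 1:6), 2),
    group = rep(rep(c("control", "aphasia"), each = 3), 2),
    band = rep(c("delta", "theta"), each = 6),
    mi_first = c(0.30, 0.25, 0.20, 0.15, 0.12, 0.10,
                 0.40, 0.35, 0.28, 0.22, 0.18, 0.12),
    mi_second = c(0.31, 0.24, 0.21, 0.14, 0.13, 0.10,
                  0.39, 0.36, 0.27, 0.23, 0.17, 0.13))
  rep <- splitHalfICC(half)
  tb <- rep@table
  expect_equal(nrow(tb), 4L)
  for (i in seq_len(4)) {
    sub <- half[half$band == tb$band[i] & half$group == tb$group[i], ]
    expect_equal(tb$icc[i], oracle_icc11(sub$mi_first, sub$mi_second),
                 tolerance = 1e-12)
  }
  expect_true(all(tb$p_corrected >= tb$p))
  expect_equal(tb$p_corrected, p.adjust(tb$p, "holm"), tolerance = 1e-12)
  expect_true(all(!is.na(tb$fisher_z_p)))
  # identical halves: perfect ICC with CI upper = 1
  same <- half; same$mi_second <- same$mi_first
  tb2 <- splitHalfICC(same)@table
  expect_true(all(tb2$icc == 1))
  expect_true(all(tb2$ci_upper == 1))
  expect_error(splitHalfICC(half[half$subject_id != "s1", ]), "3 subjects")
})
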