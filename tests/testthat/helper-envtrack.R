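# Shared fixture builders and independent oracles.

# z-scored BandEnvelope straight from raw samples (bypasses filtering;
# for tests that need full control over the signal)
mk_env <- function(x, rate = 128, band = "test", limits = c(0.5, 49)) {
  new("BandEnvelope", samples = as.numeric(scale(x)), rate = rate,
      band = band, bandLimits = limits)
}

# z-scored EEGBand from a channels x samples matrix
mk_eeg <- function(m, rate = 128, band = "test",
                   channelNames = paste0("ch", seq_len(nrow(m)))) {
  zm <- t(scale(t(m)))
  attributes(zm)[c("scaled:center", "scaled:scale")] <- NULL
  new("EEGBand", matrix = zm, rate = rate, band = band,
      channelNames = channelNames)
}

# build a TMIFCohort directly from per-band assay matrices
mk_cohort_tmif <- function(assays, lagsMs, groups,
                           ages = seq(60, length.out = length(groups))) {
  subjects <- data.frame(
    subject_id = sprintf("s%02d", seq_along(groups)),
    group = groups, age = ages)
  tmifCohort(assays, lagsMs, subjects)
}

# independent brute-force Gaussian-copula gaussianizer
oracle_gauss <- function(v) qnorm(rank(v, ties.method = "average") /
                                    (length(v) + 1))

# independent Kneedle implementation (concave increasing, S = 1, no
# smoothing/interpolation), written directly from the published algorithm
oracle_kneedle <- function(x, y, S = 1) {
  xn <- (x - min(x)) / (max(x) - min(x))
  yn <- (y - min(y)) / (max(y) - min(y))
  d <- yn - xn
  n <- length(d)
  # local maxima of the difference curve
  lm_idx <- which(vapply(seq_len(n), function(i) {
    left <- if (i > 1) d[i] > d[i - 1] else d[i] > d[i + 1]
    right <- if (i < n) d[i] >= d[i + 1] else TRUE
    left && right
  }, logical(1)))
  lm_idx <- lm_idx[d[lm_idx] > 1e-12]
  if (!length(lm_idx)) return(NULL)
  Tlmx <- d[lm_idx] - S * mean(diff(xn))
  for (k in seq_along(lm_idx)) {
    i <- lm_idx[k]
    jEnd <- if (k < length(lm_idx)) lm_idx[k + 1] else n
    if (i + 1 > jEnd) return(x[i])
    if (any(d[(i + 1):jEnd] < Tlmx[k])) return(x[i])
    if (k == length(lm_idx)) return(x[i])
  }
  NULL
}

# hand-computed one-way random-effects ICC(1,1) from the ANOVA table
oracle_icc11 <- function(x, y) {
  n <- length(x)
  dat <- cbind(x, y)
  grand <- mean(dat)
  ssb <- 2 * sum((rowMeans(dat) - grand)^2)
  ssw <- sum((dat - rowMeans(dat))^2)
  msb <- ssb / (n - 1)
  msw <- ssw / n
  (msb - msw) / (msb + msw)
}

# a small cached noise-free cohort reused by several files
cached_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- genCohort(cohortSpec(2, 2, snrDb = 5, effect = 0.5,
                                     durationMin = 1, nChannels = 4,
                                     seed = 42))
    cache
  }
})
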