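# Gaussian-copula MI estimation and the TMIF.

test_that("copula transform matches the quantile oracle and rank rules", {
  out <- copulaGaussianize(c(3, 1, 2))
  expect_equal(out, c(0.6745, -0.6745, 0), tolerance = 1e-4)
  set.seed(10)
  x <- rnorm(500)
  expect_equal(copulaGaussianize(x), oracle_gauss(x), tolerance = 1e-12)
  # invariance under strictly monotone transforms (identical ranks)
  expect_identical(copulaGaussianize(x^3), copulaGaussianize(x))
  expect_identical(copulaGaussianize(exp(x)), copulaGaussianize(x))
  # already-standard-normal large sample is nearly unchanged
  z <- rnorm(10000)
  expect_gt(cor(copulaGaussianize(z), z), 0.999)
  # order is preserved exactly
  expect_identical(order(copulaGaussianize(x)), order(x))
  expect_error(copulaGaussianize(rep(1, 50)), "constant")
  expect_error(copulaGaussianize(c(1, NA, 3)), "NaN|NA")
})

test_that("gaussian MI matches the bivariate closed form", {
  # samples constructed with the exact target correlation in-sample, so
  # the check isolates estimator error from sampling noise
  n <- 50000
  set.seed(11)
  x <- as.numeric(scale(rnorm(n)))
  e <- rnorm(n)
  e <- as.numeric(scale(lm(e ~ x)$residuals))
  for (rho in c(0, 0.3, 0.6, 0.9)) {
    y <- rho * x + sqrt(1 - rho^2) * e
    expect_equal(gaussianMI(x, y), -0.5 * log2(1 - rho^2),
                 tolerance = 0.01)
  }
  # symmetry and independence
  set.seed(12)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(gaussianMI(a, b), 0.01)
  expect_equal(gaussianMI(a, b), gaussianMI(b, a), tolerance = 1e-12)
})

test_that("MI of a linear-Gaussian channel grows as noise shrinks", {
  set.seed(13)
  n <- 20000
  X <- matrix(rnorm(2 * n), n, 2)
  mis <- vapply(c(1, 0.5, 0.1), function(sig)
    gaussianMI(X, X[, 1] + X[, 2] + sig * rnorm(n)), numeric(1))
  expect_true(all(diff(mis) > 0))
})

test_that("lag grid covers the window as specified", {
  expect_identical(lagGrid(c(-200, 500), 128), -26:64)
  expect_identical(lagGrid(c(0, 500), 128), 0:64)
  expect_length(lagGrid(c(-200, 500), 128), 91L)
})

test_that("TMIF peaks at the construction lag and respects invariances", {
  set.seed(14)
  n <- 4000
  raw <- as.numeric(scale(cumsum(rnorm(n))))   # smooth signal
  shift <- 22L                                  # 171.9 ms at 128 Hz
  eegM <- rbind(c(rep(0, shift), raw[1:(n - shift)]),
                rnorm(n))
  eeg <- mk_eeg(eegM)
  env <- mk_env(raw)
  tm <- computeTMIF(eeg, env, variant = "single_channel")
  peak <- lagTimes(tm)[which.max(miValues(tm)[, 1])]
  expect_equal(peak, shift / 128 * 1000, tolerance = 1e-9)
  expect_true(all(miValues(tm) >= 0))

  # monotone marginal transforms leave the TMIF unchanged (<= 1e-9 bits)
  tm2 <- computeTMIF(mk_eeg(rbind(eegM[1, ]^3, eegM[2, ])), env,
                     variant = "single_channel")
  expect_lt(max(abs(miValues(tm2) - miValues(tm))), 1e-9)
  # exp() then re-z-scoring is still strictly monotone
  env3 <- mk_env(exp(env@samples))
  tm3 <- computeTMIF(eeg, env3, variant = "single_channel")
  expect_lt(max(abs(miValues(tm3) - miValues(tm))), 1e-9)

  # affine rescaling of EEG channels leaves the TMIF unchanged
  tm4 <- computeTMIF(mk_eeg(rbind(5 * eegM[1, ] - 2, eegM[2, ])), env,
                     variant = "single_channel")
  expect_lt(max(abs(miValues(tm4) - miValues(tm))), 1e-9)
})

test_that("multivariate MI dominates its best member channel", {
  set.seed(15)
  n <- 50000
  y <- rnorm(n)
  X <- cbind(y + rnorm(n), y + 2 * rnorm(n))
  miJoint <- gaussianMI(X, y)
  miSingle <- max(gaussianMI(X[, 1], y), gaussianMI(X[, 2], y))
  expect_gt(miJoint, miSingle - 0.01)
})

test_that("TMIF smoothing is a 9-tap unit-sum Gaussian with DC preservation", {
  lags <- seq(-50, 200, by = 1000 / 128)
  flat <- new("TMIF", mi = matrix(0.3, length(lags), 1), lagsMs = lags,
              rate = 128, variant = "multivariate", band = "b",
              smoothed = FALSE, channelNames = character())
  expect_equal(miValues(smoothTMIF(flat)), miValues(flat),
               tolerance = 1e-12)
  imp <- flat
  imp@mi[, 1] <- 0; imp@mi[16, 1] <- 1
  sm <- smoothTMIF(imp)
  k <- exp(-((-4):4)^2 / 8); k <- k / sum(k)
  expect_equal(miValues(sm)[12:20, 1], k, tolerance = 1e-12)
  expect_equal(sum(miValues(sm)), 1, tolerance = 1e-12)
  # smoothing never increases the maximum
  set.seed(16)
  rnd <- flat; rnd@mi[, 1] <- runif(length(lags))
  expect_lte(max(miValues(smoothTMIF(rnd))), max(miValues(rnd)))
})

test_that("mean MI summarises the integration window correctly", {
  lags <- (0:64) * 1000 / 128
  tm <- new("TMIF", mi = matrix(seq_along(lags) / 65, 65, 1),
            lagsMs = lags, rate = 128, variant = "multivariate",
            band = "b", smoothed = TRUE, channelNames = character())
  expect_equal(meanMI(tm, c(0, 500)), mean(tm@mi))
  const <- tm; const@mi[] <- 0.7
  expect_equal(meanMI(const, c(0, 400)), 0.7)
  # 0-400 ms keeps lag bins 0..51 only
  expect_equal(meanMI(tm, c(0, 400)), mean(tm@mi[1:52, 1]))
  expect_error(meanMI(tm, c(900, 1000)), "empty")
})

test_that("TMIF input contracts are enforced", {
  eeg <- mk_eeg(matrix(rnorm(2 * 300), 2, 300))
  env <- mk_env(rnorm(300))
  expect_error(computeTMIF(eeg, mk_env(rnorm(200))), "equal durations")
  expect_error(computeTMIF(eeg, env, c(-2000, 3000)), "lag exceeds")
  wide <- mk_eeg(matrix(rnorm(40 * 300), 40, 300))
  expect_error(computeTMIF(wide, env), "10")
})
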