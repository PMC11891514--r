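# Feature building, nested CV SVM, metrics, Shapley attribution.

# small synthetic TMIFCohort with a separable group difference in the
# chosen bands
mk_sep_cohort <- function(n = 6, gap = 3, noise = 0.1, seed = 40,
                          effectBands = "theta") {
  set.seed(seed)
  lags <- lagGrid(c(-200, 500), 128) * 1000 / 128
  bump <- exp(-(lags - 170)^2 / (2 * 40^2))
  groups <- rep(c("control", "aphasia"), each = n)
  assays <- list()
  for (b in c("delta", "theta", "alpha", "beta", "gamma")) {
    m <- sapply(seq_along(groups), function(i) {
      amp <- if (b %in% effectBands && groups[i] == "aphasia")
        1 - gap / 4 else 1
      amp * bump + noise * rnorm(length(lags))
    })
    assays[[b]] <- pmax(m, 0)
  }
  ages <- 60 + 15 * stats::runif(length(groups))   # uninformative
  mk_cohort_tmif(assays, lags, groups, ages)
}

test_that("feature matrix has the documented layout", {
  ct <- mk_sep_cohort()
  ft <- buildFeatures(ct, pruneLenMs = 500)
  expect_equal(ncol(ft$x), 5 * 65 + 1)       # 65 nonnegative lags per band
  expect_equal(ft$columns$band[ncol(ft$x)], "age")
  ft2 <- buildFeatures(ct, pruneLenMs = 200)
  nl <- sum(lagTimes(ct) >= 0 & lagTimes(ct) <= 200)
  expect_equal(ncol(ft2$x), 5 * nl + 1)
  # identical subjects give identical rows
  a <- SummarizedExperiment::assay(ct, "theta")
  a[, 2] <- a[, 1]
  ct2 <- ct
  SummarizedExperiment::assay(ct2, "theta") <- a
  ft3 <- buildFeatures(ct2, 500, bands = "theta")
  expect_equal(unname(ft3$x[1, -ncol(ft3$x)]),
               unname(ft3$x[2, -ncol(ft3$x)]))
})

test_that("nested CV separates a separable cohort and stays deterministic", {
  ct <- mk_sep_cohort(n = 6, gap = 3, noise = 0.05,
                      effectBands = c("delta", "theta", "alpha",
                                      "beta", "gamma"))
  rep <- nestedCvSvm(ct, cGrid = c(0.1, 1, 10),
                     pruneGridMs = c(200, 400), seed = 2)
  m <- performanceMetrics(rep)
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  rep2 <- nestedCvSvm(ct, cGrid = c(0.1, 1, 10),
                      pruneGridMs = c(200, 400), seed = 2)
  expect_identical(rep2@predictions, rep@predictions)
})

test_that("held-out subjects cannot leak into fold-level choices", {
  ct <- mk_sep_cohort(n = 6, gap = 2, noise = 0.3)
  rep <- nestedCvSvm(ct, cGrid = c(0.1, 1), pruneGridMs = c(200, 400),
                     seed = 3)
  # inject an artifact into one subject; every other fold's chosen
  # hyperparameters may change (that subject trains them), but the
  # corrupted subject's own fold must pick the same hyperparameters,
  # since selection sees only its training subjects
  target <- 4L
  a <- SummarizedExperiment::assay(ct, "delta")
  a[, target] <- a[, target] + 50
  ct2 <- ct
  SummarizedExperiment::assay(ct2, "delta") <- a
  rep2 <- nestedCvSvm(ct2, cGrid = c(0.1, 1), pruneGridMs = c(200, 400),
                      seed = 3)
  expect_identical(rep2@hyperparameters[target, ],
                   rep@hyperparameters[target, ])
  # and training-fold standardization ignores the held-out subject
  sc <- envtrack:::.fit_scaler(buildFeatures(ct)$x[-target, , drop = FALSE])
  sc2 <- envtrack:::.fit_scaler(buildFeatures(ct2)$x[-target, , drop = FALSE])
  expect_identical(sc, sc2)
})

test_that("metrics reproduce the clinical confusion-matrix arithmetic", {
  labels <- c(rep("aphasia", 26), rep("control", 22))
  predicted <- c(rep("aphasia", 23), rep("control", 3),
                 rep("control", 17), rep("aphasia", 5))
  m <- classifierMetrics(predicted, labels)$metrics
  expect_equal(round(100 * m$sensitivity, 2), 88.46)
  expect_equal(round(100 * m$specificity, 2), 77.27)
  expect_equal(m$sensitivity, 23 / 26, tolerance = 1e-12)
  expect_equal(m$specificity, 17 / 22, tolerance = 1e-12)
  expect_equal(m$accuracy, 40 / 48, tolerance = 1e-12)

  allRight <- classifierMetrics(labels, labels,
                                ifelse(labels == "aphasia", 1, -1))$metrics
  expect_true(all(unlist(allRight) == 1))
  # degenerate ROC from constant decision values
  flat <- classifierMetrics(predicted, labels, rep(0, 48))
  expect_equal(flat$metrics$auc, 0.5)
  expect_error(classifierMetrics("aphasia", "aphasia"), "single-class")
})

test_that("trapezoid AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  labels <- sample(c("aphasia", "control"), 60, replace = TRUE)
  dec <- rnorm(60) + (labels == "aphasia")
  mine <- classifierMetrics(
    ifelse(dec > 0, "aphasia", "control"), labels, dec)$metrics$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    labels, dec, levels = c("control", "aphasia"),
    direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("grouped Shapley attribution is exact and identifies null bands", {
  ct <- mk_sep_cohort(n = 6, gap = 3, noise = 0.05)
  feats <- buildFeatures(ct)
  # silence two bands entirely: their columns carry no information
  feats$x[, feats$columns$band %in% c("beta", "gamma")] <- 0
  fit <- fitCohortSvm(feats, cost = 1)
  at <- shapleyAttribution(fit, feats$x, fit$groups, feats$x)
  # additivity holds exactly for exact Shapley
  expect_equal(rowSums(at@values), at@decision - at@baseline,
               tolerance = 1e-9)
  expect_lt(mean(abs(at@values[, "beta"])), 0.01)
  expect_lt(mean(abs(at@values[, "gamma"])), 0.01)
  # the engineered theta effect ranks first
  expect_equal(at@ranking[1], "theta")
  # low theta tracking pushes toward the aphasia class
  apha <- feats$labels == "aphasia"
  expect_gt(mean(at@values[apha, "theta"]),
            mean(at@values[!apha, "theta"]))

  # single-group game: the contribution equals decision - baseline
  one <- shapleyAttribution(fit, feats$x,
                            list(all = seq_len(ncol(feats$x))), feats$x)
  expect_equal(one@values[, 1], one@decision - one@baseline,
               tolerance = 1e-9)
})
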