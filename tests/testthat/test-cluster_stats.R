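# Cluster-based permutation tests.

test_that("samplewise Welch t matches a hand computation", {
  a <- rbind(c(1.0, 1.4, 1.2), c(0.2, 0.1, 0.15))
  b <- rbind(c(0.8, 0.9, 0.7), c(0.2, 0.1, 0.15))
  tt <- samplewiseStat(a, b)
  # hand-computed Welch t for bin 1
  mA <- mean(a[1, ]); mB <- mean(b[1, ])
  se <- sqrt(var(a[1, ]) / 3 + var(b[1, ]) / 3)
  expect_equal(tt[1], (mA - mB) / se, tolerance = 1e-12)
  expect_equal(tt[1], unname(t.test(a[1, ], b[1, ])$statistic),
               tolerance = 1e-12)
  expect_equal(tt[2], 0)                      # identical bins give 0
  expect_identical(samplewiseStat(a, a), c(0, 0))
  # direction: shifting B upward flips the sign
  expect_lt(samplewiseStat(a, a + 1)[1], 0)
  # zero variance with differing means is an error
  expect_error(samplewiseStat(matrix(1, 1, 3), matrix(2, 1, 3)),
               "zero variance")
})

test_that("cluster formation joins by lag contiguity and adjacency", {
  stat <- c(0, 3, 3.5, 4, 3.2, 3.1, 0.5, 3.3, 3.4, 0)
  cl <- formClusters(matrix(stat, ncol = 1), threshold = 2)
  expect_length(cl, 2L)
  expect_equal(cl[[1]]$mass, sum(stat[2:6]), tolerance = 1e-12)
  expect_equal(cl[[2]]$mass, sum(stat[8:9]), tolerance = 1e-12)
  # negative clusters tracked separately
  cl2 <- formClusters(matrix(c(3, 3, -3, -3), ncol = 1), threshold = 2)
  expect_setequal(vapply(cl2, `[[`, numeric(1), "sign"), c(1, -1))

  # spatio-temporal: adjacent channels merge, non-adjacent split
  m <- matrix(0, 5, 3)
  m[2:3, 1] <- 3; m[3:4, 2] <- 3
  adjYes <- matrix(FALSE, 3, 3); adjYes[1, 2] <- adjYes[2, 1] <- TRUE
  expect_length(formClusters(m, 2, adjYes), 1L)
  adjNo <- matrix(FALSE, 3, 3)
  expect_length(formClusters(m, 2, adjNo), 2L)
  expect_length(formClusters(matrix(0, 4, 1), 2), 0L)
})

test_that("montage adjacency is symmetric with plausible degree", {
  A <- channelAdjacency(defaultChannelSelection())
  expect_true(isSymmetric(A))
  expect_false(any(diag(A)))
  deg <- rowSums(A)
  expect_true(all(deg >= 1))
  expect_lt(mean(deg), 12)
})

test_that("permutation p-values are discrete, exchangeable, deterministic", {
  set.seed(30)
  x <- matrix(rnorm(20 * 8), 20, 8)
  x[8:12, 1:4] <- x[8:12, 1:4] + 2
  groups <- rep(c("control", "aphasia"), each = 4)
  lags <- seq(0, 148.4375, by = 1000 / 128)
  r3 <- clusterPermutationTest(x, groups, lags, nPerm = 3L, seed = 2)
  expect_true(all(clusterTable(r3)$p %in% c(0.25, 0.5, 0.75, 1)))

  # C(8,4) = 70 <= 100: the relabeling space is enumerated exactly, so
  # permuting subjects within groups leaves every p-value unchanged
  r <- clusterPermutationTest(x, groups, lags, nPerm = 100L, seed = 2)
  xp <- x[, c(3, 1, 4, 2, 7, 8, 5, 6)]
  rp <- clusterPermutationTest(xp, groups, lags, nPerm = 100L, seed = 2)
  expect_equal(clusterTable(rp)$p, clusterTable(r)$p, tolerance = 1e-12)
  # determinism given seed
  r2 <- clusterPermutationTest(x, groups, lags, nPerm = 100L, seed = 2)
  expect_identical(clusterTable(r2), clusterTable(r))
  # p floor is 1/(n+1)
  expect_gte(min(clusterTable(r)$p), 1 / (r@nPermutations + 1))
})

test_that("stronger effects never weaken the detected cluster", {
  lags <- seq(-200, 500, by = 1000 / 128)
  nl <- length(lags)
  bump <- exp(-(lags - 170)^2 / (2 * 40^2))
  ps <- vapply(c(1, 0.6, 0.2), function(scale) {
    set.seed(31)
    ctrl <- sapply(1:6, function(i) bump + 0.3 * rnorm(nl))
    apha <- sapply(1:6, function(i) scale * bump + 0.3 * rnorm(nl))
    r <- clusterPermutationTest(cbind(ctrl, apha),
                                rep(c("control", "aphasia"), each = 6),
                                lags, nPerm = 200L, seed = 7)
    tb <- clusterTable(r)
    if (nrow(tb)) min(tb$p) else 1
  }, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("spatio-temporal test localizes a channel-limited effect", {
  set.seed(32)
  chn <- c("Fz", "FCz", "Cz", "Pz", "Oz", "T7")
  nl <- 30
  x <- array(rnorm(nl * 6 * 10), c(nl, 6, 10))
  x[10:20, 1:3, 6:10] <- x[10:20, 1:3, 6:10] + 2   # frontal deficit group B
  r <- clusterPermutationTest(
    x, rep(c("aphasia", "control"), each = 5),
    lagsMs = seq(0, by = 1000 / 128, length.out = nl),
    channelNames = chn, nPerm = 100L, seed = 9)
  tb <- clusterTable(r)
  expect_gt(nrow(tb), 0)
  top <- tb[1, ]
  expect_lt(top$p, 0.05)
  topCh <- strsplit(top$channels, ",")[[1]]
  expect_true(all(c("Fz", "FCz", "Cz") %in% topCh))
})
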