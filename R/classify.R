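# Individual-level aphasia detection: per-band multivariate TMIFs + age
# into a nested cross-validated RBF-SVM (outer leave-one-subject-out,
# inner 5-fold selecting cost C and TMIF pruning length by accuracy),
# with grouped Monte-Carlo-free exact Shapley feature attribution.

.POSITIVE_CLASS <- "aphasia"

#' Build the classifier feature matrix
#'
#' Per band, the multivariate-TMIF values at nonnegative lags up to
#' \code{pruneLenMs} are concatenated, and age is appended as the last
#' column. Standardization is not applied here: scaling parameters are
#' learned inside training folds only.
#'
#' @param cohortTmif a \linkS4class{TMIFCohort}.
#' @param pruneLenMs keep lags in [0, pruneLenMs].
#' @param bands bands to include (default: all assays).
#' @return list with x (subjects x features matrix), columns (data.frame
#'   band/lag_ms per column), labels (factor control/aphasia), and
#'   subjects.
#' @export
buildFeatures <- function(cohortTmif, pruneLenMs = 500,
                          bands = SummarizedExperiment::assayNames(cohortTmif)) {
  stopifnot(is(cohortTmif, "TMIFCohort"))
  lags <- lagTimes(cohortTmif)
  keep <- which(lags >= 0 & lags <= pruneLenMs)
  if (!length(keep)) stop("pruning removed every lag")
  info <- subjectInfo(cohortTmif)
  blocks <- lapply(bands, function(b)
    t(SummarizedExperiment::assay(cohortTmif, b)[keep, , drop = FALSE]))
  x <- do.call(cbind, c(blocks, list(age = info$age)))
  columns <- data.frame(
    band = c(rep(bands, each = length(keep)), "age"),
    lag_ms = c(rep(lags[keep], length(bands)), NA))
  colnames(x) <- c(sprintf("%s_%gms", columns$band[-nrow(columns)],
                           columns$lag_ms[-nrow(columns)]), "age")
  list(x = x, columns = columns,
       labels = factor(info$group, levels = c("control", .POSITIVE_CLASS)),
       subjects = info$subject_id)
}

# column standardization learned on training rows only
.fit_scaler <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  sdv[sdv == 0] <- 1
  list(mu = mu, sd = sdv)
}
.apply_scaler <- function(x, sc) sweep(sweep(x, 2L, sc$mu), 2L, sc$sd, "/")

# fit an RBF-SVM with sklearn-style gamma = 1 / (n_features * var(X)).
# Inverse-frequency class weights are available but off by default: in
# leave-one-subject-out loops they upweight the held-out subject's class
# in every training set, which biases null-accuracy above chance.
.fit_svm <- function(x, y, cost, classWeights = FALSE) {
  g <- 1 / (ncol(x) * max(stats::var(as.vector(x)), 1e-12))
  w <- if (classWeights) {
    tab <- table(y)
    stats::setNames(as.vector(sum(tab) / (length(tab) * tab)), names(tab))
  } else NULL
  if (is.null(w))
    e1071::svm(x, y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = g, scale = FALSE)
  else
    e1071::svm(x, y, type = "C-classification", kernel = "radial",
               cost = cost, gamma = g, scale = FALSE, class.weights = w)
}

# decision values oriented so positive = aphasia
.decision_values <- function(model, x) {
  p <- stats::predict(model, x, decision.values = TRUE)
  dv <- drop(attr(p, "decision.values"))
  flip <- grepl(paste0("^", .POSITIVE_CLASS, "/"),
                colnames(attr(p, "decision.values"))[1])
  list(pred = p, decision = if (flip) dv else -dv)
}

# stratified k-fold assignment, deterministic given the RNG state
.stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Nested cross-validated SVM classification
#'
#' Outer loop: leave-one-subject-out. Inner loop: stratified 5-fold CV on
#' the remaining subjects, jointly selecting the SVM cost and the TMIF
#' pruning length by validation accuracy (ties resolved toward the
#' shorter pruning, then the smaller cost). The selected model is refit
#' on all outer-training subjects and applied to the held-out subject;
#' metrics are computed from the pooled outer predictions.
#'
#' @param cohortTmif a \linkS4class{TMIFCohort}.
#' @param cGrid SVM cost grid.
#' @param pruneGridMs candidate pruning lengths in ms.
#' @param innerFolds inner fold count (default 5).
#' @param seed RNG seed (drives the inner fold assignment).
#' @return a \linkS4class{ClassifierReport}.
#' @export
nestedCvSvm <- function(cohortTmif,
                        cGrid = 10^seq(-2, 2, by = 0.5),
                        pruneGridMs = c(100, 200, 300, 400, 500),
                        innerFolds = 5L, seed = 1L) {
  feats <- lapply(pruneGridMs, function(p) buildFeatures(cohortTmif, p))
  names(feats) <- as.character(pruneGridMs)
  labels <- feats[[1]]$labels
  subjects <- feats[[1]]$subjects
  n <- length(labels)
  if (min(table(labels)) < 3L)
    stop("need at least 3 subjects per class for nested CV")
  set.seed(seed)
  pred <- character(n)
  decision <- numeric(n)
  hyper <- data.frame(subject_id = subjects, C = NA_real_,
                      prune_ms = NA_real_)
  for (test in seq_len(n)) {
    train <- setdiff(seq_len(n), test)
    yTr <- droplevels(labels[train])
    if (nlevels(yTr) < 2L) stop("class absent from a training fold")
    fold <- .stratified_folds(labels[train], innerFolds)
    acc <- matrix(0, length(cGrid), length(pruneGridMs))
    for (pi in seq_along(pruneGridMs)) {
      xAll <- feats[[pi]]$x
      for (f in seq_len(innerFolds)) {
        trIdx <- train[fold != f]
        vaIdx <- train[fold == f]
        if (!length(vaIdx) || nlevels(droplevels(labels[trIdx])) < 2L) next
        sc <- .fit_scaler(xAll[trIdx, , drop = FALSE])
        xTr <- .apply_scaler(xAll[trIdx, , drop = FALSE], sc)
        xVa <- .apply_scaler(xAll[vaIdx, , drop = FALSE], sc)
        for (ci in seq_along(cGrid)) {
          m <- .fit_svm(xTr, labels[trIdx], cGrid[ci])
          acc[ci, pi] <- acc[ci, pi] +
            sum(stats::predict(m, xVa) == labels[vaIdx])
        }
      }
    }
    best <- which(acc == max(acc), arr.ind = TRUE)
    best <- best[order(best[, 2], best[, 1]), , drop = FALSE][1, ]
    ci <- best[1]; pi <- best[2]
    xAll <- feats[[pi]]$x
    sc <- .fit_scaler(xAll[train, , drop = FALSE])
    m <- .fit_svm(.apply_scaler(xAll[train, , drop = FALSE], sc),
                  labels[train], cGrid[ci])
    dv <- .decision_values(m, .apply_scaler(xAll[test, , drop = FALSE], sc))
    pred[test] <- as.character(dv$pred)
    decision[test] <- dv$decision
    hyper$C[test] <- cGrid[ci]
    hyper$prune_ms[test] <- pruneGridMs[pi]
  }
  rep <- classifierMetrics(pred, as.character(labels), decision)
  new("ClassifierReport", metrics = rep$metrics, roc = rep$roc,
      predictions = data.frame(subject_id = subjects,
                               label = as.character(labels),
                               predicted = pred, decision = decision),
      hyperparameters = hyper)
}

#' Classification performance metrics
#'
#' Aphasia is the positive class: sensitivity = TP / (TP + FN),
#' specificity = TN / (TN + FP), F1 for the positive class, and AUC by
#' trapezoid over the empirical ROC built from the decision values.
#'
#' @param predicted character vector of predicted labels.
#' @param labels character vector of true labels.
#' @param decision numeric decision values (larger = more aphasia-like).
#' @return list with metrics (named list) and roc (data.frame fpr/tpr).
#' @export
classifierMetrics <- function(predicted, labels, decision = NULL) {
  pos <- .POSITIVE_CLASS
  if (length(unique(labels)) < 2L)
    stop("metrics undefined for single-class input")
  tp <- sum(predicted == pos & labels == pos)
  fn <- sum(predicted != pos & labels == pos)
  tn <- sum(predicted != pos & labels != pos)
  fp <- sum(predicted == pos & labels != pos)
  accuracy <- (tp + tn) / length(labels)
  sensitivity <- tp / (tp + fn)
  specificity <- tn / (tn + fp)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  f1 <- if (precision + sensitivity == 0) 0 else
    2 * precision * sensitivity / (precision + sensitivity)
  roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  auc <- 0.5
  if (!is.null(decision)) {
    isPos <- labels == pos
    ord <- order(decision, decreasing = TRUE)
    tpr <- cumsum(isPos[ord]) / sum(isPos)
    fpr <- cumsum(!isPos[ord]) / sum(!isPos)
    # collapse threshold ties to the last point of each tie run
    keep <- c(diff(decision[ord]) != 0, TRUE)
    roc <- data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
    auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                  utils::tail(roc$tpr, -1)) / 2)
  }
  list(metrics = list(accuracy = accuracy, f1 = f1, auc = auc,
                      sensitivity = sensitivity,
                      specificity = specificity),
       roc = roc)
}

#' Grouped Shapley feature attribution
#'
#' Exact Shapley values over feature groups (one group per band plus
#' age): the value of a coalition is the mean decision value when the
#' coalition's columns come from the explained subject and the remaining
#' columns from background rows. With G groups all 2^G coalitions are
#' enumerated, so additivity (contributions sum to decision - baseline)
#' holds exactly.
#'
#' @param model fitted list with svm and scaler (see details) or an
#'   object returned by \code{.fit_svm}-based training; simplest is to
#'   pass \code{fitCohortSvm} output.
#' @param x subjects x features matrix (unscaled) to explain.
#' @param groups named list of column-index vectors.
#' @param background unscaled background matrix (training rows).
#' @return an \linkS4class{AttributionReport}.
#' @export
shapleyAttribution <- function(model, x, groups, background) {
  if (!nrow(background)) stop("background must be non-empty")
  G <- length(groups)
  if (G > 12L) stop("too many feature groups for exact enumeration")
  f <- function(m) {
    xs <- .apply_scaler(m, model$scaler)
    .decision_values(model$svm, xs)$decision
  }
  n <- nrow(x); nb <- nrow(background)
  xRep <- x[rep(seq_len(n), each = nb), , drop = FALSE]
  bRep <- background[rep(seq_len(nb), n), , drop = FALSE]
  # value of every coalition, per subject
  vals <- matrix(0, 2^G, n)
  for (s in 0:(2^G - 1)) {
    mask <- as.logical(bitwAnd(s, 2^(seq_len(G) - 1L)))
    cols <- unlist(groups[mask])
    mix <- bRep
    if (length(cols)) mix[, cols] <- xRep[, cols]
    vals[s + 1L, ] <- colMeans(matrix(f(mix), nb, n))
  }
  phi <- matrix(0, n, G, dimnames = list(rownames(x), names(groups)))
  factG <- factorial(G)
  for (g in seq_len(G)) {
    bit <- 2^(g - 1L)
    for (s in 0:(2^G - 1)) {
      if (bitwAnd(s, bit)) next
      k <- sum(as.logical(bitwAnd(s, 2^(seq_len(G) - 1L))))
      w <- factorial(k) * factorial(G - k - 1L) / factG
      phi[, g] <- phi[, g] + w * (vals[s + bit + 1L, ] - vals[s + 1L, ])
    }
  }
  baseline <- mean(vals[1L, ])
  decision <- vals[2^G, ]
  ranking <- names(sort(colMeans(abs(phi)), decreasing = TRUE))
  new("AttributionReport", values = phi, baseline = baseline,
      decision = decision, ranking = ranking)
}

#' Fit a single SVM on a whole cohort (for attribution)
#'
#' Standardizes the features, fits the RBF-SVM at the given cost, and
#' returns the pieces \code{shapleyAttribution} needs.
#'
#' @param features output of \code{buildFeatures}.
#' @param cost SVM cost parameter.
#' @return list with svm, scaler, x (unscaled), labels, and groups
#'   (per-band column indices plus age).
#' @export
fitCohortSvm <- function(features, cost = 1) {
  sc <- .fit_scaler(features$x)
  m <- .fit_svm(.apply_scaler(features$x, sc), features$labels, cost)
  bands <- unique(features$columns$band)
  groups <- lapply(bands, function(b) which(features$columns$band == b))
  names(groups) <- bands
  list(svm = m, scaler = sc, x = features$x, labels = features$labels,
       groups = groups)
}
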