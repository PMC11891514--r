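# Recording-length and reliability analyses: TMIFs on leading crops,
# SVM performance vs duration, within/between-subject stability (one-way
# ICC), Kneedle knee points, and split-half reliability with a Fisher-z
# group comparison.

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' Single-rater one-way random-effects ICC between k = 2 measurements per
#' target, with the F-based confidence interval and p-value.
#'
#' @param x,y paired measurements (one per target).
#' @param conf confidence level.
#' @return list with icc, ci (length 2), f, p, n.
#' @export
icc11 <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  k <- 2L
  dat <- cbind(x, y)
  grand <- mean(dat)
  msb <- k * sum((rowMeans(dat) - grand)^2) / (n - 1)
  msw <- sum((dat - rowMeans(dat))^2) / (n * (k - 1))
  if (msw == 0 && msb == 0) stop("constant data: ICC undefined")
  if (msw == 0) {
    return(list(icc = 1, ci = c(1, 1), f = Inf, p = 0, n = n))
  }
  fobs <- msb / msw
  icc <- (fobs - 1) / (fobs + k - 1)
  a <- (1 - conf) / 2
  fl <- fobs / stats::qf(1 - a, n - 1, n * (k - 1))
  fu <- fobs * stats::qf(1 - a, n * (k - 1), n - 1)
  list(icc = icc,
       ci = c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1)),
       f = fobs,
       p = stats::pf(fobs, n - 1, n * (k - 1), lower.tail = FALSE),
       n = n)
}

#' TMIFs on leading crops of a recording
#'
#' Crops the EEG and the envelope to the first 1, 3, 5, ... minutes and
#' recomputes the TMIF per duration with identical settings.
#'
#' @param eeg channels x samples matrix at \code{rate} (unreferenced raw).
#' @param envelope raw envelope at \code{rate}.
#' @param channelNames channel labels.
#' @param minutesGrid crop durations in minutes.
#' @param band band name.
#' @param rate input rate (Hz).
#' @param analysisRate analysis rate (Hz).
#' @param variant TMIF variant.
#' @param selection channels for the multivariate variant (default all).
#' @param smooth apply the lag smoother.
#' @return named list (minutes -> \linkS4class{TMIF}).
#' @export
cropTMIFs <- function(eeg, envelope, channelNames, minutesGrid, band,
                      rate = 512, analysisRate = 128,
                      variant = "multivariate", selection = NULL,
                      smooth = TRUE) {
  n <- ncol(eeg)
  if (max(minutesGrid) * 60 * rate > n) stop("crop longer than recording")
  out <- lapply(minutesGrid, function(m) {
    keep <- seq_len(round(m * 60 * rate))
    ref <- commonAverageReference(eeg[, keep, drop = FALSE])
    eb <- conditionEEG(ref, band, channelNames, rate, analysisRate)
    if (!is.null(selection)) eb <- selectChannels(eb, selection)
    envB <- bandEnvelope(envelope[keep], band, rate, analysisRate)
    tm <- computeTMIF(eb, envB, variant = variant)
    if (smooth) tm <- smoothTMIF(tm)
    tm
  })
  names(out) <- as.character(minutesGrid)
  out
}

#' Kneedle knee point of a saturating curve
#'
#' Kneedle on a concave increasing curve, no smoothing or interpolation:
#' x and y are min-max normalized, the difference curve d = y_n - x_n is
#' formed, and the knee is the local maximum of d that is confirmed by d
#' falling below (d_max - sensitivity * mean step) before the next local
#' maximum (the last local maximum is confirmed by the curve end).
#'
#' @param minutes x grid (strictly increasing).
#' @param values y values (same length).
#' @param sensitivity Kneedle sensitivity S (default 1).
#' @return list with minutes (knee location; last grid point when no
#'   knee exists) and found (logical).
#' @export
kneePoint <- function(minutes, values, sensitivity = 1) {
  stopifnot(length(minutes) == length(values), length(minutes) >= 3L)
  xr <- diff(range(minutes)); yr <- diff(range(values))
  if (yr <= 1e-12)
    return(list(minutes = minutes[length(minutes)], found = FALSE))
  xn <- (minutes - min(minutes)) / xr
  yn <- (values - min(values)) / yr
  d <- yn - xn
  nPts <- length(d)
  slopeSign <- sign(c(diff(d), -1))
  lmx <- which(diff(slopeSign) < 0) + 1L        # local maxima of d
  lmx <- lmx[d[lmx] > 1e-12]
  if (!length(lmx))
    return(list(minutes = minutes[nPts], found = FALSE))
  thrStep <- sensitivity * mean(diff(xn))
  for (i in seq_along(lmx)) {
    j <- lmx[i]
    thr <- d[j] - thrStep
    stopAt <- if (i < length(lmx)) lmx[i + 1] else nPts
    seg <- if (j + 1 <= stopAt) d[(j + 1):stopAt] else numeric()
    # a candidate is confirmed when d drops below its threshold before
    # the next local maximum; the last candidate is confirmed by the
    # curve end
    if (!length(seg) || any(seg < thr) || i == length(lmx))
      return(list(minutes = minutes[j], found = TRUE))
  }
  list(minutes = minutes[nPts], found = FALSE)
}

# knee on an arbitrary-length grid: degenerate grids fall back to the
# last point with the no-knee flag
.curve_knee <- function(minutes, values) {
  if (length(minutes) >= 3L) kneePoint(minutes, values)
  else list(minutes = minutes[length(minutes)],
            found = length(minutes) == 1L)
}

#' SVM performance as a function of recording length
#'
#' Recomputes the per-band TMIFs on each leading crop and reruns the full
#' nested cross-validated SVM per duration; the knee is located on the
#' accuracy curve.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param minutesGrid durations in minutes.
#' @param bands feature bands.
#' @param seed RNG seed.
#' @param ... passed to \code{nestedCvSvm}.
#' @return a \linkS4class{StabilityCurve} (kind "svm_performance") with
#'   accuracy, f1 and auc columns.
#' @export
performanceVsTime <- function(cohort, minutesGrid,
                              bands = setdiff(names(defaultBands()), "broad"),
                              seed = 1L, ...) {
  vals <- t(vapply(minutesGrid, function(m) {
    ct <- computeCohortTMIFs(cohort, bands = bands, cropMin = m)
    rep <- nestedCvSvm(ct, seed = deriveSeed(seed, "pvt", round(m * 10)), ...)
    unlist(rep@metrics[c("accuracy", "f1", "auc")])
  }, numeric(3)))
  colnames(vals) <- c("accuracy", "f1", "auc")
  kn <- if (length(minutesGrid) >= 3L)
    kneePoint(minutesGrid, vals[, "accuracy"])
  else list(minutes = minutesGrid[length(minutesGrid)],
            found = length(minutesGrid) == 1L)
  new("StabilityCurve", minutes = as.numeric(minutesGrid), values = vals,
      kind = "svm_performance", kneeMinutes = kn$minutes,
      kneeFound = kn$found)
}

#' Within-subject TMIF stability vs recording length
#'
#' Per subject, band and duration: ICC(1,1) over lag bins between the
#' cropped-duration TMIF and the full-recording TMIF. The curve is the
#' mean across subjects per band; the knee is located on the across-band
#' average.
#'
#' @param tmifsBySubject nested list: subject -> band -> duration ->
#'   \linkS4class{TMIF} (durations as produced by \code{cropTMIFs},
#'   including the full duration as the last grid point).
#' @param minutesGrid duration grid in minutes (last = full recording).
#' @return a \linkS4class{StabilityCurve} (kind "within_subject"),
#'   durations x bands, plus an "average" column.
#' @export
withinSubjectStability <- function(tmifsBySubject, minutesGrid) {
  stopifnot(length(minutesGrid) >= 2L)
  bands <- names(tmifsBySubject[[1]])
  nd <- length(minutesGrid)
  acc <- array(NA_real_, c(nd, length(bands), length(tmifsBySubject)),
               dimnames = list(NULL, bands, NULL))
  for (s in seq_along(tmifsBySubject)) for (b in bands) {
    tms <- tmifsBySubject[[s]][[b]]
    full <- rowMeans(miValues(tms[[nd]]))
    for (di in seq_len(nd)) {
      cur <- rowMeans(miValues(tms[[di]]))
      acc[di, b, s] <- tryCatch(icc11(cur, full)$icc,
                                error = function(e) NA_real_)
    }
  }
  if (anyNA(acc))
    warning("constant TMIF(s): undefined correlations excluded")
  vals <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  vals <- cbind(vals, average = rowMeans(vals))
  kn <- .curve_knee(minutesGrid, vals[, "average"])
  new("StabilityCurve", minutes = as.numeric(minutesGrid), values = vals,
      kind = "within_subject", kneeMinutes = kn$minutes,
      kneeFound = kn$found)
}

#' Between-subject stability of mean MI vs recording length
#'
#' Per band and duration: one ICC(1,1) across subjects between the
#' cropped-duration mean MI (0-400 ms) and the full-recording mean MI.
#' The knee is located on the across-band average.
#'
#' @param meanMiByBand named list: band -> subjects x durations matrix of
#'   mean MI (last column = full recording).
#' @param minutesGrid duration grid in minutes (last = full recording).
#' @return a \linkS4class{StabilityCurve} (kind "between_subject").
#' @export
betweenSubjectStability <- function(meanMiByBand, minutesGrid) {
  bands <- names(meanMiByBand)
  if (nrow(meanMiByBand[[1]]) < 3L) stop("need at least 3 subjects")
  nd <- length(minutesGrid)
  vals <- sapply(bands, function(b) {
    m <- meanMiByBand[[b]]
    full <- m[, nd]
    vapply(seq_len(nd), function(di) icc11(m[, di], full)$icc, numeric(1))
  })
  vals <- matrix(vals, nrow = nd, dimnames = list(NULL, bands))
  vals <- cbind(vals, average = rowMeans(vals))
  kn <- .curve_knee(minutesGrid, vals[, "average"])
  new("StabilityCurve", minutes = as.numeric(minutesGrid), values = vals,
      kind = "between_subject", kneeMinutes = kn$minutes,
      kneeFound = kn$found)
}

#' Split-half reliability of neural tracking
#'
#' From a per-subject table of first-half and second-half mean MI values:
#' per band and group the ICC(1,1) across subjects between halves with
#' its 95% CI and p-value, a Fisher-z comparison of the two groups' ICCs
#' per band, and multiple-comparison correction over all p-values.
#'
#' @param halfTable data.frame with columns subject_id, group, band,
#'   mi_first, mi_second.
#' @param correction p.adjust method (default "holm").
#' @return a \linkS4class{SplitHalfReport}.
#' @export
splitHalfICC <- function(halfTable, correction = "holm") {
  need <- c("subject_id", "group", "band", "mi_first", "mi_second")
  stopifnot(all(need %in% names(halfTable)))
  rows <- list()
  for (b in unique(halfTable$band)) {
    iccs <- list()
    for (g in unique(halfTable$group)) {
      sub <- halfTable[halfTable$band == b & halfTable$group == g, ]
      if (nrow(sub) < 3L) stop("group with fewer than 3 subjects")
      r <- icc11(sub$mi_first, sub$mi_second)
      iccs[[g]] <- r
      rows[[length(rows) + 1L]] <- data.frame(
        band = b, group = g, n = r$n, icc = r$icc,
        ci_lower = r$ci[1], ci_upper = r$ci[2], p = r$p)
    }
    if (length(iccs) == 2L) {
      z <- .fisher_z_test(iccs[[1]]$icc, iccs[[1]]$n,
                          iccs[[2]]$icc, iccs[[2]]$n)
      for (k in (length(rows) - 1L):length(rows))
        rows[[k]]$fisher_z_p <- z
    } else {
      for (k in length(rows)) rows[[k]]$fisher_z_p <- NA_real_
    }
  }
  tb <- do.call(rbind, rows)
  tb$p_corrected <- stats::p.adjust(tb$p, method = correction)
  tb <- tb[, c("band", "group", "n", "icc", "ci_lower", "ci_upper",
               "p", "p_corrected", "fisher_z_p")]
  new("SplitHalfReport", table = tb, correction = correction)
}

# two-sided Fisher-z comparison of two correlations
.fisher_z_test <- function(r1, n1, r2, n2) {
  cap <- function(r) max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- (atanh(cap(r1)) - atanh(cap(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  2 * stats::pnorm(-abs(z))
}

#' Per-subject split-half mean MI table for a synthetic cohort
#'
#' Splits each recording into its first and second half, recomputes the
#' band TMIFs per half with the standard pipeline, and tabulates the mean
#' MI (0-400 ms) per subject, band and half.
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param bands band names.
#' @param windowMs integration window for the mean MI.
#' @return data.frame suitable for \code{splitHalfICC}.
#' @export
splitHalfMeanMI <- function(cohort,
                            bands = setdiff(names(defaultBands()), "broad"),
                            windowMs = c(0, 400)) {
  stopifnot(is(cohort, "SyntheticCohort"))
  n <- length(cohort@envelope)
  half <- floor(n / 2)
  idx <- list(seq_len(half), (half + 1L):(2L * half))
  sel <- intersect(tolower(defaultChannelSelection()),
                   tolower(cohort@channelNames))
  if (!length(sel)) sel <- cohort@channelNames
  rows <- list()
  for (b in bands) {
    for (h in 1:2) {
      envB <- bandEnvelope(cohort@envelope[idx[[h]]], b, cohort@rate)
      for (s in seq_len(nrow(cohort@subjects))) {
        ref <- commonAverageReference(
          cohort@eeg[[s]][, idx[[h]], drop = FALSE])
        eb <- conditionEEG(ref, b, cohort@channelNames, cohort@rate)
        eb <- selectChannels(eb, sel)
        tm <- smoothTMIF(computeTMIF(eb, envB))
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = cohort@subjects$subject_id[s],
          group = cohort@subjects$group[s], band = b, half = h,
          mi = meanMI(tm, windowMs))
      }
    }
  }
  long <- do.call(rbind, rows)
  first <- long[long$half == 1L, ]
  second <- long[long$half == 2L, ]
  key <- paste(first$subject_id, first$band)
  stopifnot(identical(key, paste(second$subject_id, second$band)))
  data.frame(subject_id = first$subject_id, group = first$group,
             band = first$band, mi_first = first$mi,
             mi_second = second$mi)
}
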