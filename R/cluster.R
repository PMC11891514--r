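# Non-parametric cluster-based permutation tests for group differences:
# temporal (multivariate TMIF) and spatio-temporal (single-channel TMIF,
# with channel adjacency from the 2-D montage).

#' Channel adjacency from the montage
#'
#' Distance-threshold neighbours on the 2-D electrode positions: two
#' channels are adjacent when their distance is below
#' \code{radiusFrac} times the head radius (the maximum electrode
#' distance from the montage centroid).
#'
#' @param channelNames channels to include.
#' @param radiusFrac neighbourhood radius as a fraction of head radius.
#' @return logical adjacency matrix (diagonal FALSE).
#' @export
channelAdjacency <- function(channelNames, radiusFrac = 0.35) {
  montage <- readMontage()
  pos <- montage[match(tolower(channelNames), tolower(montage$channel)), ]
  if (anyNA(pos$x))
    stop("channel(s) absent from montage: ",
         paste(channelNames[is.na(pos$x)], collapse = ", "))
  ctr <- colMeans(montage[, c("x", "y")])
  headR <- max(sqrt((montage$x - ctr[1])^2 + (montage$y - ctr[2])^2))
  D <- as.matrix(stats::dist(pos[, c("x", "y")]))
  A <- D > 0 & D <= radiusFrac * headR
  dimnames(A) <- list(channelNames, channelNames)
  A
}

#' Samplewise group-difference statistic
#'
#' Welch's independent-samples t statistic per lag bin (and per channel
#' for spatio-temporal maps), with sign A - B. A Wilcoxon rank-sum
#' alternative (standardized, continuity-uncorrected) is available.
#'
#' @param a,b bins x subjects matrices (flatten lags x channels into the
#'   bin dimension for spatio-temporal data).
#' @param type "welch_t" or "rank_sum".
#' @return numeric vector of statistics, one per bin.
#' @export
samplewiseStat <- function(a, b, type = c("welch_t", "rank_sum")) {
  type <- match.arg(type)
  a <- as.matrix(a); b <- as.matrix(b)
  nA <- ncol(a); nB <- ncol(b)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  if (nrow(a) != nrow(b)) stop("groups must share the lag grid")
  if (type == "welch_t") {
    mA <- rowMeans(a); mB <- rowMeans(b)
    vA <- rowSums((a - mA)^2) / (nA - 1)
    vB <- rowSums((b - mB)^2) / (nB - 1)
    se2 <- vA / nA + vB / nB
    zero <- se2 == 0
    if (any(zero & (mA != mB)))
      stop("zero variance in both groups at a bin")
    out <- numeric(nrow(a))
    out[!zero] <- (mA - mB)[!zero] / sqrt(se2[!zero])
    out
  } else {
    n <- nA + nB
    apply(cbind(a, b), 1L, function(v) {
      r <- rank(v)
      W <- sum(r[seq_len(nA)])
      (W - nA * (n + 1) / 2) / sqrt(nA * nB * (n + 1) / 12)
    })
  }
}

#' Form supra-threshold clusters
#'
#' Bins whose |statistic| exceeds the threshold are joined by lag
#' contiguity, and by channel adjacency at the same lag for
#' spatio-temporal maps. Positive and negative clusters are tracked
#' separately; the cluster mass is the sum of the member statistics.
#'
#' @param statMap lags x channels matrix (one column for temporal tests).
#' @param threshold positive scalar, the cluster-forming critical value.
#' @param adjacency logical channel adjacency matrix (NULL for temporal).
#' @return list of clusters: each has bins (index matrix), sign, mass,
#'   lag and channel extent.
#' @export
formClusters <- function(statMap, threshold, adjacency = NULL) {
  statMap <- as.matrix(statMap)
  nl <- nrow(statMap); nc <- ncol(statMap)
  if (nc > 1L && is.null(adjacency))
    stop("spatio-temporal maps need a channel adjacency matrix")
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- sgn * statMap > threshold
    if (!any(supra)) next
    lab <- matrix(0L, nl, nc)
    nextLab <- 0L
    for (j in seq_len(nc)) for (i in seq_len(nl)) {
      if (!supra[i, j] || lab[i, j] != 0L) next
      nextLab <- nextLab + 1L
      queue <- list(c(i, j))
      lab[i, j] <- nextLab
      while (length(queue)) {
        cur <- queue[[1]]; queue <- queue[-1]
        ci <- cur[1]; cj <- cur[2]
        nbrs <- list()
        if (ci > 1L) nbrs <- c(nbrs, list(c(ci - 1L, cj)))
        if (ci < nl) nbrs <- c(nbrs, list(c(ci + 1L, cj)))
        if (!is.null(adjacency))
          for (cj2 in which(adjacency[cj, ])) nbrs <- c(nbrs, list(c(ci, cj2)))
        for (nb in nbrs) {
          if (supra[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
            lab[nb[1], nb[2]] <- nextLab
            queue <- c(queue, list(nb))
          }
        }
      }
    }
    for (k in seq_len(nextLab)) {
      bins <- which(lab == k, arr.ind = TRUE)
      out[[length(out) + 1L]] <- list(
        bins = bins, sign = sgn, mass = sum(statMap[bins]),
        lagRange = range(bins[, 1]), channels = sort(unique(bins[, 2])))
    }
  }
  out
}

# fast max-|cluster-mass| for permutations; temporal-only fast path
.max_cluster_mass <- function(statMap, threshold, adjacency) {
  statMap <- as.matrix(statMap)
  if (ncol(statMap) == 1L) {
    best <- 0
    for (sgn in c(1, -1)) {
      supra <- sgn * statMap[, 1] > threshold
      if (!any(supra)) next
      r <- rle(supra)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        m <- abs(sum(statMap[starts[k]:ends[k], 1]))
        if (m > best) best <- m
      }
    }
    return(best)
  }
  cl <- formClusters(statMap, threshold, adjacency)
  if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
}

#' Cluster-based permutation test for a group difference
#'
#' Computes the observed samplewise statistic map, forms supra-threshold
#' clusters (two-sided t critical value at \code{alpha} with
#' nA + nB - 2 df), and compares each observed cluster mass against the
#' permutation distribution of the maximum |cluster mass| under random
#' group relabelings with preserved group sizes. Cluster p-values use the
#' (1 + count) / (1 + nPerm) rule.
#'
#' @param x lags x subjects matrix (temporal) or lags x channels x
#'   subjects array (spatio-temporal).
#' @param groups factor/character of length n_subjects with two levels
#'   ("control", "aphasia"; the statistic sign is control - aphasia).
#' @param lagsMs lag grid of the TMIFs, ms.
#' @param channelNames channel names (spatio-temporal only).
#' @param nPerm number of relabelings.
#' @param alpha cluster-forming (and reporting) alpha.
#' @param adjacency channel adjacency (computed from the montage when
#'   omitted for spatio-temporal input).
#' @param statType samplewise statistic type (see samplewiseStat).
#' @param seed RNG seed.
#' @return a \linkS4class{ClusterResult}.
#' @export
clusterPermutationTest <- function(x, groups, lagsMs,
                                   channelNames = character(),
                                   nPerm = 1000L, alpha = 0.05,
                                   adjacency = NULL,
                                   statType = "welch_t", seed = 1L) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  lv <- c(intersect(c("control"), lv), setdiff(lv, "control"))
  spatio <- length(dim(x)) == 3L
  if (spatio) {
    nl <- dim(x)[1]; nc <- dim(x)[2]
    xm <- matrix(x, nl * nc, dim(x)[3])
    if (is.null(adjacency)) adjacency <- channelAdjacency(channelNames)
  } else {
    xm <- as.matrix(x)
    nl <- nrow(xm); nc <- 1L
  }
  iA <- which(groups == lv[1]); iB <- which(groups == lv[2])
  nA <- length(iA); nB <- length(iB)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  thr <- stats::qt(1 - alpha / 2, df = nA + nB - 2L)
  statFun <- function(ia, ib) samplewiseStat(
    xm[, ia, drop = FALSE], xm[, ib, drop = FALSE], statType)
  obsMap <- matrix(statFun(iA, iB), nl, nc)
  obs <- formClusters(obsMap, thr, if (spatio) adjacency else NULL)
  set.seed(seed)
  nTot <- nA + nB
  # with few subjects the relabeling space is enumerated exhaustively
  # (exact test, invariant to subject ordering); otherwise nPerm random
  # relabelings with preserved group sizes are drawn
  exhaustive <- choose(nTot, nA) <= nPerm
  relabels <- if (exhaustive) {
    cmb <- utils::combn(nTot, nA)
    lapply(seq_len(ncol(cmb)), function(k) cmb[, k])
  } else {
    lapply(seq_len(nPerm), function(k) sample(nTot, nA))
  }
  permMax <- vapply(relabels, function(ia) {
    pm <- matrix(statFun(ia, setdiff(seq_len(nTot), ia)), nl, nc)
    .max_cluster_mass(pm, thr, if (spatio) adjacency else NULL)
  }, numeric(1))
  nPerm <- length(permMax)
  chn <- if (spatio) channelNames else ""
  if (length(obs)) {
    clusters <- do.call(rbind, lapply(obs, function(cl) {
      data.frame(
        sign = ifelse(cl$sign > 0, "positive", "negative"),
        lag_start_ms = lagsMs[cl$lagRange[1]],
        lag_end_ms = lagsMs[cl$lagRange[2]],
        n_bins = nrow(cl$bins),
        mass = cl$mass,
        p = (1 + sum(permMax >= abs(cl$mass))) / (1 + nPerm),
        channels = if (spatio)
          paste(channelNames[cl$channels], collapse = ",") else "")
    }))
    clusters <- clusters[order(clusters$p, -abs(clusters$mass)), ]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(sign = character(), lag_start_ms = numeric(),
                           lag_end_ms = numeric(), n_bins = integer(),
                           mass = numeric(), p = numeric(),
                           channels = character())
  }
  new("ClusterResult", clusters = clusters, statMap = obsMap,
      lagsMs = lagsMs, channelNames = chn,
      nPermutations = as.integer(nPerm), thresholdAlpha = alpha,
      permMax = permMax)
}
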