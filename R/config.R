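# Run configuration: canonical band definitions, rates, windows,
# permutation counts, channel selection, and deterministic seed
# derivation. An empty YAML file reproduces all defaults.

#' Canonical EEG frequency bands
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, beta 12-30, (low-)gamma 30-49 and a
#' broad band 0.5-49 Hz covering them all.
#'
#' @return named list of numeric [low, high] pairs in Hz.
#' @export
defaultBands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 49), broad = c(0.5, 49))
}

#' Default multivariate channel selection
#'
#' A 22-channel fronto-central plus parieto-occipital set over the
#' BioSemi-64 10-20-equivalent labels. The exact membership is a documented
#' configuration value and can be overridden per run.
#'
#' @return character vector of 22 channel names.
#' @export
defaultChannelSelection <- function() {
  c("F1", "Fz", "F2", "FC3", "FC1", "FCz", "FC2", "FC4",
    "C1", "Cz", "C2",
    "P3", "P1", "Pz", "P2", "P4",
    "PO3", "POz", "PO4", "O1", "Oz", "O2")
}

#' AnalysisConfig: full run configuration
#'
#' @slot bands named list of [low, high] Hz pairs.
#' @slot rates named numeric: acquisition, intermediate, analysis (Hz).
#' @slot lagWindowMs numeric length-2, TMIF lag window in ms.
#' @slot integrationWindowMs numeric length-2, summary window in ms.
#' @slot nNullPermutations surrogate count for the per-subject null.
#' @slot nClusterPermutations relabeling count for cluster tests.
#' @slot clusterAlpha cluster-forming (and reporting) alpha.
#' @slot channelSelection channel names entering the multivariate TMIF.
#' @slot cropGridMin recording-length grid in minutes.
#' @slot globalSeed master seed; all stage seeds derive from it.
#' @slot options named list of secondary settings (null statistic, sample
#'   statistic for cluster tests, adjacency radius, SVM grids, correction
#'   method, knee sensitivity).
#' @exportClass AnalysisConfig
setClass("AnalysisConfig",
  representation(bands = "list", rates = "numeric",
                 lagWindowMs = "numeric", integrationWindowMs = "numeric",
                 nNullPermutations = "integer",
                 nClusterPermutations = "integer",
                 clusterAlpha = "numeric", channelSelection = "character",
                 cropGridMin = "numeric", globalSeed = "integer",
                 options = "list"),
  validity = function(object) {
    msg <- character()
    r <- object@rates
    if (!all(c("acquisition", "intermediate", "analysis") %in% names(r)))
      msg <- c(msg, "rates must name acquisition, intermediate, analysis")
    else {
      if (r["intermediate"] %% r["analysis"] != 0)
        msg <- c(msg, "analysis rate must divide intermediate rate")
      nyq <- r["analysis"] / 2
      for (b in names(object@bands)) {
        lim <- object@bands[[b]]
        if (!(0 < lim[1] && lim[1] < lim[2] && lim[2] <= nyq))
          msg <- c(msg, sprintf(
            "band '%s' must satisfy 0 < low < high <= Nyquist(analysis)", b))
      }
    }
    if (object@lagWindowMs[1] >= object@lagWindowMs[2])
      msg <- c(msg, "lag window must be increasing")
    if (object@integrationWindowMs[1] < object@lagWindowMs[1] ||
        object@integrationWindowMs[2] > object@lagWindowMs[2])
      msg <- c(msg, "integration window must lie inside the lag window")
    if (object@clusterAlpha <= 0 || object@clusterAlpha >= 1)
      msg <- c(msg, "clusterAlpha must be in (0, 1)")
    if (length(msg)) msg else TRUE
  })

#' Default analysis configuration
#'
#' All settings of the standard analysis: the six canonical bands, rates
#' 8192/512/128 Hz, lag window -200..500 ms, integration window 0..400 ms,
#' 1000 surrogate and 1000 cluster permutations at alpha 0.05, the
#' 22-channel selection, and the 1,3,5,...,25-minute crop grid.
#'
#' @param globalSeed master seed (integer).
#' @return an \linkS4class{AnalysisConfig}.
#' @export
defaultConfig <- function(globalSeed = 1L) {
  new("AnalysisConfig",
      bands = defaultBands(),
      rates = c(acquisition = 8192, intermediate = 512, analysis = 128),
      lagWindowMs = c(-200, 500),
      integrationWindowMs = c(0, 400),
      nNullPermutations = 1000L,
      nClusterPermutations = 1000L,
      clusterAlpha = 0.05,
      channelSelection = defaultChannelSelection(),
      cropGridMin = seq(1, 25, by = 2),
      globalSeed = as.integer(globalSeed),
      options = list(
        nullStatistic = "mean_mi",       # or "max_mi"
        samplewiseStat = "welch_t",      # or "rank_sum"
        adjacencyRadiusFrac = 0.35,      # of head radius, neighbourdist
        cGrid = 10^seq(-2, 2, by = 0.5), # SVM cost grid (9 points)
        pruneGridMs = c(100, 200, 300, 400, 500),
        correction = "holm",             # or "bonferroni", "BH"
        kneeSensitivity = 1))
}

# schema for the YAML validator: name -> list(type, len (NA = any))
.config_schema <- list(
  bands = list(type = "list", len = NA),
  rates = list(type = "numeric", len = 3L),
  lag_window_ms = list(type = "numeric", len = 2L),
  integration_window_ms = list(type = "numeric", len = 2L),
  n_null_permutations = list(type = "numeric", len = 1L),
  n_cluster_permutations = list(type = "numeric", len = 1L),
  cluster_alpha = list(type = "numeric", len = 1L),
  channel_selection = list(type = "character", len = NA),
  crop_grid_min = list(type = "numeric", len = NA),
  global_seed = list(type = "numeric", len = 1L),
  options = list(type = "list", len = NA))

#' Load a YAML configuration
#'
#' Reads a YAML file, validates every key against the configuration schema
#' (unknown keys and wrong types are errors), and merges it over the
#' defaults, so an empty file reproduces \code{defaultConfig()}.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param globalSeed seed used when the file does not set one.
#' @return an \linkS4class{AnalysisConfig}.
#' @export
loadConfig <- function(path = NULL, globalSeed = 1L) {
  cfg <- defaultConfig(globalSeed)
  if (is.null(path)) return(cfg)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) return(cfg)
  unknown <- setdiff(names(raw), names(.config_schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in names(raw)) {
    sc <- .config_schema[[k]]
    v <- raw[[k]]
    if (sc$type == "numeric") v <- unlist(v)
    if (sc$type == "character") v <- as.character(unlist(v))
    if (sc$type == "numeric" && !is.numeric(v))
      stop("config key '", k, "' must be numeric")
    if (!is.na(sc$len) && length(v) != sc$len)
      stop("config key '", k, "' must have length ", sc$len)
    switch(k,
      bands = { cfg@bands <- lapply(v, unlist) },
      rates = {
        v <- unlist(v)
        if (!all(c("acquisition", "intermediate", "analysis") %in% names(v)))
          stop("rates must name acquisition, intermediate and analysis")
        cfg@rates <- v[c("acquisition", "intermediate", "analysis")]
      },
      lag_window_ms = { cfg@lagWindowMs <- v },
      integration_window_ms = { cfg@integrationWindowMs <- v },
      n_null_permutations = { cfg@nNullPermutations <- as.integer(v) },
      n_cluster_permutations = { cfg@nClusterPermutations <- as.integer(v) },
      cluster_alpha = { cfg@clusterAlpha <- v },
      channel_selection = { cfg@channelSelection <- v },
      crop_grid_min = { cfg@cropGridMin <- v },
      global_seed = { cfg@globalSeed <- as.integer(v) },
      options = { cfg@options <- utils::modifyList(cfg@options, v) })
  }
  validObject(cfg)
  cfg
}

#' Derive a reproducible stage seed from the master seed
#'
#' Splits the master seed into independent per-stage, per-unit seeds so
#' stochastic stages are reproducible and order-independent. The result is
#' always a valid 32-bit R seed.
#'
#' @param globalSeed master seed.
#' @param stage stage label (character).
#' @param counter unit index within the stage (subject, permutation, ...).
#' @return integer seed in [0, 2^31 - 2].
#' @export
deriveSeed <- function(globalSeed, stage, counter = 0L) {
  sh <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  x <- (as.double(globalSeed) * 48271 + sh * 16807 + as.double(counter) * 69621)
  as.integer(x %% 2147483629)
}

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf(
    "AnalysisConfig: %d bands, rates %g/%g/%g Hz, lags [%g, %g] ms, seed %d\n",
    length(object@bands), object@rates[1], object@rates[2], object@rates[3],
    object@lagWindowMs[1], object@lagWindowMs[2], object@globalSeed))
})
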