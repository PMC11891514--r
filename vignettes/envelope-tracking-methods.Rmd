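---
title: "Methods: neural envelope tracking with Gaussian-copula mutual information"
author: "envtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neural envelope tracking with Gaussian-copula mutual information}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

When a listener follows continuous speech, low-frequency EEG tracks the
temporal envelope of the speech signal — the slow amplitude modulations
that carry syllabic and prosodic structure. `envtrack` quantifies this
*neural envelope tracking* and turns it into a subject-level marker, with
post-stroke aphasia detection as the driving application: people with
aphasia show weakened envelope tracking, most clearly around the second
peak of the response (~170 ms) and in the delta, theta and gamma bands.

The analysis chain is:

1. **Envelope extraction.** The audio is decomposed by a 28-channel
   4th-order gammatone filterbank (centre frequencies 50–5000 Hz, one ERB
   apart, Glasberg–Moore ERB-rate spacing). Each subband is compressed as
   `|x|^0.6` (an auditory-nerve-like power law), subbands are averaged,
   and the result is anti-alias downsampled to 512 Hz.
2. **Band filtering.** The envelope and the (artefact-cleaned,
   common-average-referenced) EEG are filtered into delta (0.5–4 Hz),
   theta (4–8), alpha (8–12), beta (12–30), low-gamma (30–49) and a broad
   band (0.5–49 Hz) with zero-phase least-squares linear-phase FIR
   filters, then z-scored and downsampled to the 128 Hz analysis rate.
3. **Temporal mutual information function (TMIF).** At every lag in
   −200…500 ms the envelope at time *t* is paired with the EEG at
   *t* + lag over the overlapping samples; both sides are
   copula-gaussianized (ranks → r/(n+1) → inverse normal CDF) and the
   parametric Gaussian MI
   `I(X;Y) = (1 / (2 ln 2)) ln(|Σx||Σy| / |Σxy|)` (bits) is evaluated.
   The single-channel variant yields one trace per channel; the
   multivariate variant treats the selected channels as one joint
   variable. Traces are smoothed along the lag axis with a 9-sample
   Gaussian kernel (SD 2 samples).
4. **Surrogate significance.** Per subject, 1000 spectrum-matched
   stationary noise envelopes (phase randomization — the amplitude
   spectrum is preserved exactly, the phases are i.i.d. uniform) are
   substituted for the true envelope; the 95th percentile (nearest rank)
   of the resulting summary statistic is the subject's significance
   level. The default summary is the mean MI over 0–400 ms of the
   multivariate TMIF, the same statistic used downstream (the per-lag
   maximum is available via `statistic = "max_mi"`).
5. **Group statistics.** Temporal (multivariate TMIF) and spatio-temporal
   (single-channel TMIF, channel adjacency from the 2-D montage)
   cluster-based permutation tests with group-size-preserving
   relabelings, cluster mass = sum of samplewise statistics, and the
   max-mass correction across positive and negative clusters.
6. **Individual-level detection.** An RBF-kernel SVM on the concatenated
   per-band multivariate TMIFs plus age, with nested cross-validation:
   leave-one-subject-out outside, stratified 5-fold inside, selecting the
   cost C and the TMIF pruning length by validation accuracy. Feature
   contribution is quantified with exact Shapley values over feature
   groups (one group per band, plus age).
7. **Reliability.** TMIFs are recomputed on leading crops
   (1, 3, 5, …, 25 min) for SVM-performance-vs-time and
   within/between-subject stability curves (one-way random-effects
   ICC(1,1)); knee points use the Kneedle algorithm; split-half
   reliability compares the two recording halves with ICC(1,1), F-based
   CIs, a Fisher-z group comparison and Holm correction.

# Key parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| rates (acquisition/intermediate/analysis) | 8192 / 512 / 128 | Hz | acquisition per the recording system; 512 Hz keeps gammatone output cheap; 128 Hz bounds the MI lag grid |
| lag window | −200…500 | ms | covers both response peaks plus a negative-lag control region |
| integration window | 0…400 | ms | where the envelope response lives; used for mean-MI summaries |
| filter ripple / attenuation | 0.25 / 10 | dB | passband and stopband bounds every designed filter must meet, measured from its transfer function |
| filter orders | 2000 (< 30 Hz edges), 500 (≥ 30 Hz) | taps | order escalation doubles the order until the measured bounds hold |
| surrogates | 1000 | — | resolves the 95th percentile well |
| cluster permutations | 1000, α = 0.05 | — | exact enumeration replaces sampling when the relabeling space is ≤ the permutation budget |
| SVM cost grid | 10^(−2…2), 9 points | — | only C is tuned (plus pruning), as in standard practice |
| pruning grid | 100…500 | ms | truncation of the nonnegative lag axis |
| channel selection | 22 fronto-central + parieto-occipital | — | the exact membership is a visible config value (`defaultChannelSelection()`), overridable |

# Numerical choices

* **Least-squares FIR design.** The linear-phase least-squares design is
  solved in closed form (Toeplitz-plus-Hankel normal equations from band
  integrals of `cos(jω)`). The nominal 10% transition is narrower than an
  order-2000 filter can realize at sub-hertz edges, so the design leaves
  one realizable transition width (`2·rate/order` Hz) of don't-care on
  the passband side of the cutoff, with a stopband weight of 10;
  compliance is then *measured* from the transfer function — the full
  stopband must sit below −10 dB and the passband from 1.5 transition
  widths inside the edge must stay within 0.25 dB. All six bands meet
  the bounds at their rule orders without escalation.
* **Zero-phase filtering and edges.** Filters are applied once by FFT
  convolution with the symmetric group delay removed, after *odd*
  (antisymmetric) reflection padding of one filter order — odd reflection
  keeps both the value and the slope continuous at the joins, so
  highpass/bandpass filters see no edge kink (with even reflection the
  delta-band energy, ~60 dB above gamma, leaks visible edge bursts into
  the narrow bands).
* **Resampling.** Downsampling is FFT-domain spectral truncation (an
  ideal anti-aliasing brick wall below the new Nyquist) on a
  reflection-padded, FFT-friendly length. Equivalence to polyphase
  resamplers is spectral: alias suppression is exact by construction.
* **Z-score order.** Signals are z-scored *before* the final downsample,
  following the stated processing order; the post-downsample moments are
  asserted to lie within 0.02 of (0, 1) (the drift is ~1e−4 in practice)
  and can be re-standardized with `restandardize = TRUE` (off by
  default).
* **Per-lag copula.** The copula transform is recomputed on each
  lag-aligned overlap, so ranks always reflect the retained samples.
  Because successive overlaps are nested prefixes/suffixes, the compiled
  core maintains ranks incrementally (one O(m) update per lag) instead
  of re-sorting; results are identical to the direct computation to
  ~1e−13 bits.
* **Degenerate covariances.** A ridge of `1e−12·trace/d` is added before
  determinants (with one `1e−8` retry); this keeps the multivariate MI
  well defined after common-average referencing, which makes the channel
  covariance rank-deficient by one.
* **Lag grid.** [−200, 500] ms at 128 Hz maps to sample shifts −26…64
  (floor/ceiling so the grid covers the window).
* **Ties.** Tied ranks are averaged; surrogate and physiological signals
  are continuous, so the tie path is a rarely-exercised fallback.
* **Percentiles.** Nearest rank, `ceil(0.95·n)`, well defined at n = 1000.
* **Knee detection.** Kneedle on the min-max-normalized curve,
  sensitivity 1, no smoothing or interpolation; a candidate knee is
  confirmed when the difference curve drops below its threshold before
  the next local maximum (the last candidate is confirmed by the curve
  end); an effectively linear curve returns the last grid point with
  `found = FALSE`.

# Design decisions where the design was open

* **Null summary statistic** — mean MI over 0–400 ms of the multivariate
  TMIF, i.e. exactly the statistic interpreted downstream; configurable
  to the per-lag maximum.
* **Samplewise statistic for cluster tests** — Welch's t (two-sided,
  threshold at the t critical value with nA+nB−2 df), with a Wilcoxon
  rank-sum alternative, matching the nonparametric style used elsewhere
  in the analysis.
* **Channel adjacency** — distance-threshold neighbours on the shipped
  2-D montage (radius 0.35 of the head radius, ~6 neighbours per
  channel), the neighbourdist construction common in EEG cluster testing.
* **Class weighting** — available but **off** by default. Inside
  leave-one-subject-out, inverse-frequency weights systematically
  upweight the held-out subject's class in every training set; on
  effect-free data this biases accuracy above chance (we measured ~0.75
  where chance is 0.5). The unweighted fit matches the scikit-learn
  default and keeps the null calibration honest.
* **Exact permutation enumeration** — when `choose(n, nA)` does not
  exceed the permutation budget the relabeling space is enumerated
  exhaustively, which makes the test invariant to subject ordering and
  removes Monte-Carlo noise for small groups.
* **Shapley attribution** — exact enumeration over the 6 feature groups
  (2^6 coalitions against a background sample), so additivity
  (contributions sum to decision − baseline) holds exactly rather than
  within a Monte-Carlo tolerance.
* **ICC flavour** — ICC(1,1), one-way random effects, single rater,
  everywhere an intraclass correlation is reported, for internal
  consistency; Holm correction over the split-half p-value family
  (Bonferroni and BH are available).
* **Fisher z for ICC comparison** — Fisher transform with variance
  1/(n−3) per group, two-sided z test.
* **Time alignment** — stimulus onset is sample 0 of both streams after
  the subject's `alignment_offset`; trigger decoding is out of scope.

# The synthetic cohort generator

Every statistical stage is exercised on synthetic cohorts
(`cohortSpec()`, `genCohort()`) whose generative model is the minimal one
under which all stages have known expected behaviour: per band, the
band-filtered story envelope is convolved with a two-peaked response
kernel (Gaussian bumps at 50 and 170 ms, SDs 12 and 30 ms, the second
peak carrying most of the energy), summed over bands, projected to
channels by a raised-cosine fronto-central topography, and buried in 1/f
Gaussian noise scaled to a per-band SNR. The aphasia group's second peak
is multiplicatively attenuated in delta, theta and gamma only. The
envelope generator rectifies spectrally shaped noise with a modulation
bump at the ~4 Hz syllable rate. Defaults are the study conditions: a
25-minute story, 64 channels, ages N(72, 10) truncated to [40, 95], a
modest in-band SNR (−5 dB) and a 50% second-peak attenuation.
`snrDb = Inf` disables the noise (used for latency-recovery checks);
`snrDb = -Inf` yields a no-response subject, 1/f noise only (used for
null calibration).

What the generator does *not* emulate: artefacts (blinks, muscle, line
noise), nonstationarity, per-subject response-latency variability,
lesioned topographies, or envelope–EEG misalignment. Passing tests
therefore demonstrate the correctness and calibration of the analysis
under its own assumptions, not robustness to real-world artefacts.

Two physical notes. First, the speech envelope's long autocorrelation
(delta-dominated) couples the intact 50-ms response to the 170-ms lag,
so removing the second kernel peak attenuates — but cannot null — the
TMIF at 170 ms; only a fully response-free subject falls to the
surrogate level. This is the familiar lag-resolution limit of lagged-MI
analyses. Second, with a common-average reference a same-gain channel
subset would cancel the shared response, so reduced synthetic montages
spread their channels across the topography-gain range.

# Verification problem sizes

The test suite verifies calibration and power by simulation at sizes
chosen to keep the full suite practical on a single core while retaining
statistical meaning: null calibration of the surrogate test uses 200
no-response subjects (30-s recordings, 3 channels) with 200 surrogates
each; cluster-test type-I error uses 100 effect-free cohorts of 8+8
subjects with 3-minute recordings and 500 permutations; power and
localization use 50 cohorts of 12+12 with 50% second-peak attenuation at
+10 dB SNR; classifier null calibration uses 20 cohorts of 11 controls +
13 aphasia (mirroring the clinical imbalance) with 30-s recordings;
reliability properties use cohorts whose per-subject SNR is spread over
a wide range — between-subject ICCs are only defined when subjects truly
differ in tracking strength — with a per-band SNR profile that declines
toward gamma, as it does empirically. Recording durations, channel
counts and SVM grid densities in these simulations are deliberately
smaller than the clinical study's; the properties tested (error rates,
calibration, ordering) are size-invariant.

# Known limitations

* Input EEG is assumed artefact-cleaned; no cleaning stages are
  implemented.
* The MI estimator is the plug-in Gaussian-copula estimate; its small
  positive bias is shared by surrogate and observed values, so
  comparisons are unaffected, but absolute bit values depend on the
  recording length.
* TMIF lag resolution is limited by the envelope autocorrelation (see
  above); peak latencies are interpretable, fine lag structure is not.
* The clinical headline numbers of the motivating application (83.33%
  accuracy etc.) depend on a private 48-subject dataset; this package
  reproduces the *method* and its calibration, not those numbers.
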