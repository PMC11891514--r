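// Gaussian-copula mutual information core.
//
// Hot loops of the TMIF (temporal mutual information function) and of the
// surrogate null distribution. All randomness stays in R; everything here
// is deterministic. The copula transform is recomputed on each lag-aligned
// overlap (ranks depend on the retained samples); because successive lag
// overlaps are nested prefixes/suffixes of the signals, ranks are
// maintained incrementally (one O(m) update per lag) instead of re-sorted.

#include <RcppArmadillo.h>
#include <map>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double LOG2 = std::log(2.0);
static const double RIDGE_EPS = 1e-12;

// copula-gaussianize x[0..m-1] into out, averaging tied ranks.
static void gaussianize_full(const double* x, int m, std::vector<int>& idx,
                             double* out) {
  if ((int)idx.size() < m) idx.resize(m);
  for (int i = 0; i < m; ++i) {
    if (ISNAN(x[i])) stop("NaN in input to the copula transform");
    idx[i] = i;
  }
  std::sort(idx.begin(), idx.begin() + m,
            [&](int a, int b) { return x[a] < x[b]; });
  int i = 0;
  bool constant = true;
  while (i < m) {
    int j = i;
    while (j + 1 < m && x[idx[j + 1]] == x[idx[i]]) ++j;
    double r = 0.5 * (i + j) + 1.0; // average 1-based rank
    double val = R::qnorm(r / (m + 1.0), 0.0, 1.0, 1, 0);
    if (j - i + 1 < m) constant = false;
    for (int k = i; k <= j; ++k) out[idx[k]] = val;
    i = j + 1;
  }
  if (constant) stop("constant column: copula transform undefined");
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussianize(NumericMatrix X) {
  int n = X.nrow(), d = X.ncol();
  NumericMatrix out(n, d);
  std::vector<int> idx(n);
  for (int j = 0; j < d; ++j)
    gaussianize_full(&X(0, j), n, idx, &out(0, j));
  return out;
}

// Maintains 1-based ranks of x[lo..hi] as the window shrinks from either
// side. Tie-free data gets O(m) updates per shrink; with ties the window
// is re-ranked from scratch (ties are vanishingly rare for the continuous
// signals this package processes).
struct WindowRanks {
  const double* x = nullptr;
  int n = 0, lo = 0, hi = -1;
  bool hasTies = false;
  std::vector<double> rank; // absolute-position indexed, valid on [lo, hi]
  std::vector<int> scratch;

  void init(const double* x_, int n_, int lo_, int hi_) {
    x = x_; n = n_; lo = lo_; hi = hi_;
    rank.assign(n, 0.0);
    rebuild();
  }
  void rebuild() {
    int m = hi - lo + 1;
    if ((int)scratch.size() < m) scratch.resize(m);
    for (int i = 0; i < m; ++i) {
      if (ISNAN(x[lo + i])) stop("NaN in input to the copula transform");
      scratch[i] = lo + i;
    }
    std::sort(scratch.begin(), scratch.begin() + m,
              [&](int a, int b) { return x[a] < x[b]; });
    hasTies = false;
    int i = 0;
    while (i < m) {
      int j = i;
      while (j + 1 < m && x[scratch[j + 1]] == x[scratch[i]]) ++j;
      if (j > i) hasTies = true;
      double r = 0.5 * (i + j) + 1.0;
      for (int k = i; k <= j; ++k) rank[scratch[k]] = r;
      i = j + 1;
    }
    if (hasTies && m > 1 && x[scratch[0]] == x[scratch[m - 1]])
      stop("constant column: copula transform undefined");
  }
  void shrink_to(int newLo, int newHi) {
    if (newLo < lo || newHi > hi) stop("window can only shrink");
    if (hasTies) { lo = newLo; hi = newHi; rebuild(); return; }
    while (hi > newHi) {
      double r = rank[hi];
      --hi;
      for (int i = lo; i <= hi; ++i) if (rank[i] > r) rank[i] -= 1.0;
    }
    while (lo < newLo) {
      double r = rank[lo];
      ++lo;
      for (int i = lo; i <= hi; ++i) if (rank[i] > r) rank[i] -= 1.0;
    }
  }
  // write gaussianized values (using a per-m table for integral ranks)
  void gauss(double* out, const std::vector<double>& tab) const {
    int m = hi - lo + 1;
    if (!hasTies) {
      for (int i = 0; i < m; ++i) out[i] = tab[(int)rank[lo + i]];
    } else {
      for (int i = 0; i < m; ++i) {
        double r = rank[lo + i];
        double ri = std::floor(r);
        out[i] = (r == ri) ? tab[(int)ri]
                           : R::qnorm(r / (m + 1.0), 0.0, 1.0, 1, 0);
      }
    }
  }
};

// cache of qnorm(r / (m + 1)) tables keyed by segment length m; capped so
// repeated analyses of equal-length recordings (cohorts, surrogate loops)
// pay for each table once
static std::map<int, std::vector<double>>& qtab_cache() {
  static std::map<int, std::vector<double>> cache;
  return cache;
}
static size_t qtab_cache_size = 0;

static const std::vector<double>& get_qtab(int m) {
  auto& cache = qtab_cache();
  auto it = cache.find(m);
  if (it != cache.end()) return it->second;
  if (qtab_cache_size > 6000000) { cache.clear(); qtab_cache_size = 0; }
  std::vector<double> tab(m + 1);
  for (int r = 1; r <= m; ++r)
    tab[r] = R::qnorm((double)r / (m + 1.0), 0.0, 1.0, 1, 0);
  qtab_cache_size += m + 1;
  return cache.emplace(m, std::move(tab)).first->second;
}

// log-determinant via Cholesky with a scaled ridge retry
static double safe_logdet(arma::mat S) {
  int d = S.n_rows;
  double tr = arma::trace(S);
  S.diag() += RIDGE_EPS * tr / d;
  arma::mat L;
  if (!arma::chol(L, S)) {
    S.diag() += 1e-8 * tr / d;
    if (!arma::chol(L, S))
      stop("singular joint covariance after regularization");
  }
  return 2.0 * arma::sum(arma::log(L.diag()));
}

static double mi_from_joint(const arma::mat& C, int d, bool multivariate,
                            double* perChannel) {
  if (multivariate) {
    double ldXY = safe_logdet(C);
    double ldX = safe_logdet(C.submat(0, 0, d - 1, d - 1));
    double ldY = std::log(C(d, d));
    double mi = (ldX + ldY - ldXY) / (2.0 * LOG2);
    return mi > 0 ? mi : 0.0;
  }
  for (int j = 0; j < d; ++j) {
    double r2 = C(j, d) * C(j, d) / (C(j, j) * C(d, d));
    if (r2 > 1.0 - 1e-15) r2 = 1.0 - 1e-15;
    double mi = -0.5 * std::log(1.0 - r2) / LOG2;
    perChannel[j] = mi > 0 ? mi : 0.0;
  }
  return 0.0;
}

// lags must arrive sorted ascending (checked in R). EEG is n x d,
// envelope length n. Positive lag: EEG window [lag, n-1], envelope window
// [0, n-1-lag]; negative lag the mirror image.
// [[Rcpp::export]]
NumericMatrix cpp_tmif(NumericMatrix eegR, NumericVector envR,
                       IntegerVector lags, bool multivariate) {
  arma::mat eeg(eegR.begin(), eegR.nrow(), eegR.ncol(), false);
  int n = eeg.n_rows, d = eeg.n_cols, nlags = lags.size();
  NumericMatrix out(nlags, multivariate ? 1 : d);
  arma::mat Z(n, d + 1);

  // process nonnegative lags in ascending order, negative in descending
  // order, so every window change is a shrink.
  std::vector<int> order;
  for (int i = 0; i < nlags; ++i) if (lags[i] >= 0) order.push_back(i);
  std::vector<int> negOrder;
  for (int i = nlags - 1; i >= 0; --i) if (lags[i] < 0) negOrder.push_back(i);

  for (int pass = 0; pass < 2; ++pass) {
    const std::vector<int>& ord = pass == 0 ? order : negOrder;
    if (ord.empty()) continue;
    std::vector<WindowRanks> chan(d);
    WindowRanks envw;
    int tau0 = lags[ord[0]];
    int eegLo0 = tau0 >= 0 ? tau0 : 0, eegHi0 = tau0 >= 0 ? n - 1 : n - 1 + tau0;
    int envLo0 = tau0 >= 0 ? 0 : -tau0, envHi0 = tau0 >= 0 ? n - 1 - tau0 : n - 1;
    for (int j = 0; j < d; ++j)
      chan[j].init(eeg.colptr(j), n, eegLo0, eegHi0);
    envw.init(envR.begin(), n, envLo0, envHi0);
    for (int oi : ord) {
      int tau = lags[oi];
      int m = n - std::abs(tau);
      if (m < 3) stop("lag exceeds signal length");
      int eegLo = tau >= 0 ? tau : 0, eegHi = tau >= 0 ? n - 1 : n - 1 + tau;
      int envLo = tau >= 0 ? 0 : -tau, envHi = tau >= 0 ? n - 1 - tau : n - 1;
      const std::vector<double>& qtab = get_qtab(m);
      for (int j = 0; j < d; ++j) {
        chan[j].shrink_to(eegLo, eegHi);
        chan[j].gauss(Z.colptr(j), qtab);
      }
      envw.shrink_to(envLo, envHi);
      envw.gauss(Z.colptr(d), qtab);
      arma::mat Zm = Z.head_rows(m);
      arma::mat C = arma::cov(Zm);
      if (multivariate) out(oi, 0) = mi_from_joint(C, d, true, nullptr);
      else {
        std::vector<double> perCh(d);
        mi_from_joint(C, d, false, perCh.data());
        for (int j = 0; j < d; ++j) out(oi, j) = perCh[j];
      }
    }
  }
  return out;
}

// Null-distribution fast path: the EEG side of every lag is fixed across
// surrogates, so its copula transform, covariance inverse and log-det are
// computed once; each surrogate column then pays one initial sort plus an
// O(m) rank update and d cross-covariances per lag.
// Returns an (nperm x nlags) matrix of multivariate MI values.
// [[Rcpp::export]]
NumericMatrix cpp_null_mi(NumericMatrix eegR, NumericMatrix surrR,
                          IntegerVector lags) {
  arma::mat eeg(eegR.begin(), eegR.nrow(), eegR.ncol(), false);
  arma::mat surr(surrR.begin(), surrR.nrow(), surrR.ncol(), false);
  int n = eeg.n_rows, d = eeg.n_cols;
  int nlags = lags.size(), nperm = surr.n_cols;
  if ((int)surr.n_rows != n) stop("surrogates must match the EEG length");

  // per-lag EEG preparation (same shrink ordering as the surrogate loop)
  std::vector<arma::mat> Zx(nlags), SxInv(nlags);
  std::vector<const std::vector<double>*> qtabs(nlags);
  std::vector<int> order;
  for (int i = 0; i < nlags; ++i) if (lags[i] >= 0) order.push_back(i);
  std::vector<int> negOrder;
  for (int i = nlags - 1; i >= 0; --i) if (lags[i] < 0) negOrder.push_back(i);

  for (int pass = 0; pass < 2; ++pass) {
    const std::vector<int>& ord = pass == 0 ? order : negOrder;
    if (ord.empty()) continue;
    std::vector<WindowRanks> chan(d);
    int tau0 = lags[ord[0]];
    for (int j = 0; j < d; ++j)
      chan[j].init(eeg.colptr(j), n,
                   tau0 >= 0 ? tau0 : 0, tau0 >= 0 ? n - 1 : n - 1 + tau0);
    for (int oi : ord) {
      int tau = lags[oi];
      int m = n - std::abs(tau);
      if (m <= d + 2) stop("lag exceeds signal length");
      qtabs[oi] = &get_qtab(m);
      arma::mat Z(m, d);
      for (int j = 0; j < d; ++j) {
        chan[j].shrink_to(tau >= 0 ? tau : 0, tau >= 0 ? n - 1 : n - 1 + tau);
        chan[j].gauss(Z.colptr(j), *qtabs[oi]);
      }
      Z.each_row() -= arma::mean(Z, 0);
      arma::mat Sx = Z.t() * Z / (m - 1);
      Sx.diag() += RIDGE_EPS * arma::trace(Sx) / d;
      Zx[oi] = std::move(Z);
      SxInv[oi] = arma::inv_sympd(Sx);
    }
  }

  NumericMatrix out(nperm, nlags);
  arma::vec zy(n);
  for (int p = 0; p < nperm; ++p) {
    for (int pass = 0; pass < 2; ++pass) {
      const std::vector<int>& ord = pass == 0 ? order : negOrder;
      if (ord.empty()) continue;
      WindowRanks envw;
      int tau0 = lags[ord[0]];
      envw.init(surr.colptr(p), n,
                tau0 >= 0 ? 0 : -tau0, tau0 >= 0 ? n - 1 - lags[ord[0]] : n - 1);
      for (int oi : ord) {
        int tau = lags[oi];
        int m = n - std::abs(tau);
        envw.shrink_to(tau >= 0 ? 0 : -tau, tau >= 0 ? n - 1 - tau : n - 1);
        envw.gauss(zy.memptr(), *qtabs[oi]);
        arma::vec zym = zy.head(m);
        zym -= arma::mean(zym);
        double vy = arma::dot(zym, zym) / (m - 1);
        arma::vec c = Zx[oi].t() * zym / (m - 1);
        double q = arma::as_scalar(c.t() * SxInv[oi] * c);
        double mi;
        if (q < vy) mi = 0.5 * std::log(vy / (vy - q)) / LOG2;
        else mi = 0.5 * std::log(1e15) / LOG2; // numerically saturated
        out(p, oi) = mi;
      }
    }
  }
  return out;
}
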