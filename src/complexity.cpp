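// Fast implementations of the five complexity measures used to summarise
// band-limited EEG epochs. All tolerances r are in absolute signal units;
// callers scale by the per-channel SD. Tested against brute-force R oracles.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

// Chebyshev distance between length-m templates starting at i and j.
// Early exit once the running max exceeds r (callers only need d <= r).
static inline bool cheb_within(const double* x, int i, int j, int m, double r) {
  for (int k = 0; k < m; ++k) {
    double d = std::fabs(x[i + k] - x[j + k]);
    if (d > r) return false;
  }
  return true;
}

// Pincus approximate entropy: Phi^m - Phi^{m+1}, self-match included,
// natural log. Phi^m averages ln(C_i) over the N-m+1 length-m templates.
// [[Rcpp::export(name = ".apen_cpp")]]
double apen_cpp(NumericVector xv, int m, double r) {
  const int N = xv.size();
  if (N <= m + 1) stop("sequence too short for ApEn (need length > m+1)");
  if (r <= 0) stop("tolerance r must be positive");
  const double* x = REAL(xv);

  double phi[2];
  for (int level = 0; level < 2; ++level) {
    const int mm = m + level;
    const int n_tpl = N - mm + 1;
    std::vector<int> cnt(n_tpl, 1); // self-match
    for (int i = 0; i < n_tpl; ++i)
      for (int j = i + 1; j < n_tpl; ++j)
        if (cheb_within(x, i, j, mm, r)) { ++cnt[i]; ++cnt[j]; }
    double s = 0.0;
    for (int i = 0; i < n_tpl; ++i)
      s += std::log((double)cnt[i] / (double)n_tpl);
    phi[level] = s / n_tpl;
  }
  return phi[0] - phi[1];
}

// Sample entropy core: -ln(A/B) over the N-m template pairs (i<j),
// self-matches excluded. A = 0 with B > 0 gives +Inf; B = 0 gives NaN
// (the exported wrapper turns that into an error, the batch extractor
// maps both non-finite cases to a cap).
static double sampen_core(const double* x, int N, int m, double r) {
  const int n_tpl = N - m; // templates of length m and m+1 both indexed 0..n_tpl-1
  long long A = 0, B = 0;
  for (int i = 0; i < n_tpl; ++i)
    for (int j = i + 1; j < n_tpl; ++j)
      if (cheb_within(x, i, j, m, r)) {
        ++B;
        if (std::fabs(x[i + m] - x[j + m]) <= r) ++A;
      }
  if (B == 0) return R_NaN;
  if (A == 0) return R_PosInf;
  return -std::log((double)A / (double)B);
}

// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector xv, int m, double r) {
  const int N = xv.size();
  if (N <= m + 1) stop("sequence too short for SampEn (need length > m+1)");
  if (r <= 0) stop("tolerance r must be positive");
  double v = sampen_core(REAL(xv), N, m, r);
  if (ISNAN(v)) stop("sample entropy undefined: no template matches at length m");
  return v;
}

// Chen's fuzzy entropy: baseline-removed templates, similarity
// exp(-(d/r)^n) with Chebyshev d; ln(phi^m) - ln(phi^{m+1}) with phi the
// mean over ordered pairs i != j of the N-m templates at each length.
// [[Rcpp::export(name = ".fuzzen_cpp")]]
double fuzzen_cpp(NumericVector xv, int m, double r, double n) {
  const int N = xv.size();
  if (N <= m + 1) stop("sequence too short for FuzzEn (need length > m+1)");
  if (r <= 0) stop("tolerance r must be positive");
  if (n <= 0) stop("fuzzy exponent n must be positive");
  const double* x = REAL(xv);
  const int n_tpl = N - m;
  const bool sq = (n == 2.0);

  double phi[2];
  for (int level = 0; level < 2; ++level) {
    const int mm = m + level;
    // mean-subtracted templates, contiguous storage
    std::vector<double> T((size_t)n_tpl * mm);
    for (int i = 0; i < n_tpl; ++i) {
      double mu = 0.0;
      for (int k = 0; k < mm; ++k) mu += x[i + k];
      mu /= mm;
      for (int k = 0; k < mm; ++k) T[(size_t)i * mm + k] = x[i + k] - mu;
    }
    double s = 0.0;
    for (int i = 0; i < n_tpl; ++i) {
      const double* ti = &T[(size_t)i * mm];
      for (int j = i + 1; j < n_tpl; ++j) {
        const double* tj = &T[(size_t)j * mm];
        double d = 0.0;
        for (int k = 0; k < mm; ++k) {
          double a = std::fabs(ti[k] - tj[k]);
          if (a > d) d = a;
        }
        double u = d / r;
        s += sq ? std::exp(-u * u) : std::exp(-std::pow(u, n));
      }
    }
    // mean over ordered pairs i != j equals sum over unordered pairs * 2 /
    // (n_tpl * (n_tpl - 1))
    phi[level] = 2.0 * s / ((double)n_tpl * (double)(n_tpl - 1));
  }
  if (phi[0] <= 0 || phi[1] <= 0)
    stop("fuzzy entropy undefined: zero mean similarity");
  return std::log(phi[0]) - std::log(phi[1]);
}

// Ordinal pattern codes for permutation entropy. Ties are broken by order
// of occurrence (the earlier index gets the lower rank), matching
// rank(ties.method = "first"). Patterns are encoded in factorial base.
// [[Rcpp::export(name = ".pe_cpp")]]
double pe_cpp(NumericVector xv, int order, int delay, bool normalize) {
  const int N = xv.size();
  if (order < 2) stop("order must be >= 2");
  if (delay < 1) stop("delay must be >= 1");
  const int span = (order - 1) * delay;
  const int n_pat = N - span;
  if (n_pat < 1) stop("sequence too short for the requested order/delay");
  const double* x = REAL(xv);

  std::map<long long, long long> counts;
  std::vector<int> rk(order);
  for (int t = 0; t < n_pat; ++t) {
    // rank of each element among the order-tuple, ties to earlier index
    for (int a = 0; a < order; ++a) {
      int r = 0;
      double xa = x[t + a * delay];
      for (int b = 0; b < order; ++b) {
        double xb = x[t + b * delay];
        if (xb < xa || (xb == xa && b < a)) ++r;
      }
      rk[a] = r;
    }
    long long code = 0;
    for (int a = 0; a < order; ++a) code = code * order + rk[a];
    ++counts[code];
  }
  double H = 0.0;
  for (auto& kv : counts) {
    double p = (double)kv.second / (double)n_pat;
    H -= p * std::log(p);
  }
  if (normalize) {
    double lf = 0.0;
    for (int k = 2; k <= order; ++k) lf += std::log((double)k);
    H /= lf;
  }
  return H;
}

// Lempel-Ziv 76 phrase count of a binary sequence by exhaustive-history
// parsing (Kaspar-Schuster scan). Input is 0/1 integers.
// [[Rcpp::export(name = ".lz76_cpp")]]
int lz76_cpp(IntegerVector s) {
  const int n = s.size();
  if (n < 1) stop("empty sequence");
  if (n == 1) return 1;
  int c = 1, l = 1, i = 0, k = 1, k_max = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > k_max) k_max = k;
      ++i;
      if (i == l) {
        ++c;
        l += k_max;
        if (l + 1 > n) break;
        i = 0; k = 1; k_max = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}

// All five measures for every channel of an epoch matrix
// (channels x samples). r is r_frac * per-channel SD; SampEn's +Inf
// sentinel is mapped to sampen_cap so downstream matrices stay finite.
// Column order: ApEn, SampEn, PE, FuzzEn, KC.
// [[Rcpp::export(name = ".features_cpp")]]
NumericMatrix features_cpp(NumericMatrix ep, int m, double r_frac,
                           int pe_order, int pe_delay, bool pe_normalize,
                           double fuzz_power, bool kc_normalize,
                           double sampen_cap) {
  const int C = ep.nrow(), N = ep.ncol();
  NumericMatrix out(C, 5);
  std::vector<double> ch(N);
  IntegerVector bin(N);
  for (int c = 0; c < C; ++c) {
    for (int t = 0; t < N; ++t) ch[t] = ep(c, t);
    NumericVector xv(ch.begin(), ch.end());
    // sample SD (denominator n-1)
    double mu = 0.0;
    for (int t = 0; t < N; ++t) mu += ch[t];
    mu /= N;
    double ss = 0.0;
    for (int t = 0; t < N; ++t) ss += (ch[t] - mu) * (ch[t] - mu);
    double sd = std::sqrt(ss / (N - 1));
    double r = r_frac * sd;
    if (r <= 0) r = r_frac; // constant channel: degenerate but defined

    bool constant = (sd == 0.0);
    if (constant) {
      out(c, 0) = 0.0; out(c, 1) = 0.0; out(c, 3) = 0.0;
    } else {
      out(c, 0) = apen_cpp(xv, m, r);
      double se = sampen_core(REAL(xv), N, m, r);
      out(c, 1) = R_finite(se) ? se : sampen_cap;
      out(c, 3) = fuzzen_cpp(xv, m, r, fuzz_power);
    }
    out(c, 2) = pe_cpp(xv, pe_order, pe_delay, pe_normalize);
    // median binarisation for LZ76
    std::vector<double> srt(ch);
    std::nth_element(srt.begin(), srt.begin() + N / 2, srt.end());
    double med;
    if (N % 2 == 1) med = srt[N / 2];
    else {
      double hi = srt[N / 2];
      std::nth_element(srt.begin(), srt.begin() + N / 2 - 1, srt.end());
      med = 0.5 * (srt[N / 2 - 1] + hi);
    }
    for (int t = 0; t < N; ++t) bin[t] = ch[t] > med ? 1 : 0;
    int phr = lz76_cpp(bin);
    out(c, 4) = kc_normalize ? phr * std::log2((double)N) / (double)N
                             : (double)phr;
  }
  return out;
}
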