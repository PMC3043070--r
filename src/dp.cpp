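#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Exact p-value of the minimum-hypergeometric (mHG) statistic.
//
// Model: a binary label vector with B ones among N positions, all C(N,B)
// arrangements equiprobable.  The statistic is the minimum over prefix
// lengths n of the hypergeometric tail HGT(b_n; N, B, n).  The p-value
// P(mHG <= s) is computed by a dynamic program over the (n, b) lattice:
// paths are absorbed the first time they enter a cell whose tail is <= s,
// and the absorbed probability mass is accumulated directly, so p-values
// far below machine epsilon are summed rather than obtained as 1 minus a
// survival probability.
//
// Within a row (fixed prefix length m) the tail HGT(b) decreases in b, so
// the rejection region is the contiguous block b >= b_crit.  b_crit is
// located by walking the hypergeometric pmf downward from b = min(m, B)
// with the ratio recurrence (one log/exp per row, multiplications per
// cell), under a running scale factor so that tails far outside double
// range are still compared correctly.  `rel_tol` guards against last-ulp
// disagreement with the caller's phyper-based score (cells whose tail
// equals s must count as attaining it).
// The score is passed in log space (log_s = log of the observed mHG score)
// so that scores far below double range remain exact.
// [[Rcpp::export]]
double mhg_pvalue_cpp(double log_s, int N, int B, double rel_tol = 1e-9) {
  if (N < 1) stop("N must be >= 1");
  if (B < 0 || B > N) stop("B must lie in [0, N]");
  if (ISNAN(log_s) || log_s > 0.0) stop("log_s must be <= 0");
  if (B == 0) return 1.0;
  double log_thresh = log_s + std::log1p(rel_tol);
  if (log_thresh >= 0.0) return 1.0;

  // log-factorial table: lchoose(n, k) = lf[n] - lf[k] - lf[n - k]
  std::vector<double> lf(N + 1, 0.0);
  for (int i = 1; i <= N; ++i) lf[i] = lf[i - 1] + std::log((double)i);
  const int NB = N - B;
  const double RESCALE = 1e-280, LOG_RESCALE = 280.0 * std::log(10.0);

  std::vector<double> cur(B + 1, 0.0), nxt(B + 1, 0.0);
  cur[0] = 1.0;
  double absorbed = 0.0;
  for (int n = 0; n < N; ++n) {
    std::fill(nxt.begin(), nxt.end(), 0.0);
    int bhi = std::min(n, B);
    double denom = (double)(N - n);
    for (int b = 0; b <= bhi; ++b) {
      double w = cur[b];
      if (w == 0.0) continue;
      double p1 = (double)(B - b) / denom;
      if (B - b > 0) nxt[b + 1] += w * p1;
      double p0 = 1.0 - p1;
      if (p0 > 0.0) nxt[b] += w * p0;
    }
    int m = n + 1;
    int bmax = std::min(m, B);
    int blo = std::max(0, m - NB);
    // locate b_crit = smallest b with HGT(b; N, B, m) <= thresh
    double shift = lf[B] - lf[bmax] - lf[B - bmax] +
                   lf[NB] - lf[m - bmax] - lf[NB - (m - bmax)] -
                   (lf[N] - lf[m] - lf[N - m]);
    double pmf_s = 1.0, tail_s = 1.0;
    double le = log_thresh - shift;
    double thresh_s = (le > 700.0) ? R_PosInf : std::exp(le);
    int b_crit = bmax + 1;
    for (int b = bmax; b >= blo; --b) {
      if (b < bmax) {
        double ratio = ((double)(b + 1) * (double)(NB - m + b + 1)) /
                       ((double)(B - b) * (double)(m - b));
        pmf_s *= ratio;
        tail_s += pmf_s;
        if (pmf_s > 1e280) {
          pmf_s *= RESCALE; tail_s *= RESCALE; shift += LOG_RESCALE;
          le = log_thresh - shift;
          thresh_s = (le > 700.0) ? R_PosInf : std::exp(le);
        }
      }
      if (tail_s <= thresh_s) b_crit = b; else break;
    }
    if (b_crit <= bmax) {
      for (int b = std::max(blo, b_crit); b <= bmax; ++b) {
        absorbed += nxt[b];
        nxt[b] = 0.0;
      }
    }
    std::swap(cur, nxt);
    if (b_crit <= blo) break;  // whole row absorbed: no surviving mass
  }
  if (absorbed < 0.0) absorbed = 0.0;
  if (absorbed > 1.0) absorbed = 1.0;
  return absorbed;
}

// Exact cumulative null distribution of the TNoM statistic.
//
// A label arrangement maps to a walk e_t = t + B - 2*b_t (b_t = ones among
// the first t positions): e_0 = B, e_N = N - B, a one steps down, a zero
// steps up.  The best threshold classifier misclassifies
// k = min(min_t e_t, N - max_t e_t) samples, so TNoM <= k iff the walk ever
// leaves the open band (k, N - k).  The DP runs in probability space with
// the exchangeable-urn transition P(next is a one) = (B - b)/(N - t) and
// accumulates the absorbed (band-exit) mass directly, so p-values far below
// machine epsilon are summed rather than obtained as 1 minus a survival
// probability.
//
// Returns the cumulative probabilities for k = 0, ..., min(n1, n0).
// [[Rcpp::export]]
NumericVector tnom_null_cpp(int n1, int n0) {
  if (n1 < 1 || n0 < 1) stop("both class sizes must be >= 1");
  int N = n1 + n0, B = n1;
  int kmax = std::min(n1, n0);
  NumericVector cum(kmax + 1);
  for (int k = 0; k <= kmax; ++k) {
    if (B <= k || (N - B) <= k) { cum[k] = 1.0; continue; }
    int lo = k + 1, hi = N - k - 1;
    std::vector<double> f(B + 1, 0.0), g(B + 1, 0.0);
    f[0] = 1.0;  // e_0 = B, inside the band by the guard above
    double absorbed = 0.0;
    for (int t = 0; t < N; ++t) {
      std::fill(g.begin(), g.end(), 0.0);
      int bhiT = std::min(t, B);
      double denom = (double)(N - t);
      for (int b = 0; b <= bhiT; ++b) {
        double w = f[b];
        if (w == 0.0) continue;
        double p1 = (double)(B - b) / denom;
        if (p1 > 0.0) {  // take a one: e decreases
          int e = (t + 1) + B - 2 * (b + 1);
          if (e >= lo && e <= hi) g[b + 1] += w * p1;
          else absorbed += w * p1;
        }
        double p0 = 1.0 - p1;
        if (p0 > 0.0) {  // take a zero: e increases
          int e = (t + 1) + B - 2 * b;
          if (e >= lo && e <= hi) g[b] += w * p0;
          else absorbed += w * p0;
        }
      }
      std::swap(f, g);
    }
    if (absorbed < 0.0) absorbed = 0.0;
    if (absorbed > 1.0) absorbed = 1.0;
    cum[k] = absorbed;
  }
  return cum;
}
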