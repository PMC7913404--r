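// Hot loops behind the R API: fused inverse-logit reductions over
// posterior-draw x subject grids, the Bernoulli log-likelihood, and the
// greedy nearest-neighbour matching scan. All orchestration, linear algebra
// and model logic stay in R.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <cstdint>
using namespace Rcpp;

// exp(x) by range reduction exp(x) = 2^k exp(r), |r| <= ln(2)/2, with a
// degree-10 Taylor kernel (relative error ~2e-13). The system libm's exp is
// the dominant cost of the draw x subject reductions on some platforms;
// this keeps the kernels arithmetic-bound.
static inline double fast_exp(double x) {
  if (x > 709.0) return R_PosInf;
  if (x < -745.0) return 0.0;
  const double log2e = 1.4426950408889634074;
  const double ln2hi = 6.93147180369123816490e-01;
  const double ln2lo = 1.90821492927058770002e-10;
  const double kd = std::nearbyint(x * log2e);
  const double r = (x - kd * ln2hi) - kd * ln2lo;
  double p = 1.0 / 3628800.0;
  p = p * r + 1.0 / 362880.0;
  p = p * r + 1.0 / 40320.0;
  p = p * r + 1.0 / 5040.0;
  p = p * r + 1.0 / 720.0;
  p = p * r + 1.0 / 120.0;
  p = p * r + 1.0 / 24.0;
  p = p * r + 1.0 / 6.0;
  p = p * r + 0.5;
  p = p * r + 1.0;
  p = p * r + 1.0;
  // scale by 2^k via exponent-field arithmetic (k is within range after
  // the clamps above guarantee |k| < 1075)
  const int64_t k = static_cast<int64_t>(kd);
  if (k <= -1022) {  // subnormal range: fall back to ldexp
    return std::ldexp(p, static_cast<int>(k));
  }
  uint64_t bits;
  std::memcpy(&bits, &p, 8);
  bits += static_cast<uint64_t>(k) << 52;
  std::memcpy(&p, &bits, 8);
  return p;
}

static inline double expit_d(double x) { return 1.0 / (1.0 + fast_exp(-x)); }

// Vectorized inverse logit using the fast exp kernel.
// [[Rcpp::export]]
NumericVector cpp_expit(const NumericVector& x) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = expit_d(x[i]);
  return out;
}

// -sum(log(1 + exp(sgn * eta))): Bernoulli log-likelihood with sgn = 1 - 2y.
// [[Rcpp::export]]
double cpp_bernoulli_loglik(const NumericVector& eta, const NumericVector& sgn) {
  const R_xlen_t n = eta.size();
  double acc = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double t = sgn[i] * eta[i];
    acc += (t > 0.0 ? t : 0.0) + std::log1p(fast_exp(-std::fabs(t)));
  }
  return -acc;
}

// Posterior-mean probabilities per subject: e_i = mean_s expit(F_s.x_i + phi).
// F: draws x p fixed-effect draws (first column multiplies X's first column,
// conventionally the intercept). X: subjects x p. PHI: draws x n_regions
// county-effect draws (0 columns for a non-spatial model). county: 1-based
// region index per subject.
// [[Rcpp::export]]
NumericVector cpp_mean_expit(const NumericMatrix& F, const NumericMatrix& X,
                             const NumericMatrix& PHI,
                             const IntegerVector& county) {
  const int S = F.nrow(), p = F.ncol(), n = X.nrow();
  const bool spatial = PHI.ncol() > 0;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    const int c = spatial ? county[i] - 1 : 0;
    for (int s = 0; s < S; ++s) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += F(s, j) * X(i, j);
      if (spatial) eta += PHI(s, c);
      acc += expit_d(eta);
    }
    out[i] = acc / S;
  }
  return out;
}

// Per-draw standardized risk differences:
// delta_s = mean_i [ expit(eta_si + bz_s) - expit(eta_si) ], with eta the
// draw's linear predictor at exposure 0 and bz the draw's exposure
// coefficient. Arguments as in cpp_mean_expit; X0 has the exposure column
// set to zero.
// [[Rcpp::export]]
NumericVector cpp_srd_delta(const NumericMatrix& F, const NumericMatrix& X0,
                            const NumericMatrix& PHI,
                            const IntegerVector& county,
                            const NumericVector& bz) {
  const int S = F.nrow(), p = F.ncol(), n = X0.nrow();
  const bool spatial = PHI.ncol() > 0;
  NumericVector acc(S);
  for (int i = 0; i < n; ++i) {
    const int c = spatial ? county[i] - 1 : 0;
    for (int s = 0; s < S; ++s) {
      double eta = 0.0;
      for (int j = 0; j < p; ++j) eta += F(s, j) * X0(i, j);
      if (spatial) eta += PHI(s, c);
      acc[s] += expit_d(eta + bz[s]) - expit_d(eta);
    }
  }
  for (int s = 0; s < S; ++s) acc[s] /= n;
  return acc;
}

// Greedy nearest-neighbour caliper matching without replacement on sorted
// control logits. sl: sorted control logits; srt: original (1-based) control
// index per sorted position; tl: treated logits; pos: findInterval(tl, sl)
// (1-based, 0 = before first); proc: 1-based processing order of treated.
// Ties between equally-near available controls break toward the smallest
// original control index. Returns the matched sorted position per treated
// (0 = unmatched).
// [[Rcpp::export]]
IntegerVector cpp_greedy_match(const NumericVector& sl,
                               const IntegerVector& srt,
                               const NumericVector& tl,
                               const IntegerVector& pos,
                               const IntegerVector& proc, double caliper) {
  const int m = sl.size(), nt = tl.size();
  IntegerVector mt(nt);
  std::vector<bool> alive(m + 2, true);
  // jump pointers with path compression; positions are 1..m, 0 and m+1 are
  // sentinels
  std::vector<int> rightp(m + 2), leftp(m + 2);
  for (int i = 0; i <= m + 1; ++i) { rightp[i] = i; leftp[i] = i; }
  int n_alive = m;

  // first alive position >= i (or m+1)
  auto find_right = [&](int i) {
    int r = i;
    while (r <= m && !alive[r]) r = (rightp[r] > r ? rightp[r] : r + 1);
    for (int j = i; j < r; ) { int nx = (rightp[j] > j ? rightp[j] : j + 1); rightp[j] = r; j = nx; }
    return r;
  };
  // last alive position <= i (or 0)
  auto find_left = [&](int i) {
    int l = i;
    while (l >= 1 && !alive[l]) l = (leftp[l] < l ? leftp[l] : l - 1);
    for (int j = i; j > l; ) { int pv = (leftp[j] < j ? leftp[j] : j - 1); leftp[j] = l; j = pv; }
    return l;
  };

  for (int k0 = 0; k0 < nt; ++k0) {
    if (n_alive == 0) break;
    const int k = proc[k0] - 1;
    const double x = tl[k];
    const int p0 = pos[k];
    const int l = (p0 >= 1) ? find_left(p0) : 0;
    const int r = find_right(p0 + 1);
    const double dl = (l >= 1) ? x - sl[l - 1] : R_PosInf;
    const double dr = (r <= m) ? sl[r - 1] - x : R_PosInf;
    const double d = dl < dr ? dl : dr;
    if (!(d <= caliper)) continue;
    // collect equally-near alive candidates (runs of equal logits), pick
    // the smallest original control index
    int pick = 0, best_idx = m + 1;
    auto scan_run = [&](int centre) {
      int lo = centre, hi = centre;
      while (lo > 1 && sl[lo - 2] == sl[centre - 1]) --lo;
      while (hi < m && sl[hi] == sl[centre - 1]) ++hi;
      for (int q = lo; q <= hi; ++q) {
        if (alive[q] && srt[q - 1] < best_idx) { best_idx = srt[q - 1]; pick = q; }
      }
    };
    if (dl == d) scan_run(l);
    if (dr == d && !(dl == d && sl[l - 1] == sl[r - 1])) scan_run(r);
    mt[k] = pick;
    alive[pick] = false;
    --n_alive;
    rightp[pick] = pick + 1;
    leftp[pick] = pick - 1;
  }
  return mt;
}
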