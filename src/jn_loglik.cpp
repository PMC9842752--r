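// Pruning likelihood for the jump-normal (pulsed Levy) trait model.
//
// Displacement over a branch of length t is N(0, sigma2 * t) convolved with
// a Poisson(lambda * t) number of N(0, delta2) jumps. Conditional tip
// likelihoods are finite normal mixtures; per branch the Poisson count is
// truncated at the smallest K with tail mass < tailTol, node products are
// taken component-wise, tiny-weight components are dropped and the mixture
// is merged down to <= cap components by moment matching.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <numeric>
#include <vector>
using namespace Rcpp;

namespace {

struct Mix {
  std::vector<double> w, mu, v;
  size_t size() const { return w.size(); }
  void push(double W, double M, double V) {
    w.push_back(W); mu.push_back(M); v.push_back(V);
  }
};

inline double dnorm0(double x, double m, double s2) {
  if (s2 < 1e-300) s2 = 1e-300;
  double z = x - m;
  return std::exp(-0.5 * z * z / s2) / std::sqrt(2.0 * M_PI * s2);
}

// Indices sorted by decreasing weight.
std::vector<size_t> byWeightDesc(const std::vector<double> &w) {
  std::vector<size_t> ord(w.size());
  std::iota(ord.begin(), ord.end(), (size_t)0);
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return w[a] > w[b]; });
  return ord;
}

// Moment-match two components into one.
inline void mergePair(double w1, double m1, double v1, double w2, double m2,
                      double v2, double &W, double &M, double &V) {
  W = w1 + w2;
  M = (w1 * m1 + w2 * m2) / W;
  V = (w1 * (v1 + m1 * m1) + w2 * (v2 + m2 * m2)) / W - M * M;
  if (V < 0) V = 0;
}

// Runnalls-style scalar merge cost: expected likelihood-shape loss of
// replacing two components by their moment-matched merge.
inline double mergeCost(double w1, double m1, double v1, double w2,
                        double m2, double v2) {
  double W, M, V;
  mergePair(w1, m1, v1, w2, m2, v2, W, M, V);
  double lv1 = std::log(std::max(v1, 1e-12));
  double lv2 = std::log(std::max(v2, 1e-12));
  double lvm = std::log(std::max(V, 1e-12));
  return 0.5 * (W * lvm - w1 * lv1 - w2 * lv2);
}

// Drop components below pruneTol * max weight; if still above cap, sort by
// (variance, mean) and sweep-merge the cheapest adjacent pairs (components
// with near-identical shape merge at near-zero cost) until within cap.
void reduce(Mix &m, int cap, double pruneTol) {
  if (m.size() == 0) return;
  double wmax = *std::max_element(m.w.begin(), m.w.end());
  Mix keep;
  keep.w.reserve(m.size());
  for (size_t i = 0; i < m.size(); ++i) {
    if (m.w[i] >= pruneTol * wmax) keep.push(m.w[i], m.mu[i], m.v[i]);
  }
  while ((int)keep.size() > cap) {
    size_t n = keep.size();
    std::vector<size_t> ord(n);
    std::iota(ord.begin(), ord.end(), (size_t)0);
    std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
      if (keep.v[a] != keep.v[b]) return keep.v[a] < keep.v[b];
      return keep.mu[a] < keep.mu[b];
    });
    std::vector<double> cost(n - 1);
    for (size_t k = 0; k + 1 < n; ++k) {
      size_t i = ord[k], j = ord[k + 1];
      cost[k] = mergeCost(keep.w[i], keep.mu[i], keep.v[i], keep.w[j],
                          keep.mu[j], keep.v[j]);
    }
    size_t need = n - cap;
    std::vector<double> sortedCost(cost);
    std::nth_element(sortedCost.begin(), sortedCost.begin() + need - 1,
                     sortedCost.end());
    double thr = sortedCost[need - 1];
    // chain-merge pass: absorb runs of cheap neighbours into one component
    Mix merged;
    merged.w.reserve(cap + need);
    double W = keep.w[ord[0]], M = keep.mu[ord[0]], V = keep.v[ord[0]];
    for (size_t k = 1; k < n; ++k) {
      size_t j = ord[k];
      if (mergeCost(W, M, V, keep.w[j], keep.mu[j], keep.v[j]) <= thr) {
        double W2, M2, V2;
        mergePair(W, M, V, keep.w[j], keep.mu[j], keep.v[j], W2, M2, V2);
        W = W2; M = M2; V = V2;
      } else {
        merged.push(W, M, V);
        W = keep.w[j]; M = keep.mu[j]; V = keep.v[j];
      }
    }
    merged.push(W, M, V);
    if (merged.size() == keep.size()) break;  // no progress; give up
    keep = merged;
  }
  m = keep;
}

}  // namespace

namespace {

// Returns the root message mixture; logScale accumulates the rescaling
// factors so that likelihood(a) = sum_i w_i N(a; mu_i, v_i) * exp(logScale).
bool rootMixture(const IntegerMatrix &edge, const NumericVector &edgeLen,
                 const NumericVector &tipVals, int nTip, int nNodeTotal,
                 double sigma2, double lambda, double delta2, double tailTol,
                 double pruneTol, int cap, Mix &out, double &logScale) {
  std::vector<Mix> msg(nNodeTotal + 1);
  std::vector<bool> has(nNodeTotal + 1, false);
  logScale = 0.0;

  for (int i = 1; i <= nTip; ++i) {
    msg[i].push(1.0, tipVals[i - 1], 0.0);
    has[i] = true;
  }

  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0), ch = edge(e, 1);
    double t = edgeLen[e];
    double lt = lambda * t;

    // Poisson truncation for this branch. For large intensities the jump
    // sum is effectively Gaussian (CLT), so the branch transition is
    // collapsed to its moment-matched normal: one component with variance
    // sigma2 t + lambda t delta2.
    int K = 0;
    bool collapse = lt > 15.0;
    if (lt > 0 && !collapse) {
      double term = std::exp(-lt), cum = term;
      while (1.0 - cum >= tailTol) {
        ++K;
        term *= lt / K;
        cum += term;
        if (K > 10000) stop("jump-count truncation exceeded 10000 terms");
      }
    }
    std::vector<double> pj(K + 1);
    if (collapse) {
      pj[0] = 1.0;
    } else {
      double term = std::exp(-lt);
      for (int j = 0; j <= K; ++j) { pj[j] = term; term *= lt / (j + 1); }
    }

    // propagate the child's message along the branch (convolution adds
    // sigma2 * t + j * delta2 to each component's variance)
    Mix &cm = msg[ch];
    double wmax = *std::max_element(cm.w.begin(), cm.w.end());
    double thr = pruneTol * wmax * pj[0];
    Mix up;
    up.w.reserve(cm.size() * (K + 1));
    double base = sigma2 * t + (collapse ? lt * delta2 : 0.0);
    for (size_t i = 0; i < cm.size(); ++i) {
      for (int j = 0; j <= K; ++j) {
        double w = cm.w[i] * pj[j];
        if (w < thr) { if (pj[j] < pj[0]) break; else continue; }
        up.push(w, cm.mu[i], cm.v[i] + base + j * delta2);
      }
    }
    reduce(up, cap, pruneTol);
    if (up.size() == 0) return false;

    if (!has[par]) {
      msg[par] = up;
      has[par] = true;
    } else {
      Mix &pm = msg[par];
      std::vector<size_t> oa = byWeightDesc(pm.w);
      std::vector<size_t> ob = byWeightDesc(up.w);
      double bw = pm.w[oa[0]] * up.w[ob[0]];
      double thr2 = pruneTol * bw;
      Mix prod;
      prod.w.reserve(std::min(pm.size() * up.size(), (size_t)65536));
      for (size_t ia = 0; ia < oa.size(); ++ia) {
        double w1 = pm.w[oa[ia]];
        if (w1 * up.w[ob[0]] < thr2) break;
        double mu1 = pm.mu[oa[ia]], v1 = pm.v[oa[ia]];
        for (size_t ib = 0; ib < ob.size(); ++ib) {
          double w12 = w1 * up.w[ob[ib]];
          if (w12 < thr2) break;
          double v2 = up.v[ob[ib]], mu2 = up.mu[ob[ib]];
          double s = v1 + v2;
          double w = w12 * dnorm0(mu1, mu2, s);
          if (w <= 0 || !std::isfinite(w)) continue;
          double vv = (s < 1e-300) ? 0.0 : (v1 * v2) / s;
          double mm = (s < 1e-300) ? mu1 : (mu1 * v2 + mu2 * v1) / s;
          prod.push(w, mm, vv);
        }
      }
      if (prod.size() == 0) return false;
      double mx = *std::max_element(prod.w.begin(), prod.w.end());
      for (double &w : prod.w) w /= mx;
      logScale += std::log(mx);
      reduce(prod, cap, pruneTol);
      msg[par] = prod;
    }
  }

  int root = nTip + 1;
  if (!has[root]) stop("root message missing; edge matrix not postorder?");
  out = msg[root];
  return true;
}

}  // namespace

// edge: postorder edge matrix (parent, child), 1-based ape numbering with
// root = nTip + 1; tipVals ordered by tip index 1..nTip.
// [[Rcpp::export]]
double jn_loglik_cpp(IntegerMatrix edge, NumericVector edgeLen,
                     NumericVector tipVals, int nTip, int nNodeTotal,
                     double sigma2, double lambda, double delta2,
                     double rootState, double tailTol = 1e-8,
                     double pruneTol = 1e-10, int cap = 256) {
  Mix rm;
  double logScale;
  if (!rootMixture(edge, edgeLen, tipVals, nTip, nNodeTotal, sigma2, lambda,
                   delta2, tailTol, pruneTol, cap, rm, logScale)) {
    return R_NegInf;
  }
  double lik = 0.0;
  for (size_t i = 0; i < rm.size(); ++i) {
    lik += rm.w[i] * dnorm0(rootState, rm.mu[i], rm.v[i]);
  }
  if (lik <= 0 || !std::isfinite(lik)) return R_NegInf;
  return std::log(lik) + logScale;
}

// Root-message mixture, for profiling the root state out of ML fits.
// [[Rcpp::export]]
List jn_root_mixture_cpp(IntegerMatrix edge, NumericVector edgeLen,
                         NumericVector tipVals, int nTip, int nNodeTotal,
                         double sigma2, double lambda, double delta2,
                         double tailTol = 1e-8, double pruneTol = 1e-10,
                         int cap = 256) {
  Mix rm;
  double logScale;
  bool ok = rootMixture(edge, edgeLen, tipVals, nTip, nNodeTotal, sigma2,
                        lambda, delta2, tailTol, pruneTol, cap, rm, logScale);
  return List::create(_["ok"] = ok, _["w"] = wrap(rm.w),
                      _["mu"] = wrap(rm.mu), _["v"] = wrap(rm.v),
                      _["logScale"] = logScale);
}
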