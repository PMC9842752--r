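// Banded fitting alignment of a read against a gene model: global in the
// read, local in the model (model flanks are free). Scoring: match +1,
// mismatch -1, gap open -2, gap extend -1 (affine: opening a gap costs
// -2 for its first base, -1 for each extension). The band of half-width
// `band` is centred on the best ungapped diagonal, found by a full scan.
//
// Returns, per read base, the 1-based model position it aligns to (0 for
// an insertion relative to the model), plus the score and match count.

#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>
using namespace Rcpp;

namespace {
const double NEG = -1e18;
}

// [[Rcpp::export]]
List banded_fit_align_cpp(std::string read, std::string model,
                          int band = 16) {
  int n = read.size(), m = model.size();
  if (n == 0 || m == 0 || n > m) {
    return List::create(_["ok"] = false);
  }
  // best ungapped diagonal: offset d aligns read[i] to model[i + d]
  int bestD = 0, bestMatches = -1;
  for (int d = 0; d + n <= m; ++d) {
    int matches = 0;
    for (int i = 0; i < n; ++i) {
      if (read[i] == model[i + d]) ++matches;
    }
    if (matches > bestMatches) { bestMatches = matches; bestD = d; }
  }
  int lo = std::max(0, bestD - band), hi = std::min(m, bestD + n + band);
  int W = hi - lo;  // model window width

  // DP over read rows i = 0..n and model window columns j = 0..W
  // (model position lo + j). M: read[i] aligned to model col j.
  // X: gap in model (insertion in read). Y: gap in read (model base
  // consumed inside the alignment).
  std::vector<double> M((n + 1) * (W + 1), NEG), X = M, Y = M;
  std::vector<signed char> bM((n + 1) * (W + 1), 0), bX = bM, bY = bM;
  const double gapOpen = -2, gapExt = -1;
  auto at = [W](int i, int j) { return i * (W + 1) + j; };
  for (int j = 0; j <= W; ++j) M[at(0, j)] = 0;  // free model prefix
  for (int i = 1; i <= n; ++i) {
    // X: read base i unaligned (gap in model)
    for (int j = 0; j <= W; ++j) {
      double fromM = M[at(i - 1, j)] + gapOpen;
      double fromX = X[at(i - 1, j)] + gapExt;
      if (fromM >= fromX) { X[at(i, j)] = fromM; bX[at(i, j)] = 0; }
      else { X[at(i, j)] = fromX; bX[at(i, j)] = 1; }
      M[at(i, j)] = NEG; Y[at(i, j)] = NEG;
    }
    for (int j = 1; j <= W; ++j) {
      double s = (read[i - 1] == model[lo + j - 1]) ? 1.0 : -1.0;
      double best = M[at(i - 1, j - 1)];
      signed char bt = 0;
      if (X[at(i - 1, j - 1)] > best) { best = X[at(i - 1, j - 1)]; bt = 1; }
      if (Y[at(i - 1, j - 1)] > best) { best = Y[at(i - 1, j - 1)]; bt = 2; }
      if (best > NEG / 2) { M[at(i, j)] = best + s; bM[at(i, j)] = bt; }
      // Y: model base j consumed without a read base (deletion in read)
      double fromM = M[at(i, j - 1)] + gapOpen;
      double fromY = Y[at(i, j - 1)] + gapExt;
      if (fromM >= fromY) { Y[at(i, j)] = fromM; bY[at(i, j)] = 0; }
      else { Y[at(i, j)] = fromY; bY[at(i, j)] = 2; }
    }
  }
  // free model suffix: best over states at row n (Y at row n would mean a
  // trailing model deletion inside the alignment; allow ending in M or X)
  double best = NEG; int bj = 0; int bs = 0;
  for (int j = 0; j <= W; ++j) {
    if (M[at(n, j)] > best) { best = M[at(n, j)]; bj = j; bs = 0; }
    if (X[at(n, j)] > best) { best = X[at(n, j)]; bj = j; bs = 1; }
  }
  if (best <= NEG / 2) return List::create(_["ok"] = false);

  IntegerVector modelPos(n);
  int i = n, j = bj, s = bs, nmatch = 0;
  while (i > 0) {
    if (s == 0) {  // M
      modelPos[i - 1] = lo + j;  // 1-based model position
      if (read[i - 1] == model[lo + j - 1]) ++nmatch;
      s = bM[at(i, j)];
      --i; --j;
    } else if (s == 1) {  // X: insertion in read
      modelPos[i - 1] = 0;
      s = bX[at(i, j)];
      --i;
    } else {  // Y: model deletion
      s = bY[at(i, j)];
      --j;
    }
  }
  return List::create(_["ok"] = true, _["score"] = best,
                      _["nmatch"] = nmatch, _["modelPos"] = modelPos);
}
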