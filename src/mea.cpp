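// Nussinov-style maximum expected accuracy decoder over nested structures.
// wp(i,j): gain of pairing (i,j) (already includes the factor for the two
// positions and any weight overrides); -Inf where the pair is disallowed.
// wss(i): gain of leaving i unpaired; -Inf where i must pair.
// Deterministic tie-break: prefer unpaired, then the smallest left index.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double NEGINF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".mea_dp_cpp")]]
List mea_dp_cpp(NumericMatrix wp, NumericVector wss) {
  const int N = wss.size();
  std::vector<double> Mv((size_t)(N + 2) * (N + 2), 0.0);
  auto M = [&](int i, int j) -> double& {
    return Mv[(size_t)i * (N + 2) + j];
  };
  auto Mget = [&](int i, int j) -> double {
    if (i > j) return 0.0;
    return M(i, j);
  };
  for (int len = 1; len <= N; ++len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      double best = (wss[j - 1] == NEGINF) ? NEGINF
                                           : Mget(i, j - 1) + wss[j - 1];
      for (int k = i; k <= j - 1; ++k) {
        double w = wp(k - 1, j - 1);
        if (w == NEGINF) continue;
        double left = Mget(i, k - 1), mid = Mget(k + 1, j - 1);
        if (left == NEGINF || mid == NEGINF) continue;
        double cand = left + w + mid;
        if (cand > best) best = cand;
      }
      M(i, j) = best;
    }
  }
  // traceback
  std::vector<int> pi, pj;
  std::vector<std::pair<int, int>> stack;
  stack.push_back({1, N});
  const double eps = 1e-12;
  while (!stack.empty()) {
    auto [i, j] = stack.back();
    stack.pop_back();
    if (i > j) continue;
    double target = Mget(i, j);
    if (target == NEGINF) stop("infeasible decoding constraints");
    if (wss[j - 1] != NEGINF &&
        std::abs(Mget(i, j - 1) + wss[j - 1] - target) <= eps) {
      stack.push_back({i, j - 1});
      continue;
    }
    bool found = false;
    for (int k = i; k <= j - 1 && !found; ++k) {
      double w = wp(k - 1, j - 1);
      if (w == NEGINF) continue;
      double left = Mget(i, k - 1), mid = Mget(k + 1, j - 1);
      if (left == NEGINF || mid == NEGINF) continue;
      if (std::abs(left + w + mid - target) <= eps) {
        pi.push_back(k);
        pj.push_back(j);
        stack.push_back({i, k - 1});
        stack.push_back({k + 1, j - 1});
        found = true;
      }
    }
    if (!found) stop("MEA traceback failed (numerical inconsistency)");
  }
  return List::create(_["score"] = Mget(1, N),
                      _["pairs_i"] = wrap(pi), _["pairs_j"] = wrap(pj));
}
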