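// Inside-outside for the lightweight structural SCFG
//   S -> LS | L ,  L -> s | dFd ,  F -> dFd | LS
// in log space.  Emissions arrive pre-computed (phylogenetic column
// likelihoods); constraint masks are already folded into them:
//   ws[i]    = log( p(L->s) * e_s(i) )   (0 for prior-free linker columns,
//              -Inf where the position must pair)
//   lep[i,j] = log e_p(i,j)              (-Inf where the pair is disallowed)
// Returns logZ and, optionally, posterior pair/single-stranded reliabilities.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double NEGINF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEGINF) return b;
  if (b == NEGINF) return a;
  double m = std::max(a, b);
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

struct LTab {
  int N;
  std::vector<double> v;
  LTab(int n) : N(n), v((size_t)n * n, NEGINF) {}
  double& operator()(int i, int j) { return v[(size_t)(i - 1) * N + (j - 1)]; }
  double at(int i, int j) const {
    if (i > j) return NEGINF;
    return v[(size_t)(i - 1) * N + (j - 1)];
  }
};

// [[Rcpp::export(name = ".scfg_io_cpp")]]
List scfg_io_cpp(NumericVector ws, NumericMatrix lep, NumericVector lq,
                 bool wantP) {
  const int N = ws.size();
  const double qSLS = lq["S->LS"], qSL = lq["S->L"];
  const double qLF = lq["L->dFd"], qFF = lq["F->dFd"], qFLS = lq["F->LS"];

  LTab S(N), L(N), F(N);
  std::vector<double> buf;
  buf.reserve(N + 2);
  auto lsebuf = [&]() -> double {
    double m = NEGINF;
    for (double x : buf) m = std::max(m, x);
    if (m == NEGINF) return NEGINF;
    double s = 0;
    for (double x : buf) s += std::exp(x - m);
    return m + std::log(s);
  };

  for (int len = 1; len <= N; ++len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      // L
      if (len == 1) {
        L(i, j) = ws[i - 1];
      } else {
        double pl = NEGINF;
        if (len >= 3 && lep(i - 1, j - 1) != NEGINF)
          pl = lep(i - 1, j - 1) + qLF + F.at(i + 1, j - 1);
        L(i, j) = pl;
      }
      // F (span >= 2)
      if (len >= 2) {
        double pf = NEGINF;
        if (len >= 3 && lep(i - 1, j - 1) != NEGINF)
          pf = lep(i - 1, j - 1) + qFF + F.at(i + 1, j - 1);
        buf.clear();
        for (int k = i; k <= j - 1; ++k) {
          double t = L.at(i, k) + S.at(k + 1, j);
          if (t != NEGINF) buf.push_back(t);
        }
        F(i, j) = lse2(pf, qFLS + lsebuf());
      }
      // S
      {
        double t1 = qSL + L.at(i, j);
        buf.clear();
        for (int k = i; k <= j - 1; ++k) {
          double t = L.at(i, k) + S.at(k + 1, j);
          if (t != NEGINF) buf.push_back(t);
        }
        S(i, j) = lse2(t1, qSLS + lsebuf());
      }
    }
  }
  double logZ = S.at(1, N);

  NumericMatrix P(N, N);
  NumericVector Pss(N);
  if (wantP && logZ != NEGINF) {
    LTab bS(N), bL(N), bF(N);
    bS(1, N) = 0.0;
    for (int len = N; len >= 1; --len) {
      for (int i = 1; i + len - 1 <= N; ++i) {
        int j = i + len - 1;
        double bs = bS.at(i, j);
        if (bs != NEGINF) {
          bL(i, j) = lse2(bL.at(i, j), bs + qSL);
          for (int k = i; k <= j - 1; ++k) {
            double sr = S.at(k + 1, j), ll = L.at(i, k);
            if (sr != NEGINF)
              bL(i, k) = lse2(bL.at(i, k), bs + qSLS + sr);
            if (ll != NEGINF)
              bS(k + 1, j) = lse2(bS.at(k + 1, j), bs + qSLS + ll);
          }
        }
        double bf = bF.at(i, j);
        if (bf != NEGINF) {
          if (len >= 3 && lep(i - 1, j - 1) != NEGINF)
            bF(i + 1, j - 1) = lse2(bF.at(i + 1, j - 1),
                                    bf + qFF + lep(i - 1, j - 1));
          for (int k = i; k <= j - 1; ++k) {
            double sr = S.at(k + 1, j), ll = L.at(i, k);
            if (sr != NEGINF)
              bL(i, k) = lse2(bL.at(i, k), bf + qFLS + sr);
            if (ll != NEGINF)
              bS(k + 1, j) = lse2(bS.at(k + 1, j), bf + qFLS + ll);
          }
        }
        double bl = bL.at(i, j);
        if (bl != NEGINF && len >= 3 && lep(i - 1, j - 1) != NEGINF) {
          bF(i + 1, j - 1) = lse2(bF.at(i + 1, j - 1),
                                  bl + qLF + lep(i - 1, j - 1));
        }
      }
    }
    for (int i = 1; i <= N; ++i) {
      double x = ws[i - 1] + bL.at(i, i);
      Pss[i - 1] = (x == NEGINF) ? 0.0 : std::exp(x - logZ);
      for (int j = i + 2; j <= N; ++j) {
        if (lep(i - 1, j - 1) == NEGINF) continue;
        double inner = F.at(i + 1, j - 1);
        if (inner == NEGINF) continue;
        double w = lse2(bL.at(i, j) + qLF, bF.at(i, j) + qFF);
        if (w == NEGINF) continue;
        double p = std::exp(lep(i - 1, j - 1) + inner + w - logZ);
        P(i - 1, j - 1) = p;
        P(j - 1, i - 1) = p;
      }
    }
  }
  return List::create(_["logZ"] = logZ, _["P"] = P, _["Pss"] = Pss);
}
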