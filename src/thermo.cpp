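// Constrained partition function over nested RNA structures with a
// simplified nearest-neighbor energy model, including cofolding of two
// sequences across a linker ("cut") that cannot pair.  Loops that contain
// the cut are scored as exterior-like regions (no loop penalty); pairs
// spanning the cut are exempt from the hairpin minimum.  Optionally
// excludes isolated pairs (every helix must have length >= 2).
//
// Decomposition (weights are Boltzmann factors exp(-E/RT)):
//   Q(i,j)      exterior ensemble on [i..j] (no surrounding penalty)
//   Qstar(i,j)  pair (i,j) with non-stack content (hairpin / interior with
//               one branch != (i+1,j-1) / multiloop / linker-exterior)
//   Qb(i,j)     pair (i,j), any content          (standard mode)
//   Qh(i,j)     pair (i,j) starting a stack of >= 2 pairs (noLP mode)
//   M(i,j)      multiloop filling, >= 1 branch; M1(i,j) one branch at i
// Pair probabilities come from the mirrored outside pass.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Tab {
  int N;
  std::vector<double> v;
  Tab(int n) : N(n), v((size_t)n * n, 0.0) {}
  double& operator()(int i, int j) { return v[(size_t)(i - 1) * N + (j - 1)]; }
  double get(int i, int j) const {
    if (i > j) return 1.0;  // empty span sentinel for Q-like tables
    return v[(size_t)(i - 1) * N + (j - 1)];
  }
  double at(int i, int j) const {
    if (i > j) return 0.0;
    return v[(size_t)(i - 1) * N + (j - 1)];
  }
};

// [[Rcpp::export(name = ".thermo_dp_cpp")]]
List thermo_dp_cpp(IntegerVector seq, int cut, LogicalMatrix pair_ok,
                   LogicalVector can_ss, List pars, bool noLP, bool wantP) {
  const int N = seq.size();
  NumericMatrix stack6 = pars["stack"];
  const double ah = pars["hairpin_a"], bh = pars["hairpin_b"];
  const double ai = pars["interior_a"], bi = pars["interior_b"];
  const double am = pars["ml_a"], bm = pars["ml_b"], cm = pars["ml_c"];
  const double RT = pars["RT"];
  const int minhp = as<int>(pars["min_hairpin"]);

  auto pt = [&](int i, int j) -> int {  // 1-based; pair type 0..5 or -1
    int a = seq[i - 1], b = seq[j - 1];
    if (a == 1 && b == 4) return 0;  // AU
    if (a == 4 && b == 1) return 1;  // UA
    if (a == 3 && b == 2) return 2;  // GC
    if (a == 2 && b == 3) return 3;  // CG
    if (a == 3 && b == 4) return 4;  // GU
    if (a == 4 && b == 3) return 5;  // UG
    return -1;
  };
  auto ok = [&](int i, int j) -> bool {
    return pair_ok(i - 1, j - 1) && pt(i, j) >= 0;
  };
  auto ssok = [&](int i) -> bool { return can_ss[i - 1]; };
  auto spansCut = [&](int i, int j) -> bool {
    return cut > 0 && i <= cut && j > cut;
  };
  auto estk = [&](int i, int j) -> double {  // stack (i,j) on (i+1,j-1)
    return std::exp(-stack6(pt(i, j), pt(i + 1, j - 1)) / RT);
  };
  const double ebm1 = std::exp(-bm / RT), ecm = std::exp(-cm / RT);
  const double eam = std::exp(-am / RT);

  // allSS(i,j): every position in [i..j] may be unpaired (empty span: true)
  std::vector<std::vector<bool>> allSS(N + 2, std::vector<bool>(N + 2, true));
  for (int i = 1; i <= N; ++i) {
    bool acc = true;
    for (int j = i; j <= N; ++j) {
      acc = acc && ssok(j);
      allSS[i][j] = acc;
    }
  }
  auto sse = [&](int i, int j) -> double {  // all-unpaired multiloop weight
    if (i > j) return 1.0;
    return allSS[i][j] ? std::exp(-bm * (j - i + 1) / RT) : 0.0;
  };

  Tab Q(N), Qstar(N), QbE(N), M(N), M1(N);

  for (int len = 1; len <= N; ++len) {
    for (int i = 1; i + len - 1 <= N; ++i) {
      int j = i + len - 1;
      // ---- pair tables ----
      if (len >= 2 && ok(i, j)) {
        bool xc = spansCut(i, j);
        double qs = 0.0;
        if (!xc) {
          int u = j - i - 1;
          if (u >= minhp && allSS[i + 1][j - 1])
            qs += std::exp(-(ah + bh * u) / RT);
          for (int k = i + 1; k <= j - 2; ++k) {
            if (!allSS[i + 1][k - 1] && k > i + 1) break;
            if (!allSS[i + 1][k - 1]) continue;
            for (int l = k + 1; l <= j - 1; ++l) {
              if (k == i + 1 && l == j - 1) continue;
              if (!allSS[l + 1][j - 1]) continue;
              double qb = QbE.at(k, l);
              if (qb == 0.0) continue;
              qs += std::exp(-(ai + bi * ((k - i - 1) + (j - l - 1))) / RT) * qb;
            }
          }
          for (int k = i + 2; k <= j - 2; ++k)
            qs += eam * M.at(i + 1, k - 1) * M1.at(k, j - 1);
        } else {
          qs += Q.get(i + 1, cut) * Q.get(cut + 1, j - 1);
          for (int k = i + 1; k <= cut; ++k) {
            for (int l = cut + 1; l <= j - 1; ++l) {
              double qb = QbE.at(k, l);
              if (qb == 0.0) continue;
              if (!(k == i + 1 && l == j - 1) && allSS[i + 1][k - 1] &&
                  allSS[l + 1][j - 1]) {
                qs += std::exp(-(ai + bi * ((k - i - 1) + (j - l - 1))) / RT) * qb;
              }
              double Wl = sse(i + 1, k - 1) + M.at(i + 1, k - 1);
              double Wr = sse(l + 1, j - 1) + M.at(l + 1, j - 1);
              double corr = sse(i + 1, k - 1) * sse(l + 1, j - 1);
              qs += eam * ecm * qb * (Wl * Wr - corr);
            }
          }
        }
        Qstar(i, j) = qs;
        // a stack step is only valid when outer and inner agree on spanning
        // the cut: an outer pair spanning the cut with a side-local inner
        // pair has the cut in its loop (exterior-like, counted in EXT above)
        bool innerok = (j - 1 > i + 1) && ok(i + 1, j - 1) &&
                       (!xc || spansCut(i + 1, j - 1));
        if (!noLP) {
          QbE(i, j) = qs + (innerok ? estk(i, j) * QbE.at(i + 1, j - 1) : 0.0);
        } else {
          QbE(i, j) = innerok
                          ? estk(i, j) * (Qstar.at(i + 1, j - 1) + QbE.at(i + 1, j - 1))
                          : 0.0;
        }
      }
      // ---- multiloop tables (side-local spans only) ----
      if (!spansCut(i, j)) {
        double m1 = 0.0;
        for (int l = i + 1; l <= j; ++l) {
          double qb = QbE.at(i, l);
          if (qb != 0.0 && allSS[l + 1][j])
            m1 += qb * ecm * std::exp(-bm * (j - l) / RT);
        }
        M1(i, j) = m1;
        double mm = (len >= 2 && ssok(j)) ? ebm1 * M.at(i, j - 1) : 0.0;
        for (int k = i; k <= j - 1; ++k) {
          double qb = QbE.at(k, j);
          if (qb == 0.0) continue;
          double pre = (allSS[i][k - 1] ? std::exp(-bm * (k - i) / RT) : 0.0) +
                       M.at(i, k - 1);
          mm += pre * qb * ecm;
        }
        M(i, j) = mm;
      }
      // ---- exterior ----
      double q = ssok(j) ? Q.get(i, j - 1) : 0.0;
      for (int k = i; k <= j - 1; ++k) {
        double qb = QbE.at(k, j);
        if (qb != 0.0) q += Q.get(i, k - 1) * qb;
      }
      Q(i, j) = q;
    }
  }

  double Z = Q.get(1, N);
  if (!R_finite(Z))
    stop("partition function overflow; sequence too long for linear scaling");
  double logZ = (Z > 0) ? std::log(Z) : R_NegInf;

  NumericMatrix P(N, N);
  if (wantP && Z > 0) {
    Tab OQ(N), OM(N), OM1(N), ObE(N), Ostar(N);
    // empty-span outside entries are never read; Tab::at gives 0
    OQ(1, N) = 1.0;
    for (int len = N; len >= 1; --len) {
      // pass A: Q, M, M1 pushes
      for (int i = 1; i + len - 1 <= N; ++i) {
        int j = i + len - 1;
        double oq = OQ.at(i, j);
        if (oq != 0.0) {
          if (len >= 2 && ssok(j)) OQ(i, j - 1) += oq;
          for (int k = i; k <= j - 1; ++k) {
            double qb = QbE.at(k, j);
            if (qb != 0.0 && k > i) OQ(i, k - 1) += oq * qb;
            ObE(k, j) += oq * Q.get(i, k - 1);
          }
        }
        if (!spansCut(i, j)) {
          double om = OM.at(i, j);
          if (om != 0.0) {
            if (len >= 2 && ssok(j)) OM(i, j - 1) += om * ebm1;
            for (int k = i; k <= j - 1; ++k) {
              double qb = QbE.at(k, j);
              if (qb == 0.0) continue;
              double pre = (allSS[i][k - 1] ? std::exp(-bm * (k - i) / RT) : 0.0) +
                           M.at(i, k - 1);
              ObE(k, j) += om * pre * ecm;
              if (k > i) OM(i, k - 1) += om * qb * ecm;
            }
          }
          double om1 = OM1.at(i, j);
          if (om1 != 0.0) {
            for (int l = i + 1; l <= j; ++l) {
              if (allSS[l + 1][j])
                ObE(i, l) += om1 * ecm * std::exp(-bm * (j - l) / RT);
            }
          }
        }
      }
      // pass B: pair-table pushes
      for (int i = 1; i + len - 1 <= N; ++i) {
        int j = i + len - 1;
        if (len < 2 || !ok(i, j)) continue;
        bool xc = spansCut(i, j);
        double ob = ObE.at(i, j);
        bool innerok = (j - 1 > i + 1) && ok(i + 1, j - 1) &&
                       (!xc || spansCut(i + 1, j - 1));
        double os;  // outside of the Qstar item at (i,j)
        if (!noLP) {
          Ostar(i, j) += ob;
          if (innerok && ob != 0.0) ObE(i + 1, j - 1) += ob * estk(i, j);
          os = Ostar.at(i, j);
        } else {
          if (innerok && ob != 0.0) {
            Ostar(i + 1, j - 1) += ob * estk(i, j);
            ObE(i + 1, j - 1) += ob * estk(i, j);
          }
          os = Ostar.at(i, j);
        }
        if (os == 0.0) continue;
        if (!xc) {
          for (int k = i + 1; k <= j - 2; ++k) {
            if (!allSS[i + 1][k - 1]) continue;
            for (int l = k + 1; l <= j - 1; ++l) {
              if (k == i + 1 && l == j - 1) continue;
              if (!allSS[l + 1][j - 1]) continue;
              ObE(k, l) +=
                  os * std::exp(-(ai + bi * ((k - i - 1) + (j - l - 1))) / RT);
            }
          }
          for (int k = i + 2; k <= j - 2; ++k) {
            OM(i + 1, k - 1) += os * eam * M1.at(k, j - 1);
            OM1(k, j - 1) += os * eam * M.at(i + 1, k - 1);
          }
        } else {
          if (i + 1 <= cut) OQ(i + 1, cut) += os * Q.get(cut + 1, j - 1);
          if (cut + 1 <= j - 1) OQ(cut + 1, j - 1) += os * Q.get(i + 1, cut);
          for (int k = i + 1; k <= cut; ++k) {
            for (int l = cut + 1; l <= j - 1; ++l) {
              double qb = QbE.at(k, l);
              if (!(k == i + 1 && l == j - 1) && allSS[i + 1][k - 1] &&
                  allSS[l + 1][j - 1]) {
                ObE(k, l) +=
                    os * std::exp(-(ai + bi * ((k - i - 1) + (j - l - 1))) / RT);
              }
              double Wl = sse(i + 1, k - 1) + M.at(i + 1, k - 1);
              double Wr = sse(l + 1, j - 1) + M.at(l + 1, j - 1);
              double corr = sse(i + 1, k - 1) * sse(l + 1, j - 1);
              ObE(k, l) += os * eam * ecm * (Wl * Wr - corr);
              if (qb != 0.0) {
                if (i + 1 <= k - 1) OM(i + 1, k - 1) += os * eam * ecm * qb * Wr;
                if (l + 1 <= j - 1) OM(l + 1, j - 1) += os * eam * ecm * qb * Wl;
              }
            }
          }
        }
      }
    }
    for (int i = 1; i <= N; ++i) {
      for (int j = i + 1; j <= N; ++j) {
        if (!ok(i, j)) continue;
        double w;
        if (!noLP) {
          w = ObE.at(i, j) * QbE.at(i, j);
        } else {
          w = ObE.at(i, j) * QbE.at(i, j) + Ostar.at(i, j) * Qstar.at(i, j);
        }
        double p = w / Z;
        if (p < 0 && p > -1e-12) p = 0;
        P(i - 1, j - 1) = p;
        P(j - 1, i - 1) = p;
      }
    }
  }
  return List::create(_["logZ"] = logZ, _["P"] = P, _["Z_positive"] = (Z > 0));
}
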