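// Minimum-free-energy secondary structure folding by Zuker-style dynamic
// programming under a loop-based nearest-neighbour energy model:
//   - stacking energies for directly stacked pairs (6x6 by pair type),
//   - hairpin / bulge / internal loop penalties by unpaired size
//     (internal & bulge loops capped at `maxloop` unpaired nt; hairpins
//     extrapolated logarithmically beyond the table),
//   - affine multibranch loops (a + b per branch incl. closing + c per
//     unpaired nt), exterior bases free,
//   - allowed pairs AU/UA/GC/CG/GU/UG, minimum hairpin loop 3 nt,
//   - no dangles, coaxial stacks or terminal-pair penalties.
// The same model is evaluated structure-by-structure by the R enumeration
// reference (`fold_enumerate`), which this DP must reproduce exactly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = 1e9;

// base codes: A=0, C=1, G=2, U=3
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0; // AU
  if (a == 3 && b == 0) return 1; // UA
  if (a == 2 && b == 1) return 2; // GC
  if (a == 1 && b == 2) return 3; // CG
  if (a == 2 && b == 3) return 4; // GU
  if (a == 3 && b == 2) return 5; // UG
  return -1;
}

struct Params {
  std::vector<double> stack;   // 36, [p1*6+p2]
  std::vector<double> hairpin; // index 0 -> size 1 ... size 30
  double hp_ext;               // coefficient for sizes > 30
  std::vector<double> bulge;
  std::vector<double> internal_;
  double Ma, Mb, Mc;
  int maxloop;
  bool wobble;                 // allow GU/UG pairs

  double hairpinE(int n) const {
    if (n < 3) return INF;
    if (n <= 30) return hairpin[n - 1];
    return hairpin[29] + hp_ext * std::log((double)n / 30.0);
  }
  double loopE(int n1, int n2, int pt_out, int pt_in) const {
    int tot = n1 + n2;
    if (tot == 0) return stack[pt_out * 6 + pt_in];
    if (tot > maxloop) return INF;
    if (n1 == 0 || n2 == 0) return bulge[tot - 1];
    return internal_[tot - 1];
  }
};

static Params make_params(List par) {
  Params P;
  NumericMatrix st = par["stack"];
  P.stack.assign(36, INF);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) P.stack[i * 6 + j] = st(i, j);
  P.hairpin = as<std::vector<double> >(par["hairpin"]);
  P.hp_ext = as<double>(par["hp_ext"]);
  P.bulge = as<std::vector<double> >(par["bulge"]);
  P.internal_ = as<std::vector<double> >(par["internal"]);
  P.Ma = as<double>(par["Ma"]);
  P.Mb = as<double>(par["Mb"]);
  P.Mc = as<double>(par["Mc"]);
  P.maxloop = as<int>(par["maxloop"]);
  P.wobble = as<bool>(par["wobble"]);
  return P;
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector seq, List par, IntegerMatrix forbid) {
  const int n = seq.size();
  Params P = make_params(par);

  std::vector<bool> banned((size_t)n * n, false);
  for (int r = 0; r < forbid.nrow(); ++r) {
    int i = forbid(r, 0), j = forbid(r, 1);
    if (i >= 0 && j >= 0 && i < n && j < n) {
      banned[(size_t)i * n + j] = true;
      banned[(size_t)j * n + i] = true;
    }
  }

  std::vector<double> V((size_t)n * n, INF), WM((size_t)n * n, INF);
  std::vector<double> WMT((size_t)n * n, INF); // transposed copy of WM
  #define VV(i, j) V[(size_t)(i) * n + (j)]
  #define WMM(i, j) WM[(size_t)(i) * n + (j)]
  #define WMTT(i, j) WMT[(size_t)(j) * n + (i)]

  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int pt = pair_type(seq[i], seq[j]);
      if (!P.wobble && pt >= 4) pt = -1;
      if (pt >= 0 && !banned[(size_t)i * n + j]) {
        double best = P.hairpinE(j - i - 1);
        // stack / bulge / internal
        int kmax = std::min(j - 5, i + P.maxloop + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + 4, j - 1 - (P.maxloop - (k - i - 1)));
          for (int l = std::max(lmin, k + 4); l <= j - 1; ++l) {
            if (k == i + 1 && l == j - 1) { // stack handled via loopE(0,0)
            }
            int pt2 = pair_type(seq[k], seq[l]);
            if (!P.wobble && pt2 >= 4) pt2 = -1;
            if (pt2 < 0) continue;
            if (VV(k, l) >= INF) continue;
            double e = P.loopE(k - i - 1, j - l - 1, pt, pt2);
            if (e >= INF) continue;
            double cand = e + VV(k, l);
            if (cand < best) best = cand;
          }
        }
        // multibranch: a + b (closing) + WM2(i+1, j-1)
        {
          const double *rowA = &WM[(size_t)(i + 1) * n];      // WM(i+1, k)
          const double *colB = &WMT[(size_t)(j - 1) * n];     // WM(k+1, j-1)
          double mb = INF;
          for (int k = i + 2; k <= j - 2; ++k) {
            double a = rowA[k], b = colB[k + 1];
            if (a < INF && b < INF) {
              double s = a + b;
              if (s < mb) mb = s;
            }
          }
          if (mb < INF) {
            double cand = P.Ma + P.Mb + mb;
            if (cand < best) best = cand;
          }
        }
        VV(i, j) = best;
      }
      // WM over [i, j]
      double w = INF;
      if (WMM(i, j - 1) < INF) w = std::min(w, WMM(i, j - 1) + P.Mc);
      if (j - 1 >= i + 1 && WMM(i + 1, j) < INF)
        w = std::min(w, WMM(i + 1, j) + P.Mc);
      if (VV(i, j) < INF) w = std::min(w, VV(i, j) + P.Mb);
      {
        const double *rowA = &WM[(size_t)i * n];
        const double *colB = &WMT[(size_t)j * n];
        for (int k = i + 1; k < j; ++k) {
          double a = rowA[k], b = colB[k + 1];
          if (a < INF && b < INF) {
            double s = a + b;
            if (s < w) w = s;
          }
        }
      }
      WMM(i, j) = w;
      WMTT(i, j) = w;
    }
  }
  // short spans: WM for d < 4 (no pair possible): WM stays INF except
  // nothing; V stays INF.  WM(i,i)..: all INF (needs >=1 branch).

  // exterior
  std::vector<double> W(n + 1, 0.0);
  std::vector<int> Wtb(n + 1, -1); // traceback: pairing start or -1 unpaired
  for (int j = 0; j < n; ++j) {
    double best = W[j]; // j unpaired (W indices shifted by one)
    int arg = -1;
    for (int i = 0; i + 4 <= j; ++i) {
      if (VV(i, j) < INF) {
        double cand = W[i] + VV(i, j);
        if (cand < best - 1e-12) { best = cand; arg = i; }
      }
    }
    W[j + 1] = best;
    Wtb[j + 1] = arg;
  }
  double mfe = W[n];

  // traceback
  IntegerVector pairing(n, -1);
  std::vector<std::pair<int, int> > stackV; // V intervals to trace
  {
    int j = n - 1;
    while (j >= 0) {
      if (Wtb[j + 1] < 0) { j -= 1; continue; }
      int i = Wtb[j + 1];
      stackV.push_back(std::make_pair(i, j));
      j = i - 1;
    }
  }
  std::vector<std::pair<int, int> > stackWM;
  const double EPS = 1e-9;
  while (!stackV.empty() || !stackWM.empty()) {
    if (!stackV.empty()) {
      int i = stackV.back().first, j = stackV.back().second;
      stackV.pop_back();
      pairing[i] = j; pairing[j] = i;
      int pt = pair_type(seq[i], seq[j]);
      if (!P.wobble && pt >= 4) pt = -1;
      double target = VV(i, j);
      if (std::fabs(target - P.hairpinE(j - i - 1)) < EPS) continue;
      bool found = false;
      int kmax = std::min(j - 5, i + P.maxloop + 1);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        for (int l = k + 4; l <= j - 1 && !found; ++l) {
          int pt2 = pair_type(seq[k], seq[l]);
            if (!P.wobble && pt2 >= 4) pt2 = -1;
          if (pt2 < 0 || VV(k, l) >= INF) continue;
          double e = P.loopE(k - i - 1, j - l - 1, pt, pt2);
          if (e >= INF) continue;
          if (std::fabs(target - (e + VV(k, l))) < EPS) {
            stackV.push_back(std::make_pair(k, l));
            found = true;
          }
        }
      }
      if (found) continue;
      for (int k = i + 2; k <= j - 2 && !found; ++k) {
        if (WMM(i + 1, k) >= INF || WMM(k + 1, j - 1) >= INF) continue;
        if (std::fabs(target - (P.Ma + P.Mb + WMM(i + 1, k) +
                                WMM(k + 1, j - 1))) < EPS) {
          stackWM.push_back(std::make_pair(i + 1, k));
          stackWM.push_back(std::make_pair(k + 1, j - 1));
          found = true;
        }
      }
    } else {
      int i = stackWM.back().first, j = stackWM.back().second;
      stackWM.pop_back();
      double target = WMM(i, j);
      if (target >= INF) continue;
      if (VV(i, j) < INF && std::fabs(target - (VV(i, j) + P.Mb)) < EPS) {
        stackV.push_back(std::make_pair(i, j));
        continue;
      }
      if (j - 1 >= i && WMM(i, j - 1) < INF &&
          std::fabs(target - (WMM(i, j - 1) + P.Mc)) < EPS) {
        stackWM.push_back(std::make_pair(i, j - 1));
        continue;
      }
      if (i + 1 <= j && WMM(i + 1, j) < INF &&
          std::fabs(target - (WMM(i + 1, j) + P.Mc)) < EPS) {
        stackWM.push_back(std::make_pair(i + 1, j));
        continue;
      }
      bool found = false;
      for (int k = i + 1; k < j && !found; ++k) {
        if (WMM(i, k) < INF && WMM(k + 1, j) < INF &&
            std::fabs(target - (WMM(i, k) + WMM(k + 1, j))) < EPS) {
          stackWM.push_back(std::make_pair(i, k));
          stackWM.push_back(std::make_pair(k + 1, j));
          found = true;
        }
      }
    }
  }

  #undef VV
  #undef WMM
  return List::create(_["energy"] = mfe, _["pairing"] = pairing);
}
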