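#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Minimum-free-energy folding restricted to single-hairpin (stem-loop)
// topologies: a chain of nested base pairs closed by one terminal loop,
// with stacked pairs, bulges and internal loops between consecutive pairs.
// Multiloops and pseudoknots are outside the structure space by design;
// precursor scoring only ever needs the best stem-loop.

static const double INF = std::numeric_limits<double>::infinity();

// pair types: 0 none, 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA (DNA alphabet, T==U)
static inline int pairType(char a, char b) {
  if (a == 'C' && b == 'G') return 1;
  if (a == 'G' && b == 'C') return 2;
  if (a == 'G' && b == 'T') return 3;
  if (a == 'T' && b == 'G') return 4;
  if (a == 'A' && b == 'T') return 5;
  if (a == 'T' && b == 'A') return 6;
  return 0;
}

struct Params {
  NumericMatrix stack;     // 6x6, indexed [p1-1, p2-1]
  NumericVector hairpin;   // sizes 1..length, Inf below min size
  NumericVector bulge;     // sizes 1..length
  NumericVector internal;  // sizes 1..length (internal loop total size)
  double lxc;              // Jacobson-Stockmayer extrapolation coefficient
  double asym;             // internal-loop asymmetry penalty per nt
  double asymMax;          // cap on the asymmetry penalty
  int maxLoop;             // max unpaired bases between consecutive pairs
  int minHairpin;          // min terminal loop size
};

static inline double extrap(const NumericVector& tab, int n, double lxc) {
  int m = tab.size();
  if (n <= m) return tab[n - 1];
  return tab[m - 1] + lxc * std::log((double)n / (double)m);
}

static inline double loopEnergy(const Params& P, int p1, int p2,
                                int a, int b) {
  if (a == 0 && b == 0) return P.stack(p1 - 1, p2 - 1);
  int n = a + b;
  if (a == 0 || b == 0) {
    double e = extrap(P.bulge, n, P.lxc);
    if (n == 1) e += P.stack(p1 - 1, p2 - 1);  // bulge-1 keeps the stack
    return e;
  }
  double e = extrap(P.internal, n, P.lxc);
  e += std::min(P.asymMax, P.asym * std::abs(a - b));
  return e;
}

// [[Rcpp::export(name = ".fold_hairpin_cpp")]]
List foldHairpinCpp(std::string seq, NumericMatrix stack,
                    NumericVector hairpin, NumericVector bulge,
                    NumericVector internal_, double lxc, double asym,
                    double asymMax, int maxLoop, int minHairpin) {
  Params P{stack, hairpin, bulge, internal_, lxc, asym, asymMax,
           maxLoop, minHairpin};
  int n = seq.size();
  std::vector<int> pt(n * n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      pt[i * n + j] = pairType(seq[i], seq[j]);

  std::vector<double> H(n * n, INF);
  std::vector<int> chK(n * n, -1), chL(n * n, -1);

  for (int span = minHairpin + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int p1 = pt[i * n + j];
      if (p1 == 0) continue;
      double best = (j - i - 1 >= minHairpin)
                        ? extrap(P.hairpin, j - i - 1, P.lxc)
                        : INF;
      int bk = -1, bl = -1;
      int kmax = std::min(j - 1, i + maxLoop + 1);
      for (int k = i + 1; k <= kmax; ++k) {
        int a = k - i - 1;
        int lmin = std::max(k + minHairpin + 1, j - 1 - (maxLoop - a));
        for (int l = j - 1; l >= lmin; --l) {
          int p2 = pt[k * n + l];
          if (p2 == 0) continue;
          double sub = H[k * n + l];
          if (!std::isfinite(sub)) continue;
          double e = loopEnergy(P, p1, p2, a, j - l - 1) + sub;
          if (e < best) { best = e; bk = k; bl = l; }
        }
      }
      H[i * n + j] = best;
      chK[i * n + j] = bk;
      chL[i * n + j] = bl;
    }
  }

  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (H[i * n + j] < mfe) { mfe = H[i * n + j]; bi = i; bj = j; }

  std::string db(n, '.');
  std::vector<int> pi, pj;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (i >= 0) {
      db[i] = '(';
      db[j] = ')';
      pi.push_back(i + 1);
      pj.push_back(j + 1);
      int k = chK[i * n + j], l = chL[i * n + j];
      i = k; j = l;
    }
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    pairs(r, 0) = pi[r];
    pairs(r, 1) = pj[r];
  }
  return List::create(_["mfe"] = mfe, _["structure"] = db,
                      _["pairs"] = pairs);
}
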