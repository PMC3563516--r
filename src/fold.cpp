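// Minimum-free-energy secondary structure by dynamic programming under a
// simplified nearest-neighbour energy model (see foldRNA() docs for the model).
//
// Matrices:
//   V[i][j]  : min energy of [i..j] given (i,j) paired
//   WM[i][j] : min energy of [i..j] holding >= 1 top-level branch (multiloop interior)
//   W[j]     : min energy of prefix [1..j] (external bases free)
//
// Interior/bulge loops are capped at MAX_INTERIOR unpaired bases (standard
// practice); hairpin loops need >= MIN_HAIRPIN unpaired bases.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();
static const int MIN_HAIRPIN = 3;
static const int MAX_INTERIOR = 30;

// base codes: A=0, C=1, G=2, U/T=3, other=-1
static inline int baseCode(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

struct EnergyModel {
  double bpGC, bpAU, bpGU;       // per-pair strengths used in stack terms
  double h0, h1;                 // hairpin loop: h0 + h1 * loop_len
  double i0, i1;                 // interior/bulge: i0 + i1 * loop_len
  double m0;                     // multiloop closing constant
};

// pair strength; < 0 means not pairable
static inline double pairStrength(int a, int b, const EnergyModel &em) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return em.bpGC;
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return em.bpAU;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return em.bpGU;
  return -1.0;
}

static inline double stackEnergy(double so, double si) {
  return -(so + si) / 2.0;
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, NumericVector par) {
  EnergyModel em;
  em.bpGC = par[0]; em.bpAU = par[1]; em.bpGU = par[2];
  em.h0 = par[3]; em.h1 = par[4];
  em.i0 = par[5]; em.i1 = par[6];
  em.m0 = par[7];

  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = baseCode(seq[i]);
    if (s[i] < 0) stop("invalid base at position %d", i + 1);
  }
  if (n == 0) return List::create(_["mfe"] = 0.0, _["structure"] = "");

  // strength[i][j], -1 if unpairable
  std::vector< std::vector<double> > V(n, std::vector<double>(n, INF));
  std::vector< std::vector<double> > WM(n, std::vector<double>(n, INF));
  auto canPair = [&](int i, int j) { return pairStrength(s[i], s[j], em) >= 0; };

  for (int len = MIN_HAIRPIN + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      // V
      if (canPair(i, j)) {
        double so = pairStrength(s[i], s[j], em);
        double best = em.h0 + em.h1 * (j - i - 1);  // hairpin
        // stack
        if (j - 1 - (i + 1) - 1 >= MIN_HAIRPIN && canPair(i + 1, j - 1) &&
            V[i + 1][j - 1] < INF) {
          double e = stackEnergy(so, pairStrength(s[i + 1], s[j - 1], em)) +
                     V[i + 1][j - 1];
          if (e < best) best = e;
        }
        // interior / bulge (k,l) != (i+1, j-1)
        for (int k = i + 1; k <= j - 1; ++k) {
          int lmin = k + MIN_HAIRPIN + 1;
          for (int l = lmin; l <= j - 1; ++l) {
            int L = (k - i - 1) + (j - l - 1);
            if (L == 0) continue;             // that's the stack case
            if (L > MAX_INTERIOR) continue;
            if (V[k][l] >= INF) continue;
            double e = em.i0 + em.i1 * L + V[k][l];
            if (e < best) best = e;
          }
          if (k - i - 1 > MAX_INTERIOR) break;
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 1; k <= j - 2; ++k) {
          if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF) {
            double e = em.m0 + WM[i + 1][k] + WM[k + 1][j - 1];
            if (e < best) best = e;
          }
        }
        V[i][j] = best;
      }
      // WM
      double wbest = INF;
      if (V[i][j] < wbest) wbest = V[i][j];
      if (i + 1 <= j && WM[i + 1][j] < wbest) wbest = WM[i + 1][j];
      if (j - 1 >= i && WM[i][j - 1] < wbest) wbest = WM[i][j - 1];
      for (int k = i; k < j; ++k) {
        if (WM[i][k] < INF && WM[k + 1][j] < INF) {
          double e = WM[i][k] + WM[k + 1][j];
          if (e < wbest) wbest = e;
        }
      }
      WM[i][j] = wbest;
    }
  }

  // external
  std::vector<double> W(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) {
    double best = W[j - 1];
    for (int i = 1; i <= j; ++i) {
      if (V[i - 1][j - 1] < INF) {
        double e = W[i - 1] + V[i - 1][j - 1];
        if (e < best) best = e;
      }
    }
    W[j] = best;
  }
  double mfe = std::min(0.0, W[n]);

  // traceback
  std::string db(n, '.');
  const double EPS = 1e-9;
  struct Seg { int i, j, kind; };  // kind: 0 = external W prefix, 1 = V, 2 = WM
  std::vector<Seg> stack;
  if (W[n] < -EPS) stack.push_back({1, n, 0});
  while (!stack.empty()) {
    Seg sg = stack.back(); stack.pop_back();
    if (sg.kind == 0) {
      int j = sg.j;
      while (j >= 1) {
        if (std::abs(W[j] - W[j - 1]) < EPS) { --j; continue; }
        bool found = false;
        for (int i = 1; i <= j; ++i) {
          if (V[i - 1][j - 1] < INF &&
              std::abs(W[i - 1] + V[i - 1][j - 1] - W[j]) < EPS) {
            stack.push_back({i - 1, j - 1, 1});
            j = i - 1; found = true; break;
          }
        }
        if (!found) --j;
      }
    } else if (sg.kind == 1) {
      int i = sg.i, j = sg.j;
      db[i] = '('; db[j] = ')';
      double so = pairStrength(s[i], s[j], em);
      double v = V[i][j];
      // hairpin?
      if (std::abs(em.h0 + em.h1 * (j - i - 1) - v) < EPS) continue;
      // stack?
      if (j - 1 - (i + 1) - 1 >= MIN_HAIRPIN && canPair(i + 1, j - 1) &&
          V[i + 1][j - 1] < INF &&
          std::abs(stackEnergy(so, pairStrength(s[i + 1], s[j - 1], em)) +
                   V[i + 1][j - 1] - v) < EPS) {
        stack.push_back({i + 1, j - 1, 1});
        continue;
      }
      // interior?
      bool done = false;
      for (int k = i + 1; k <= j - 1 && !done; ++k) {
        if (k - i - 1 > MAX_INTERIOR) break;
        for (int l = k + MIN_HAIRPIN + 1; l <= j - 1; ++l) {
          int L = (k - i - 1) + (j - l - 1);
          if (L == 0 || L > MAX_INTERIOR || V[k][l] >= INF) continue;
          if (std::abs(em.i0 + em.i1 * L + V[k][l] - v) < EPS) {
            stack.push_back({k, l, 1});
            done = true; break;
          }
        }
      }
      if (done) continue;
      // multiloop
      for (int k = i + 1; k <= j - 2; ++k) {
        if (WM[i + 1][k] < INF && WM[k + 1][j - 1] < INF &&
            std::abs(em.m0 + WM[i + 1][k] + WM[k + 1][j - 1] - v) < EPS) {
          stack.push_back({i + 1, k, 2});
          stack.push_back({k + 1, j - 1, 2});
          break;
        }
      }
    } else {
      int i = sg.i, j = sg.j;
      double w = WM[i][j];
      if (w >= INF) continue;
      if (V[i][j] < INF && std::abs(V[i][j] - w) < EPS) {
        stack.push_back({i, j, 1});
        continue;
      }
      if (i + 1 <= j && WM[i + 1][j] < INF && std::abs(WM[i + 1][j] - w) < EPS) {
        stack.push_back({i + 1, j, 2});
        continue;
      }
      if (j - 1 >= i && WM[i][j - 1] < INF && std::abs(WM[i][j - 1] - w) < EPS) {
        stack.push_back({i, j - 1, 2});
        continue;
      }
      for (int k = i; k < j; ++k) {
        if (WM[i][k] < INF && WM[k + 1][j] < INF &&
            std::abs(WM[i][k] + WM[k + 1][j] - w) < EPS) {
          stack.push_back({i, k, 2});
          stack.push_back({k + 1, j, 2});
          break;
        }
      }
    }
  }

  return List::create(_["mfe"] = mfe, _["structure"] = db);
}
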