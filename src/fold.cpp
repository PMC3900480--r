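#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <stack>
#include <string>
#include <array>
using namespace Rcpp;

// Minimum-free-energy folding of a single RNA strand under a compact
// nearest-neighbor model: Watson-Crick + G:U stacking energies, length
// penalties for hairpin/bulge/internal loops, and an affine multiloop
// penalty.  Energies are held as integer tenths of kcal/mol.  Pseudoknots
// are excluded; interior loops are capped at MAXLOOP unpaired bases.

static const int INF = 1000000;
static const int MAXLOOP = 30;
static const int MIN_HAIRPIN = 3;      // minimal unpaired bases in a hairpin
static const int MULTI_A = 34;         // multiloop closing penalty (0.1 kcal/mol)
static const int MULTI_B = 4;          // per-branch penalty
static const int MULTI_C = 0;          // per-unpaired-base penalty
static const double RT_LOOP = 10.0 * 1.75 * 0.616; // Jacobson-Stockmayer slope

// pair codes: 0 AU, 1 CG, 2 GC, 3 GU, 4 UA, 5 UG, -1 none
static int pair_code(int a, int b) {
  // bases: 0 A, 1 C, 2 G, 3 U
  if (a == 0 && b == 3) return 0;
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 0) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// stacking energies, outer pair x inner pair, tenths of kcal/mol
static const int STACK[6][6] = {
  // inner:  AU   CG   GC   GU   UA   UG     outer
  {          -9, -22, -21,  -6, -11, -14 }, // AU
  {         -21, -33, -24, -14, -21, -21 }, // CG
  {         -24, -34, -33, -15, -22, -25 }, // GC
  {         -13, -25, -21,  -5, -14,  13 }, // GU
  {         -13, -24, -21, -10,  -9, -13 }, // UA
  {         -10, -15, -14,   3,  -6,  -5 }  // UG
};

static const int HAIRPIN_TAB[10] = { 0, 0, 0, 54, 56, 57, 54, 60, 55, 64 };
static const int BULGE_TAB[7]   = { 0, 38, 28, 32, 36, 40, 44 };
static const int INTERNAL_TAB[7] = { 0, 0, 15, 16, 17, 20, 21 };

static int extrap(int base_e, int base_n, int n) {
  return base_e + (int)std::lround(RT_LOOP * std::log((double)n / base_n));
}

static int hairpin_e(int n) {
  if (n < MIN_HAIRPIN) return INF;
  if (n <= 9) return HAIRPIN_TAB[n];
  return extrap(HAIRPIN_TAB[9], 9, n);
}

static int bulge_e(int n) {
  if (n <= 0) return INF;
  if (n <= 6) return BULGE_TAB[n];
  return extrap(BULGE_TAB[6], 6, n);
}

static int internal_e(int n) {
  if (n < 2) return INF;
  if (n <= 6) return INTERNAL_TAB[n];
  return extrap(INTERNAL_TAB[6], 6, n);
}

// energy of the loop closed by (i,j) with inner pair (k,l); 0-based
static int loop_e(int i, int j, int k, int l, const std::vector<int>& s) {
  int n1 = k - i - 1, n2 = j - l - 1;
  int pc_out = pair_code(s[i], s[j]);
  int pc_in = pair_code(s[k], s[l]);
  if (pc_out < 0 || pc_in < 0) return INF;
  if (n1 == 0 && n2 == 0) return STACK[pc_out][pc_in];
  if (n1 == 0 || n2 == 0) return bulge_e(n1 + n2);
  return internal_e(n1 + n2);
}

static std::vector<int> encode(const std::string& seq) {
  std::vector<int> s(seq.size());
  for (size_t i = 0; i < seq.size(); ++i) {
    switch (seq[i]) {
      case 'A': case 'a': s[i] = 0; break;
      case 'C': case 'c': s[i] = 1; break;
      case 'G': case 'g': s[i] = 2; break;
      case 'U': case 'u': case 'T': case 't': s[i] = 3; break;
      default: stop("fold_mfe: sequence contains non-ACGTU character");
    }
  }
  return s;
}

struct FoldState {
  int n;
  std::vector<int> s;
  std::vector<int> V, WM, W;
  int& v(int i, int j) { return V[i * n + j]; }
  int& wm(int i, int j) { return WM[i * n + j]; }
};

static void fill_tables(FoldState& fs) {
  int n = fs.n;
  fs.V.assign((size_t)n * n, INF);
  fs.WM.assign((size_t)n * n, INF);
  fs.W.assign(n + 1, 0);
  for (int d = MIN_HAIRPIN + 1; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V(i,j)
      if (pair_code(fs.s[i], fs.s[j]) >= 0) {
        int best = hairpin_e(j - i - 1);
        // interior / stack / bulge
        int kmax = std::min(j - 1, i + MAXLOOP + 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + MIN_HAIRPIN + 1, j - 1 - (MAXLOOP - (k - i - 1)));
          for (int l = j - 1; l >= lmin; --l) {
            if (pair_code(fs.s[k], fs.s[l]) < 0) continue;
            int e = loop_e(i, j, k, l, fs.s);
            if (e >= INF) continue;
            int cand = e + fs.v(k, l);
            if (cand < best) best = cand;
          }
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 1; k < j - 1; ++k) {
          int a = fs.wm(i + 1, k), b = fs.wm(k + 1, j - 1);
          if (a >= INF || b >= INF) continue;
          int cand = MULTI_A + MULTI_B + a + b;
          if (cand < best) best = cand;
        }
        fs.v(i, j) = best;
      }
      // WM(i,j): >= 1 branch, unpaired cost MULTI_C
      int best = INF;
      if (fs.v(i, j) < INF) best = fs.v(i, j) + MULTI_B;
      if (i + 1 <= j && fs.wm(i + 1, j) < INF)
        best = std::min(best, fs.wm(i + 1, j) + MULTI_C);
      if (j - 1 >= i && fs.wm(i, j - 1) < INF)
        best = std::min(best, fs.wm(i, j - 1) + MULTI_C);
      for (int k = i + 1; k <= j; ++k) {
        int a = fs.wm(i, k - 1), b = fs.wm(k, j);
        if (a < INF && b < INF) best = std::min(best, a + b);
      }
      fs.wm(i, j) = best;
    }
  }
  // external loop, W[j] = best for prefix 1..j (1-based length index)
  for (int j = 1; j <= n; ++j) {
    int best = fs.W[j - 1];
    for (int i = 1; i <= j; ++i) {
      int vij = (j - i > MIN_HAIRPIN) ? fs.v(i - 1, j - 1) : INF;
      if (vij < INF) best = std::min(best, fs.W[i - 1] + vij);
    }
    fs.W[j] = best;
  }
}

static void traceback(FoldState& fs, std::string& db) {
  int n = fs.n;
  db.assign(n, '.');
  // stack entries: (i, j, mode) mode 0 = V, 1 = WM, 2 = external prefix j
  std::stack<std::array<int,3>> st;
  st.push({0, n, 2});
  while (!st.empty()) {
    auto t = st.top(); st.pop();
    if (t[2] == 2) {
      int j = t[1];
      while (j >= 1) {
        if (fs.W[j] == fs.W[j - 1]) { --j; continue; }
        bool found = false;
        for (int i = 1; i <= j; ++i) {
          int vij = (j - i > MIN_HAIRPIN) ? fs.v(i - 1, j - 1) : INF;
          if (vij < INF && fs.W[j] == fs.W[i - 1] + vij) {
            st.push({i - 1, j - 1, 0});
            j = i - 1;
            found = true;
            break;
          }
        }
        if (!found) --j;
      }
    } else if (t[2] == 0) {
      int i = t[0], j = t[1];
      db[i] = '('; db[j] = ')';
      int vij = fs.v(i, j);
      if (vij == hairpin_e(j - i - 1)) continue;
      bool found = false;
      int kmax = std::min(j - 1, i + MAXLOOP + 1);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int lmin = std::max(k + MIN_HAIRPIN + 1, j - 1 - (MAXLOOP - (k - i - 1)));
        for (int l = j - 1; l >= lmin; --l) {
          if (pair_code(fs.s[k], fs.s[l]) < 0) continue;
          int e = loop_e(i, j, k, l, fs.s);
          if (e < INF && fs.v(k, l) < INF && vij == e + fs.v(k, l)) {
            st.push({k, l, 0});
            found = true;
            break;
          }
        }
      }
      if (found) continue;
      for (int k = i + 1; k < j - 1; ++k) {
        int a = fs.wm(i + 1, k), b = fs.wm(k + 1, j - 1);
        if (a < INF && b < INF && vij == MULTI_A + MULTI_B + a + b) {
          st.push({i + 1, k, 1});
          st.push({k + 1, j - 1, 1});
          found = true;
          break;
        }
      }
    } else { // WM
      int i = t[0], j = t[1];
      int w = fs.wm(i, j);
      if (w >= INF) continue;
      if (fs.v(i, j) < INF && w == fs.v(i, j) + MULTI_B) {
        st.push({i, j, 0});
        continue;
      }
      if (i + 1 <= j && fs.wm(i + 1, j) < INF && w == fs.wm(i + 1, j) + MULTI_C) {
        st.push({i + 1, j, 1});
        continue;
      }
      if (j - 1 >= i && fs.wm(i, j - 1) < INF && w == fs.wm(i, j - 1) + MULTI_C) {
        st.push({i, j - 1, 1});
        continue;
      }
      for (int k = i + 1; k <= j; ++k) {
        int a = fs.wm(i, k - 1), b = fs.wm(k, j);
        if (a < INF && b < INF && w == a + b) {
          st.push({i, k - 1, 1});
          st.push({k, j, 1});
          break;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List fold_rna_cpp(std::string seq) {
  FoldState fs;
  fs.s = encode(seq);
  fs.n = (int)fs.s.size();
  if (fs.n < 1) stop("fold_mfe: empty sequence");
  std::string db(fs.n, '.');
  double mfe = 0.0;
  if (fs.n > MIN_HAIRPIN + 1) {
    fill_tables(fs);
    mfe = fs.W[fs.n] / 10.0;
    if (fs.W[fs.n] < 0) traceback(fs, db);
  }
  return List::create(_["structure"] = db, _["energy"] = mfe);
}

// Expose the energy model so the R-side structure evaluator shares one
// parameter source with the DP.
// [[Rcpp::export]]
List fold_energy_model_cpp() {
  NumericMatrix stk(6, 6);
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j) stk(i, j) = STACK[i][j] / 10.0;
  CharacterVector pn = CharacterVector::create("AU","CG","GC","GU","UA","UG");
  rownames(stk) = pn; colnames(stk) = pn;
  NumericVector hp(31), bl(31), il(31);
  for (int n = 0; n <= 30; ++n) {
    hp[n] = (n < MIN_HAIRPIN) ? NA_REAL : hairpin_e(n) / 10.0;
    bl[n] = (n < 1) ? NA_REAL : bulge_e(n) / 10.0;
    il[n] = (n < 2) ? NA_REAL : internal_e(n) / 10.0;
  }
  return List::create(
    _["stack"] = stk, _["hairpin"] = hp, _["bulge"] = bl, _["internal"] = il,
    _["multi_closing"] = MULTI_A / 10.0, _["multi_branch"] = MULTI_B / 10.0,
    _["multi_unpaired"] = MULTI_C / 10.0, _["min_hairpin"] = MIN_HAIRPIN,
    _["max_interior"] = MAXLOOP,
    _["loop_slope"] = RT_LOOP / 10.0);
}

// [[Rcpp::export]]
double loop_extrapolate_cpp(double base_e, int base_n, int n) {
  return extrap((int)std::lround(base_e * 10.0), base_n, n) / 10.0;
}
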