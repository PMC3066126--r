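// Built-in deterministic nearest-neighbour folding engine.
//
// Energy model (integer decikilocalories/mol):
//   * allowed pairs: AU, CG, GC, UA, GU, UG
//   * helix stacks from the 6x6 table passed in from R (single source
//     of truth shared with the duplex-energy model)
//   * hairpin loop of u unpaired bases (u >= 3):  45 + 17.5*ln(u/3)
//   * bulge of u bases (u >= 1):                  38 + 17.5*ln(u)
//   * interior loop of u total bases (u >= 2):    18 + 17.5*ln(u/2)
//   * multibranch closing penalty:                34
//   * no dangles, no coaxial stacking, interior loops capped at 30 nt
//
// Minimisation is a Zuker-style DP (V = energy given i.j paired, W =
// optimal energy of a region); ties are broken by a fixed case order so
// the traceback is fully deterministic.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF = 1000000000;
static const int MAXLOOP = 30;
static const int MULTI_CLOSE = 34;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3;
    default: return -1;
  }
}

// Pair index in the order AU,CG,GC,UA,GU,UG (1..6), 0 if not pairable.
static inline int pair_idx(int a, int b) {
  if (a == 0 && b == 3) return 1;  // AU
  if (a == 1 && b == 2) return 2;  // CG
  if (a == 2 && b == 1) return 3;  // GC
  if (a == 3 && b == 0) return 4;  // UA
  if (a == 2 && b == 3) return 5;  // GU
  if (a == 3 && b == 2) return 6;  // UG
  return 0;
}

static inline int hairpin_pen(int u) {
  if (u < 3) return INF;
  return 45 + (int)std::lround(17.5 * std::log((double)u / 3.0));
}

static inline int loop_pen(int s1, int s2) {
  int u = s1 + s2;
  if (s1 == 0 || s2 == 0)
    return 38 + (int)std::lround(17.5 * std::log((double)u));
  return 18 + (int)std::lround(17.5 * std::log((double)u / 2.0));
}

struct FoldCtx {
  int n;
  std::vector<int> code;
  std::vector<std::vector<int> > V, W;
  const IntegerMatrix* stack;
  inline int pidx(int i, int j) const { return pair_idx(code[i], code[j]); }
  inline int stk(int pout, int pin) const { return (*stack)(pout - 1, pin - 1); }
};

static int compute(FoldCtx& c) {
  int n = c.n;
  c.V.assign(n, std::vector<int>(n, INF));
  c.W.assign(n, std::vector<int>(n, 0));
  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      // V(i,j)
      int p = c.pidx(i, j);
      if (p > 0) {
        int best = hairpin_pen(j - i - 1);
        int pin = c.pidx(i + 1, j - 1);
        if (pin > 0 && c.V[i + 1][j - 1] < INF) {
          int e = c.V[i + 1][j - 1] + c.stk(p, pin);
          if (e < best) best = e;
        }
        for (int i2 = i + 1; i2 <= std::min(i + MAXLOOP + 1, j - 5); ++i2) {
          int s1 = i2 - i - 1;
          for (int j2 = j - 1; j2 >= i2 + 4 && (j - 1 - j2) + s1 <= MAXLOOP; --j2) {
            int s2 = j - j2 - 1;
            if (s1 == 0 && s2 == 0) continue;
            if (c.V[i2][j2] >= INF) continue;
            int e = c.V[i2][j2] + loop_pen(s1, s2);
            if (e < best) best = e;
          }
        }
        for (int k = i + 2; k <= j - 3; ++k) {
          if (c.W[i + 1][k] < 0 && c.W[k + 1][j - 1] < 0) {
            int e = c.W[i + 1][k] + c.W[k + 1][j - 1] + MULTI_CLOSE;
            if (e < best) best = e;
          }
        }
        c.V[i][j] = best;
      }
      // W(i,j)
      int w = c.W[i + 1][j];
      int w2 = c.W[i][j - 1];
      if (w2 < w) w = w2;
      if (c.V[i][j] < w) w = c.V[i][j];
      for (int k = i; k < j; ++k) {
        int e = c.W[i][k] + c.W[k + 1][j];
        if (e < w) w = e;
      }
      c.W[i][j] = w;
    }
  }
  return c.W[0][n - 1];
}

static void traceback(FoldCtx& c, std::string& db) {
  int n = c.n;
  db.assign(n, '.');
  std::vector<std::pair<std::pair<int, int>, int> > st;  // ((i,j), table) 0=W 1=V
  if (n >= 5) st.push_back(std::make_pair(std::make_pair(0, n - 1), 0));
  while (!st.empty()) {
    int i = st.back().first.first, j = st.back().first.second;
    int tab = st.back().second;
    st.pop_back();
    if (j - i < 4) continue;
    if (tab == 0) {
      int w = c.W[i][j];
      if (w == 0) continue;
      if (w == c.W[i + 1][j]) { st.push_back(std::make_pair(std::make_pair(i + 1, j), 0)); continue; }
      if (w == c.W[i][j - 1]) { st.push_back(std::make_pair(std::make_pair(i, j - 1), 0)); continue; }
      if (w == c.V[i][j]) { st.push_back(std::make_pair(std::make_pair(i, j), 1)); continue; }
      bool done = false;
      for (int k = i; k < j && !done; ++k) {
        if (c.W[i][k] + c.W[k + 1][j] == w) {
          st.push_back(std::make_pair(std::make_pair(i, k), 0));
          st.push_back(std::make_pair(std::make_pair(k + 1, j), 0));
          done = true;
        }
      }
    } else {
      int v = c.V[i][j];
      db[i] = '('; db[j] = ')';
      int p = c.pidx(i, j);
      if (v == hairpin_pen(j - i - 1)) continue;
      int pin = c.pidx(i + 1, j - 1);
      if (pin > 0 && c.V[i + 1][j - 1] < INF &&
          v == c.V[i + 1][j - 1] + c.stk(p, pin)) {
        st.push_back(std::make_pair(std::make_pair(i + 1, j - 1), 1));
        continue;
      }
      bool done = false;
      for (int i2 = i + 1; i2 <= std::min(i + MAXLOOP + 1, j - 5) && !done; ++i2) {
        int s1 = i2 - i - 1;
        for (int j2 = j - 1; j2 >= i2 + 4 && (j - 1 - j2) + s1 <= MAXLOOP && !done; --j2) {
          int s2 = j - j2 - 1;
          if (s1 == 0 && s2 == 0) continue;
          if (c.V[i2][j2] >= INF) continue;
          if (v == c.V[i2][j2] + loop_pen(s1, s2)) {
            st.push_back(std::make_pair(std::make_pair(i2, j2), 1));
            done = true;
          }
        }
      }
      if (done) continue;
      for (int k = i + 2; k <= j - 3 && !done; ++k) {
        if (c.W[i + 1][k] < 0 && c.W[k + 1][j - 1] < 0 &&
            v == c.W[i + 1][k] + c.W[k + 1][j - 1] + MULTI_CLOSE) {
          st.push_back(std::make_pair(std::make_pair(i + 1, k), 0));
          st.push_back(std::make_pair(std::make_pair(k + 1, j - 1), 0));
          done = true;
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_fold_nn(std::string seq, IntegerMatrix stack) {
  int n = (int)seq.size();
  if (n < 1 || n > 2000) stop("sequence length out of range for folding");
  FoldCtx c;
  c.n = n;
  c.stack = &stack;
  c.code.resize(n);
  for (int i = 0; i < n; ++i) c.code[i] = base_code(seq[i]);
  int mfe;
  std::string db;
  if (n < 5) {
    mfe = 0;
    db.assign(n, '.');
  } else {
    mfe = compute(c);
    if (mfe > 0) mfe = 0;  // never report a destabilising structure
    if (mfe == 0) db.assign(n, '.'); else traceback(c, db);
  }
  return List::create(_["structure"] = db, _["mfe_dc"] = mfe);
}

// Rescore a given dot-bracket structure with the same loop decomposition
// as the DP above (independent energy-consistency oracle).
// [[Rcpp::export]]
int cpp_eval_structure(std::string seq, std::string db, IntegerMatrix stack) {
  int n = (int)seq.size();
  if ((int)db.size() != n) stop("structure length != sequence length");
  std::vector<int> pt(n, -1);
  std::vector<int> stk_pos;
  for (int i = 0; i < n; ++i) {
    if (db[i] == '(') stk_pos.push_back(i);
    else if (db[i] == ')') {
      if (stk_pos.empty()) stop("unbalanced structure");
      pt[i] = stk_pos.back(); pt[stk_pos.back()] = i; stk_pos.pop_back();
    }
  }
  if (!stk_pos.empty()) stop("unbalanced structure");
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
  int total = 0;
  for (int i = 0; i < n; ++i) {
    int j = pt[i];
    if (j <= i) continue;
    int p = pair_idx(code[i], code[j]);
    if (p == 0) stop("structure pairs two non-complementary bases");
    // children: maximal pairs directly inside (i,j)
    std::vector<std::pair<int, int> > kids;
    int k = i + 1;
    while (k < j) {
      if (pt[k] > k) { kids.push_back(std::make_pair(k, pt[k])); k = pt[k] + 1; }
      else ++k;
    }
    if (kids.empty()) {
      total += hairpin_pen(j - i - 1);
    } else if (kids.size() == 1) {
      int i2 = kids[0].first, j2 = kids[0].second;
      int s1 = i2 - i - 1, s2 = j - j2 - 1;
      if (s1 == 0 && s2 == 0) {
        int pin = pair_idx(code[i2], code[j2]);
        total += stack(p - 1, pin - 1);
      } else {
        total += loop_pen(s1, s2);
      }
    } else {
      total += MULTI_CLOSE;
    }
  }
  return total;
}
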