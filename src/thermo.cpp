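// Nearest-neighbour RNA secondary-structure engine.
//
// Energies are integers in units of 0.01 kcal/mol (centi-kcal), as is usual
// for MFE dynamic programming, so traceback decisions are exact. The model:
//   - Watson-Crick + GU wobble pairs; min hairpin loop 3 nt; no pseudoknots.
//   - stacking energies: Turner-1999-style 6x6 table (incl. wobble rows),
//     symmetric under strand flip by construction (checked in tests).
//   - hairpin / bulge / internal-loop size initiations with Jacobson-
//     Stockmayer log extrapolation; interior+bulge loops are capped at
//     MAXLOOP=30 unpaired nt (a property of the model, enforced identically
//     in the DP and in the explicit-structure scorer).
//   - multiloop: linear model a + b*branches + c per unpaired nt (c = 0).
//   - terminal AU/GU penalty at helix ends facing hairpin/multi/exterior
//     loops; a separate closure penalty flanking internal/bulge loops.
//   - dangle mode "some": constant 5'/3' dangle bonuses on helix ends in
//     exterior and multiloops (d2-like: applied whenever a neighbour exists).
// Cotranscriptional variant: every loop term attributed to a closing pair
// (i,j) is scaled by gamma(d) = alpha*exp(-d/tau) + (1-alpha), d = j-i;
// branch-local terms are scaled by the branch pair's own gamma. alpha = 0
// reproduces the equilibrium fold exactly (gamma == 1 in IEEE arithmetic).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static const int INF_E = 10000000;
static const int MAXLOOP = 30;
static const int NBPAIRS = 6; // 1 CG, 2 GC, 3 GU, 4 UG, 5 AU, 6 UA
static const double GASCONST = 1.98717e-3; // kcal/(mol K)

// pair type lookup: bases A=0 C=1 G=2 U=3
static const int PAIR_TYPE[4][4] = {
  /*A*/ {0, 0, 0, 5},
  /*C*/ {0, 0, 1, 0},
  /*G*/ {0, 2, 0, 3},
  /*U*/ {6, 0, 4, 0}
};

// stack37[p1][p2]: pair (i,j) of type p1 stacked on inner pair (i+1,j-1) of
// type p2. Symmetric under (p1,p2) -> (flip p2, flip p1).
static const int STACK37[NBPAIRS + 1][NBPAIRS + 1] = {
  {INF_E, INF_E, INF_E, INF_E, INF_E, INF_E, INF_E},
  /*CG*/ {INF_E, -330, -240, -140, -210, -210, -210},
  /*GC*/ {INF_E, -340, -330, -150, -250, -240, -220},
  /*GU*/ {INF_E, -250, -210,  -50,  130, -130, -140},
  /*UG*/ {INF_E, -150, -140,   30,  -50, -100,  -60},
  /*AU*/ {INF_E, -220, -210,  -60, -140,  -90, -110},
  /*UA*/ {INF_E, -240, -210, -100, -130, -130,  -90}
};

static const int ML_CLOSING37 = 340;
static const int ML_BRANCH37  = 40;
static const int ML_BASE37    = 0;
static const int TERM_AU37    = 50;  // helix end facing hairpin/multi/exterior
static const int INT_AU37     = 70;  // helix end flanking internal/bulge loop
static const int NINIO37      = 50;  // per unit of internal-loop asymmetry
static const int NINIO_MAX37  = 300;
static const int DANGLE5_37   = -30;
static const int DANGLE3_37   = -50;
static const double LXC37     = 107.856; // log-extrapolation coefficient

static int hairpin_init(int size) {
  static const int tab[] = {INF_E, INF_E, INF_E, 570, 560, 560, 540, 590, 560, 640};
  if (size <= 2) return INF_E;
  if (size <= 9) return tab[size];
  return 640 + (int) std::lround(LXC37 * std::log(size / 9.0));
}

static int bulge_init(int size) {
  static const int tab[] = {INF_E, 380, 280, 320, 360, 400, 440};
  if (size < 1) return INF_E;
  if (size <= 6) return tab[size];
  return 440 + (int) std::lround(LXC37 * std::log(size / 6.0));
}

static int internal_init(int size) {
  static const int tab[] = {INF_E, INF_E, 150, 160, 170, 180, 200, 220, 230, 240, 250, 260};
  if (size < 2) return INF_E;
  if (size <= 11) return tab[size];
  return 260 + (int) std::lround(LXC37 * std::log(size / 11.0));
}

static inline int term_au(int pt) { return (pt > 2) ? TERM_AU37 : 0; }
static inline int int_au(int pt)  { return (pt > 2) ? INT_AU37 : 0; }

struct Model {
  int minloop;        // min hairpin loop size (nt)
  int dangles;        // 0 none, 1 "some" (constant d2-like terms)
  double temperature; // Celsius, enters RT only
  double alpha;       // cotranscriptional scaling; 0 = equilibrium
  double tau;
  double rt() const { return GASCONST * (temperature + 273.15); }
};

static inline double gamma_d(const Model& md, int d) {
  if (md.alpha == 0.0) return 1.0;
  return md.alpha * std::exp(-(double) d / md.tau) + (1.0 - md.alpha);
}

static inline int scale_e(const Model& md, int e, int d) {
  if (e >= INF_E) return INF_E;
  if (md.alpha == 0.0) return e;
  return (int) std::llround(gamma_d(md, d) * (double) e);
}

// hairpin closed by (i,j) (loop terms only, unscaled)
static inline int e_hairpin(int size, int pt) {
  int h = hairpin_init(size);
  if (h >= INF_E) return INF_E;
  return h + term_au(pt);
}

// interior/bulge/stack between (i,j) and inner (k,l); n1,n2 unpaired counts
static inline int e_intloop(int n1, int n2, int pt_out, int pt_in) {
  if (n1 + n2 > MAXLOOP) return INF_E;
  if (n1 == 0 && n2 == 0) return STACK37[pt_out][pt_in];
  if (n1 == 0 || n2 == 0) {
    int m = n1 + n2;
    if (m == 1) return bulge_init(1) + STACK37[pt_out][pt_in];
    return bulge_init(m) + int_au(pt_out) + int_au(pt_in);
  }
  int asym = NINIO37 * std::abs(n1 - n2);
  if (asym > NINIO_MAX37) asym = NINIO_MAX37;
  return internal_init(n1 + n2) + asym + int_au(pt_out) + int_au(pt_in);
}

static inline int add_e(int a, int b) {
  if (a >= INF_E || b >= INF_E) return INF_E;
  return a + b;
}

// --------------------------------------------------------------------------
// shared sequence/constraint state

struct Fold {
  int n;
  std::vector<int> s;        // 1-based codes
  std::vector<char> fu;      // forced unpaired
  std::vector<char> fpair;   // forced paired
  std::vector<int> fp_cum;   // cumsum of fpair
  Model md;

  Fold(const IntegerVector& seq, const Model& model,
       const LogicalVector& f_un, const LogicalVector& f_pa) : md(model) {
    n = seq.size();
    s.assign(n + 2, -1);
    fu.assign(n + 2, 0);
    fpair.assign(n + 2, 0);
    fp_cum.assign(n + 2, 0);
    for (int i = 1; i <= n; ++i) {
      s[i] = seq[i - 1];
      fu[i] = f_un.size() ? (char) f_un[i - 1] : 0;
      fpair[i] = f_pa.size() ? (char) f_pa[i - 1] : 0;
      fp_cum[i] = fp_cum[i - 1] + fpair[i];
    }
  }
  inline int ptype(int i, int j) const { return PAIR_TYPE[s[i]][s[j]]; }
  inline bool can_pair(int i, int j) const {
    if (j - i <= md.minloop) return false;
    if (fu[i] || fu[j]) return false;
    return ptype(i, j) != 0;
  }
  inline bool free_region(int i, int j) const { // [i..j] may be all-unpaired
    if (i > j) return true;
    return (fp_cum[j] - fp_cum[i - 1]) == 0;
  }
  inline bool may_unpair(int i) const { return !fpair[i]; }
  // branch term in a multiloop (b + terminal AU + dangles), scaled by own gamma
  inline int ml_branch(int i, int j) const {
    int pt = ptype(i, j);
    int e = ML_BRANCH37 + term_au(pt) + (md.dangles ? DANGLE5_37 + DANGLE3_37 : 0);
    return scale_e(md, e, j - i);
  }
  // exterior-loop branch term, scaled by own gamma
  inline int ext_branch(int i, int j) const {
    int pt = ptype(i, j);
    int e = term_au(pt);
    if (md.dangles) {
      if (i > 1) e += DANGLE5_37;
      if (j < n) e += DANGLE3_37;
    }
    return scale_e(md, e, j - i);
  }
  // multiloop closing-pair local terms, scaled by closing gamma
  inline int ml_closing(int i, int j) const {
    int pt = ptype(i, j);
    int e = ML_CLOSING37 + ML_BRANCH37 + term_au(pt) +
            (md.dangles ? DANGLE5_37 + DANGLE3_37 : 0);
    return scale_e(md, e, j - i);
  }
};

// --------------------------------------------------------------------------
// MFE fill + traceback

struct MfeArrays {
  int n;
  std::vector<int> V, ML, M1; // flat (n+2)*(n+2)
  std::vector<int> W;
  inline int idx(int i, int j) const { return i * (n + 2) + j; }
};

static void mfe_fill(const Fold& f, MfeArrays& a) {
  int n = f.n;
  a.n = n;
  a.V.assign((n + 2) * (n + 2), INF_E);
  a.ML.assign((n + 2) * (n + 2), INF_E);
  a.M1.assign((n + 2) * (n + 2), INF_E);
  a.W.assign(n + 2, INF_E);

  for (int d = f.md.minloop + 1; d < n; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      // V(i,j)
      if (f.can_pair(i, j)) {
        int pt = f.ptype(i, j);
        int best = INF_E;
        // interior (incl. stack, bulge)
        int kmax = std::min(i + MAXLOOP + 1, j - f.md.minloop - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          if (!f.free_region(i + 1, k - 1)) break;
          int n1 = k - i - 1;
          int lmin = std::max(k + f.md.minloop + 1, j - 1 - (MAXLOOP - n1));
          for (int l = lmin; l <= j - 1; ++l) {
            if (!f.can_pair(k, l)) continue;
            if (!f.free_region(l + 1, j - 1)) continue;
            int e = e_intloop(n1, j - l - 1, pt, f.ptype(k, l));
            int cand = add_e(scale_e(f.md, e, j - i), a.V[a.idx(k, l)]);
            if (cand < best) best = cand;
          }
        }
        // hairpin
        if (f.free_region(i + 1, j - 1)) {
          int eh = scale_e(f.md, e_hairpin(j - i - 1, pt), j - i);
          if (eh < best) best = eh;
        }
        // multiloop
        int close = f.ml_closing(i, j);
        for (int k = i + 2; k <= j - 2; ++k) {
          int cand = add_e(close,
                     add_e(a.ML[a.idx(i + 1, k - 1)], a.M1[a.idx(k, j - 1)]));
          if (cand < best) best = cand;
        }
        a.V[a.idx(i, j)] = best;
      }
      // M1(i,j): one branch starting exactly at i, trailing unpaired allowed
      {
        int best = INF_E;
        if (f.can_pair(i, j))
          best = add_e(a.V[a.idx(i, j)], f.ml_branch(i, j));
        if (f.may_unpair(j)) {
          int cand = add_e(a.M1[a.idx(i, j - 1)], ML_BASE37);
          if (cand < best) best = cand;
        }
        a.M1[a.idx(i, j)] = best;
      }
      // ML(i,j): >= 1 branch in multiloop context
      {
        int best = INF_E;
        if (f.may_unpair(i)) best = add_e(a.ML[a.idx(i + 1, j)], ML_BASE37);
        if (f.may_unpair(j)) {
          int cand = add_e(a.ML[a.idx(i, j - 1)], ML_BASE37);
          if (cand < best) best = cand;
        }
        if (f.can_pair(i, j)) {
          int cand = add_e(a.V[a.idx(i, j)], f.ml_branch(i, j));
          if (cand < best) best = cand;
        }
        for (int k = i + 1; k <= j; ++k) {
          int cand = add_e(a.ML[a.idx(i, k - 1)], a.M1[a.idx(k, j)]);
          if (cand < best) best = cand;
        }
        a.ML[a.idx(i, j)] = best;
      }
    }
  }
  // exterior
  a.W[0] = 0;
  for (int j = 1; j <= n; ++j) {
    int best = INF_E;
    if (f.may_unpair(j)) best = a.W[j - 1];
    for (int k = 1; k <= j - f.md.minloop - 1; ++k) {
      if (!f.can_pair(k, j)) continue;
      int cand = add_e(a.W[k - 1], add_e(a.V[a.idx(k, j)], f.ext_branch(k, j)));
      if (cand < best) best = cand;
    }
    a.W[j] = best;
  }
}

// traceback helpers: candidate order matches the fill; the first exact match
// wins, which prefers inner pairs with smallest i (then smallest j).
static void trace_v(const Fold& f, const MfeArrays& a, int i, int j, std::vector<int>& pt_out);

// unwind an M1 entry: branch starts at i, trailing unpaired up to j
static void trace_m1(const Fold& f, const MfeArrays& a, int i, int j, std::vector<int>& pt_out) {
  int em = a.M1[a.idx(i, j)];
  while (!(f.can_pair(i, j) &&
           em == add_e(a.V[a.idx(i, j)], f.ml_branch(i, j)))) {
    j--;
    em -= ML_BASE37;
    if (j <= i) stop("M1 traceback failed"); // LCOV_EXCL_LINE
  }
  trace_v(f, a, i, j, pt_out);
}

static void trace_ml(const Fold& f, const MfeArrays& a, int i, int j, std::vector<int>& pt_out) {
  while (i <= j) {
    int e = a.ML[a.idx(i, j)];
    if (f.can_pair(i, j) &&
        e == add_e(a.V[a.idx(i, j)], f.ml_branch(i, j))) {
      trace_v(f, a, i, j, pt_out);
      return;
    }
    for (int k = i + 1; k <= j; ++k) {
      if (e == add_e(a.ML[a.idx(i, k - 1)], a.M1[a.idx(k, j)])) {
        trace_ml(f, a, i, k - 1, pt_out);
        trace_m1(f, a, k, j, pt_out);
        return;
      }
    }
    if (f.may_unpair(i) && e == add_e(a.ML[a.idx(i + 1, j)], ML_BASE37)) { i++; continue; }
    if (f.may_unpair(j) && e == add_e(a.ML[a.idx(i, j - 1)], ML_BASE37)) { j--; continue; }
    stop("multiloop traceback failed"); // LCOV_EXCL_LINE
  }
}

static void trace_v(const Fold& f, const MfeArrays& a, int i, int j, std::vector<int>& pt_out) {
  pt_out[i] = j; pt_out[j] = i;
  int e = a.V[a.idx(i, j)];
  int pt = f.ptype(i, j);
  int kmax = std::min(i + MAXLOOP + 1, j - f.md.minloop - 2);
  for (int k = i + 1; k <= kmax; ++k) {
    if (!f.free_region(i + 1, k - 1)) break;
    int n1 = k - i - 1;
    int lmin = std::max(k + f.md.minloop + 1, j - 1 - (MAXLOOP - n1));
    for (int l = lmin; l <= j - 1; ++l) {
      if (!f.can_pair(k, l)) continue;
      if (!f.free_region(l + 1, j - 1)) continue;
      int ei = e_intloop(n1, j - l - 1, pt, f.ptype(k, l));
      if (e == add_e(scale_e(f.md, ei, j - i), a.V[a.idx(k, l)])) {
        trace_v(f, a, k, l, pt_out);
        return;
      }
    }
  }
  if (f.free_region(i + 1, j - 1) &&
      e == scale_e(f.md, e_hairpin(j - i - 1, pt), j - i)) return;
  int close = f.ml_closing(i, j);
  for (int k = i + 2; k <= j - 2; ++k) {
    if (e == add_e(close, add_e(a.ML[a.idx(i + 1, k - 1)], a.M1[a.idx(k, j - 1)]))) {
      trace_ml(f, a, i + 1, k - 1, pt_out);
      trace_m1(f, a, k, j - 1, pt_out);
      return;
    }
  }
  stop("pair traceback failed"); // LCOV_EXCL_LINE
}

static Model model_from_list(const List& par) {
  Model md;
  md.minloop = as<int>(par["min_loop"]);
  std::string dg = as<std::string>(par["dangles"]);
  md.dangles = (dg == "none") ? 0 : 1;
  md.temperature = as<double>(par["temperature"]);
  md.alpha = par.containsElementNamed("alpha") ? as<double>(par["alpha"]) : 0.0;
  md.tau = par.containsElementNamed("tau") ? as<double>(par["tau"]) : 640.0;
  return md;
}

// [[Rcpp::export]]
List rsw_fold(IntegerVector seq, List par,
              LogicalVector forced_unpaired, LogicalVector forced_paired) {
  Model md = model_from_list(par);
  Fold f(seq, md, forced_unpaired, forced_paired);
  MfeArrays a;
  mfe_fill(f, a);
  int n = f.n;
  if (a.W[n] >= INF_E) stop("constraints admit no structure");
  std::vector<int> pt(n + 2, 0);
  // exterior traceback, 5'-most pairing preferred
  int j = n;
  while (j > 0) {
    int e = a.W[j];
    bool paired = false;
    for (int k = 1; k <= j - md.minloop - 1 && !paired; ++k) {
      if (!f.can_pair(k, j)) continue;
      if (e == add_e(a.W[k - 1], add_e(a.V[a.idx(k, j)], f.ext_branch(k, j)))) {
        trace_v(f, a, k, j, pt);
        j = k - 1;
        paired = true;
      }
    }
    if (!paired) j--;
  }
  IntegerVector pairs(n);
  std::string db(n, '.');
  for (int i = 1; i <= n; ++i) {
    pairs[i - 1] = pt[i];
    if (pt[i] > i) db[i - 1] = '(';
    else if (pt[i] && pt[i] < i) db[i - 1] = ')';
  }
  return List::create(_["energy"] = a.W[n] / 100.0,
                      _["dot_bracket"] = db,
                      _["pairs"] = pairs);
}

// --------------------------------------------------------------------------
// explicit-structure scorer (loop decomposition over a given pair table;
// shares the parameter table but is independent of the DP recursions)

static int score_closed(const Fold& f, const std::vector<int>& pt, int i, int j) {
  int ptij = f.ptype(i, j);
  if (ptij == 0) stop("structure contains a non-pairable base pair");
  std::vector<std::pair<int, int> > kids;
  int u = i + 1;
  int unpaired = 0;
  while (u < j) {
    if (pt[u] > u) { kids.push_back(std::make_pair(u, pt[u])); u = pt[u] + 1; }
    else if (pt[u] == 0) { unpaired++; u++; }
    else stop("structure is not properly nested");
  }
  if (kids.empty())
    return scale_e(f.md, e_hairpin(j - i - 1, ptij), j - i);
  if (kids.size() == 1) {
    int k = kids[0].first, l = kids[0].second;
    int e = e_intloop(k - i - 1, j - l - 1, ptij, f.ptype(k, l));
    return add_e(scale_e(f.md, e, j - i), score_closed(f, pt, k, l));
  }
  int e = f.ml_closing(i, j);
  e = add_e(e, ML_BASE37 * unpaired);
  for (size_t b = 0; b < kids.size(); ++b) {
    e = add_e(e, f.ml_branch(kids[b].first, kids[b].second));
    e = add_e(e, score_closed(f, pt, kids[b].first, kids[b].second));
  }
  return e;
}

static int score_structure(const Fold& f, const std::vector<int>& pt) {
  int e = 0;
  int u = 1;
  while (u <= f.n) {
    if (pt[u] > u) {
      e = add_e(e, f.ext_branch(u, pt[u]));
      e = add_e(e, score_closed(f, pt, u, pt[u]));
      u = pt[u] + 1;
    } else if (pt[u] == 0) u++;
    else stop("structure is not properly nested");
  }
  return e;
}

// [[Rcpp::export]]
double rsw_energy(IntegerVector seq, IntegerVector pairs, List par) {
  Model md = model_from_list(par);
  LogicalVector none(0);
  Fold f(seq, md, none, none);
  int n = f.n;
  std::vector<int> pt(n + 2, 0);
  for (int i = 1; i <= n; ++i) {
    pt[i] = pairs[i - 1];
    if (pt[i] < 0 || pt[i] > n || (pt[i] && pairs[pt[i] - 1] != i))
      stop("inconsistent pair table");
    if (pt[i] && std::abs(pt[i] - i) <= md.minloop)
      stop("pair violates the minimum loop size");
  }
  int e = score_structure(f, pt);
  return (e >= INF_E) ? NA_REAL : e / 100.0;
}

// --------------------------------------------------------------------------
// exhaustive enumeration (test oracle for small n)

static void enum_all(const Fold& f, int i, std::vector<int>& pt,
                     std::vector<std::string>& dbs, std::vector<double>& es, int cap) {
  int n = f.n;
  if (i > n) {
    for (int u = 1; u <= n; ++u)
      if (f.fpair[u] && pt[u] == 0) return; // forced-paired base left open
    std::string db(n, '.');
    for (int u = 1; u <= n; ++u) {
      if (pt[u] > u) db[u - 1] = '(';
      else if (pt[u] && pt[u] < u) db[u - 1] = ')';
    }
    int e = score_structure(f, pt);
    if (e < INF_E) {
      if ((int) dbs.size() >= cap) stop("structure count exceeds enumeration cap");
      dbs.push_back(db);
      es.push_back(e / 100.0);
    }
    return;
  }
  if (pt[i] != 0) { enum_all(f, i + 1, pt, dbs, es, cap); return; }
  // option 1: i unpaired
  enum_all(f, i + 1, pt, dbs, es, cap);
  // option 2: pair i with j, bounded by the nearest enclosing fixed pair so
  // that no crossing can arise (all fixed pairs start left of i)
  int limit = n;
  int u = i - 1;
  while (u >= 1) {
    if (pt[u] == 0) { u--; continue; }
    if (pt[u] > i) { limit = pt[u] - 1; break; }
    u = pt[u] - 1; // skip a completed region entirely left of i
  }
  for (int j = i + f.md.minloop + 1; j <= limit; ++j) {
    if (pt[j] != 0) continue;
    if (!f.can_pair(i, j)) continue;
    pt[i] = j; pt[j] = i;
    enum_all(f, i + 1, pt, dbs, es, cap);
    pt[i] = 0; pt[j] = 0;
  }
}

// [[Rcpp::export]]
List rsw_enumerate(IntegerVector seq, List par,
                   LogicalVector forced_unpaired, LogicalVector forced_paired,
                   int cap) {
  Model md = model_from_list(par);
  Fold f(seq, md, forced_unpaired, forced_paired);
  std::vector<int> pt(f.n + 2, 0);
  std::vector<std::string> dbs;
  std::vector<double> es;
  enum_all(f, 1, pt, dbs, es, cap);
  return List::create(_["dot_bracket"] = wrap(dbs), _["energy"] = wrap(es));
}

// --------------------------------------------------------------------------
// partition function (McCaskill) with base-pair probabilities.
// Arrays are rescaled per-nucleotide (anchored at the MFE) so no overflow
// occurs for n <= 200; reported quantities are ratios or corrected log-sums.

struct PfArrays {
  int n;
  std::vector<double> QB, QM, QM1;
  std::vector<double> Q, Qr;
  inline int idx(int i, int j) const { return i * (n + 2) + j; }
};

// [[Rcpp::export]]
List rsw_partition(IntegerVector seq, List par,
                   LogicalVector forced_unpaired, LogicalVector forced_paired,
                   bool want_bpp) {
  Model md = model_from_list(par);
  if (md.alpha != 0.0) stop("partition function is defined for the equilibrium model");
  Fold f(seq, md, forced_unpaired, forced_paired);
  int n = f.n;
  double rt = md.rt();

  // anchor the per-nucleotide scale at the MFE
  MfeArrays ma;
  mfe_fill(f, ma);
  if (ma.W[n] >= INF_E) stop("constraints admit no structure");
  double mfe = ma.W[n] / 100.0;
  double lnsc = (n > 0) ? (-1.07 * mfe / (rt * n)) : 0.0;
  if (lnsc < 0) lnsc = 0;
  std::vector<double> scpow(2 * n + 2);
  for (int m = 0; m <= 2 * n + 1; ++m) scpow[m] = std::exp(-lnsc * m);
  double scinv = scpow[1];

  PfArrays q;
  q.n = n;
  q.QB.assign((n + 2) * (n + 2), 0.0);
  q.QM.assign((n + 2) * (n + 2), 0.0);
  q.QM1.assign((n + 2) * (n + 2), 0.0);
  q.Q.assign(n + 2, 0.0);
  q.Qr.assign(n + 3, 0.0);

  #define EXPE(e) std::exp(-((double)(e)) / 100.0 / rt)

  for (int d = md.minloop + 1; d < n; ++d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      if (f.can_pair(i, j)) {
        int pt = f.ptype(i, j);
        double sum = 0.0;
        int kmax = std::min(i + MAXLOOP + 1, j - md.minloop - 2);
        for (int k = i + 1; k <= kmax; ++k) {
          if (!f.free_region(i + 1, k - 1)) break;
          int n1 = k - i - 1;
          int lmin = std::max(k + md.minloop + 1, j - 1 - (MAXLOOP - n1));
          for (int l = lmin; l <= j - 1; ++l) {
            if (!f.can_pair(k, l)) continue;
            if (!f.free_region(l + 1, j - 1)) continue;
            int e = e_intloop(n1, j - l - 1, pt, f.ptype(k, l));
            if (e >= INF_E) continue;
            sum += EXPE(e) * q.QB[q.idx(k, l)] * scpow[n1 + (j - l - 1) + 2];
          }
        }
        if (f.free_region(i + 1, j - 1)) {
          int eh = e_hairpin(j - i - 1, pt);
          if (eh < INF_E) sum += EXPE(eh) * scpow[j - i + 1];
        }
        {
          double close = EXPE(f.ml_closing(i, j)) * scpow[2];
          double msum = 0.0;
          for (int k = i + 2; k <= j - 2; ++k)
            msum += q.QM[q.idx(i + 1, k - 1)] * q.QM1[q.idx(k, j - 1)];
          sum += close * msum;
        }
        q.QB[q.idx(i, j)] = sum;
      }
      // QM1(i,j): branch starts at i, trailing unpaired to j
      {
        double sum = 0.0;
        double trail = 1.0;
        for (int l = j; l >= i + md.minloop + 1; --l) {
          if (f.can_pair(i, l) && q.QB[q.idx(i, l)] > 0)
            sum += q.QB[q.idx(i, l)] * EXPE(f.ml_branch(i, l)) * trail;
          if (!f.may_unpair(l)) break;
          trail *= EXPE(ML_BASE37) * scinv;
        }
        q.QM1[q.idx(i, j)] = sum;
      }
      // QM(i,j): >= 1 branch; parsed by the start k of the last branch
      {
        double sum = 0.0;
        double lead = 1.0;
        bool lead_ok = true;
        for (int k = i; k <= j; ++k) {
          double m1 = q.QM1[q.idx(k, j)];
          if (m1 > 0) {
            if (lead_ok) sum += lead * m1;
            if (k > i) sum += q.QM[q.idx(i, k - 1)] * m1;
          }
          if (!f.may_unpair(k)) lead_ok = false;
          lead *= EXPE(ML_BASE37) * scinv;
        }
        q.QM[q.idx(i, j)] = sum;
      }
    }
  }
  // exterior prefix / suffix
  q.Q[0] = 1.0;
  for (int j = 1; j <= n; ++j) {
    double sum = f.may_unpair(j) ? q.Q[j - 1] * scinv : 0.0;
    for (int k = 1; k <= j - md.minloop - 1; ++k) {
      if (!f.can_pair(k, j)) continue;
      double qb = q.QB[q.idx(k, j)];
      if (qb > 0) sum += q.Q[k - 1] * qb * EXPE(f.ext_branch(k, j));
    }
    q.Q[j] = sum;
  }
  q.Qr[n + 1] = 1.0;
  for (int i = n; i >= 1; --i) {
    double sum = f.may_unpair(i) ? q.Qr[i + 1] * scinv : 0.0;
    for (int l = i + md.minloop + 1; l <= n; ++l) {
      if (!f.can_pair(i, l)) continue;
      double qb = q.QB[q.idx(i, l)];
      if (qb > 0) sum += qb * EXPE(f.ext_branch(i, l)) * q.Qr[l + 1];
    }
    q.Qr[i] = sum;
  }

  double Zred = q.Q[n];
  if (!(Zred > 0)) stop("constraints admit no structure");
  double lnZ = std::log(Zred) + lnsc * n;
  double gE = -rt * lnZ;

  List out = List::create(_["lnZ"] = lnZ,
                          _["ensemble_energy"] = gE,
                          _["mfe"] = mfe);
  if (!want_bpp) return out;

  // outside pass; OB(i,j) is the outside weight reduced by sc^-(n-(j-i+1))
  std::vector<double> OB((n + 2) * (n + 2), 0.0);
  NumericMatrix P(n, n);
  for (int d = n - 1; d >= md.minloop + 1; --d) {
    for (int i = 1; i + d <= n; ++i) {
      int j = i + d;
      if (!f.can_pair(i, j) || q.QB[q.idx(i, j)] <= 0) continue;
      double ob = q.Q[i - 1] * q.Qr[j + 1] * EXPE(f.ext_branch(i, j));
      // enclosed as the inner pair of an interior loop closed by (k,l)
      int ptin = f.ptype(i, j);
      int kmin = std::max(1, i - MAXLOOP - 1);
      for (int k = kmin; k <= i - 1; ++k) {
        if (!f.free_region(k + 1, i - 1)) continue;
        int n1 = i - k - 1;
        int lmax = std::min(n, j + 1 + (MAXLOOP - n1));
        for (int l = j + 1; l <= lmax; ++l) {
          if (!f.can_pair(k, l)) continue;
          double obkl = OB[q.idx(k, l)];
          if (obkl <= 0) continue;
          if (!f.free_region(j + 1, l - 1)) continue;
          int e = e_intloop(n1, l - j - 1, f.ptype(k, l), ptin);
          if (e >= INF_E) continue;
          ob += obkl * EXPE(e) * scpow[n1 + (l - j - 1) + 2];
        }
      }
      // as one branch of a multiloop closed by (k,l)
      double brm = EXPE(f.ml_branch(i, j));
      for (int k = 1; k <= i - 1; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          if (!f.can_pair(k, l)) continue;
          double obkl = OB[q.idx(k, l)];
          if (obkl <= 0) continue;
          double close = EXPE(f.ml_closing(k, l)) * scpow[2];
          double left_qm = q.QM[q.idx(k + 1, i - 1)];
          double right_qm = q.QM[q.idx(j + 1, l - 1)];
          double left_un = f.free_region(k + 1, i - 1)
            ? std::pow(EXPE(ML_BASE37) * scinv, i - 1 - k) : 0.0;
          double right_un = f.free_region(j + 1, l - 1)
            ? std::pow(EXPE(ML_BASE37) * scinv, l - 1 - j) : 0.0;
          double inner = left_qm * right_qm + left_qm * right_un + left_un * right_qm;
          if (inner > 0) ob += obkl * close * brm * inner;
        }
      }
      OB[q.idx(i, j)] = ob;
      double p = q.QB[q.idx(i, j)] * ob / Zred;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
    }
  }
  out["bpp"] = P;
  return out;
}

// --------------------------------------------------------------------------
// small accessors for the duplex (two-strand) energy computed in R

// [[Rcpp::export]]
int rsw_pair_code(int a, int b) { return PAIR_TYPE[a][b]; }

// [[Rcpp::export]]
double rsw_stack_energy(int p1, int p2) {
  if (p1 < 1 || p1 > 6 || p2 < 1 || p2 > 6) stop("invalid pair code");
  return STACK37[p1][p2] / 100.0;
}

// [[Rcpp::export]]
double rsw_internal_energy(int n1, int n2, int p_out, int p_in) {
  int e = e_intloop(n1, n2, p_out, p_in);
  return (e >= INF_E) ? NA_REAL : e / 100.0;
}

// [[Rcpp::export]]
double rsw_terminal_au(int p) { return term_au(p) / 100.0; }
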