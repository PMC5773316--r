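// Native quartet maximum-likelihood engine under JC69.
//
// Alignments are summarised as counts over the 256 possible ungapped
// four-taxon site patterns (index = sA + 4*sB + 16*sC + 64*sO, states
// A=0, C=1, G=2, T=3).  For each of the three unrooted quartet
// topologies the five branch lengths are optimised by cyclic
// one-dimensional Brent minimisation of the negative log-likelihood,
// computed by explicit summation over the two internal-node states
// (Felsenstein pruning specialised to four taxa).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// cherry pair / far pair per topology: 0 = AB | CO, 1 = AC | BO, 2 = BC | AO
static const int CHERRY[3][2] = {{0, 1}, {0, 2}, {1, 2}};
static const int FARPAIR[3][2] = {{2, 3}, {1, 3}, {0, 3}};

struct PatternData {
  std::vector<int> st[4];      // state of taxon 0..3 per retained pattern
  std::vector<double> cnt;     // pattern count
};

static PatternData unpack_counts(const NumericVector &counts256) {
  PatternData pd;
  if (counts256.size() != 256)
    stop("pattern count vector must have length 256");
  for (int i = 0; i < 256; ++i) {
    double c = counts256[i];
    if (c > 0) {
      pd.st[0].push_back(i & 3);
      pd.st[1].push_back((i >> 2) & 3);
      pd.st[2].push_back((i >> 4) & 3);
      pd.st[3].push_back((i >> 6) & 3);
      pd.cnt.push_back(c);
    }
  }
  return pd;
}

// JC69 log-likelihood of one topology given 5 branch lengths
// (bl[0..3] = tip branches of taxa A,B,C,O; bl[4] = internal branch).
// Pattern probabilities given u_e = exp(-4 t_e / 3) per edge.  The site
// probability is multilinear in the u_e, which the optimiser exploits.
static void pattern_probs_u(const PatternData &pd, int topo, const double *u,
                            std::vector<double> &out) {
  double same[5], diff[5];
  for (int e = 0; e < 5; ++e) {
    same[e] = 0.25 + 0.75 * u[e];
    diff[e] = 0.25 - 0.25 * u[e];
  }
  const int p = CHERRY[topo][0], q = CHERRY[topo][1];
  const int r = FARPAIR[topo][0], s = FARPAIR[topo][1];
  const size_t n = pd.cnt.size();
  out.resize(n);
  for (size_t i = 0; i < n; ++i) {
    const int sp = pd.st[p][i], sq = pd.st[q][i];
    const int sr = pd.st[r][i], ss = pd.st[s][i];
    double prob = 0.0;
    for (int x = 0; x < 4; ++x) {
      double l1 = (x == sp ? same[p] : diff[p]) * (x == sq ? same[q] : diff[q]);
      double inner = 0.0;
      for (int y = 0; y < 4; ++y) {
        double l2 = (y == sr ? same[r] : diff[r]) * (y == ss ? same[s] : diff[s]);
        inner += (x == y ? same[4] : diff[4]) * l2;
      }
      prob += l1 * inner;
    }
    out[i] = 0.25 * prob;
  }
}

static double lnl_topology(const PatternData &pd, int topo, const double *bl) {
  double same[5], diff[5];
  for (int e = 0; e < 5; ++e) {
    double x = std::exp(-4.0 * bl[e] / 3.0);
    same[e] = 0.25 + 0.75 * x;   // same-state transition prob
    diff[e] = 0.25 - 0.25 * x;   // each of the 3 different states
  }
  const int p = CHERRY[topo][0], q = CHERRY[topo][1];
  const int r = FARPAIR[topo][0], s = FARPAIR[topo][1];
  double lnl = 0.0;
  const size_t n = pd.cnt.size();
  for (size_t i = 0; i < n; ++i) {
    const int sp = pd.st[p][i], sq = pd.st[q][i];
    const int sr = pd.st[r][i], ss = pd.st[s][i];
    double prob = 0.0;
    for (int x = 0; x < 4; ++x) {
      double l1 = (x == sp ? same[p] : diff[p]) * (x == sq ? same[q] : diff[q]);
      double inner = 0.0;
      for (int y = 0; y < 4; ++y) {
        double l2 = (y == sr ? same[r] : diff[r]) * (y == ss ? same[s] : diff[s]);
        inner += (x == y ? same[4] : diff[4]) * l2;
      }
      prob += l1 * inner;
    }
    lnl += pd.cnt[i] * std::log(0.25 * prob);
  }
  return lnl;
}

// Brent's one-dimensional minimiser on [a, b] (derivative-free).
template <typename F>
static double brent_min(F f, double a, double b, double tol, double *fmin) {
  const double golden = 0.3819660112501051;
  const double eps = 1e-12;
  double x = a + golden * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + eps;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool use_golden = true;
    if (std::fabs(e) > tol1) {
      double rr = (x - w) * (fx - fv);
      double qq = (x - v) * (fx - fw);
      double pp = (x - v) * qq - (x - w) * rr;
      qq = 2.0 * (qq - rr);
      if (qq > 0.0) pp = -pp;
      qq = std::fabs(qq);
      double etemp = e;
      e = d;
      if (std::fabs(pp) < std::fabs(0.5 * qq * etemp) &&
          pp > qq * (a - x) && pp < qq * (b - x)) {
        d = pp / qq;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x ? tol1 : -tol1);
        use_golden = false;
      }
    }
    if (use_golden) {
      e = (x >= xm ? a - x : b - x);
      d = golden * e;
    }
    double u = (std::fabs(d) >= tol1 ? x + d : x + (d >= 0 ? tol1 : -tol1));
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        v = w; w = u; fv = fw; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  *fmin = fx;
  return x;
}

// JC distance matrix from pattern counts, capped for starting values.
static void jc_dist_init(const PatternData &pd, double dist[4][4]) {
  double tot = 0.0;
  for (double c : pd.cnt) tot += c;
  for (int i = 0; i < 4; ++i)
    for (int j = i + 1; j < 4; ++j) {
      double mism = 0.0;
      for (size_t k = 0; k < pd.cnt.size(); ++k)
        if (pd.st[i][k] != pd.st[j][k]) mism += pd.cnt[k];
      double p = (tot > 0 ? mism / tot : 0.0);
      double d;
      if (p >= 0.70) d = 2.0;            // near saturation: flat start
      else d = -0.75 * std::log(1.0 - 4.0 * p / 3.0);
      dist[i][j] = dist[j][i] = d;
      dist[i][i] = 0.0;
    }
  dist[3][3] = 0.0;
}

static double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Optimise the 5 branch lengths of one topology by cyclic Brent sweeps.
// For each coordinate the site probabilities are linear in
// u = exp(-4 t / 3), so two full pattern passes (u = 0, u = 1) give
// per-pattern coefficients and every Brent evaluation is O(npatterns).
static double optimise_topology(const PatternData &pd, int topo, double *bl,
                                bool fix_internal, double tol, int max_sweeps) {
  const size_t n = pd.cnt.size();
  std::vector<double> p_u0(n), p_u1(n);
  double lnl = lnl_topology(pd, topo, bl);
  int ncoord = fix_internal ? 4 : 5;
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double prev = lnl;
    for (int c = 0; c < ncoord; ++c) {
      double u[5];
      for (int e = 0; e < 5; ++e) u[e] = std::exp(-4.0 * bl[e] / 3.0);
      u[c] = 0.0;
      pattern_probs_u(pd, topo, u, p_u0);
      u[c] = 1.0;
      pattern_probs_u(pd, topo, u, p_u1);
      auto f = [&](double v) {
        double uc = std::exp(-4.0 * v / 3.0);
        double s = 0.0;
        for (size_t i = 0; i < n; ++i) {
          double prob = p_u0[i] + (p_u1[i] - p_u0[i]) * uc;
          s += pd.cnt[i] * std::log(prob > 1e-300 ? prob : 1e-300);
        }
        return -s;
      };
      double fmin;
      double xbest = brent_min(f, 0.0, 10.0, tol, &fmin);
      double f0 = f(0.0);                 // boundary may beat the interior
      if (f0 <= fmin) { xbest = 0.0; fmin = f0; }
      if (-fmin >= lnl) { bl[c] = xbest; lnl = -fmin; }
    }
    if (lnl - prev < 1e-9) break;
  }
  return lnl;
}

//' @noRd
// [[Rcpp::export(name = ".quartet_ml_fit_cpp")]]
List quartet_ml_fit_cpp(NumericVector counts256, double tol = 1e-8,
                        int max_sweeps = 60) {
  PatternData pd = unpack_counts(counts256);
  if (pd.cnt.empty()) stop("no comparable sites");
  double dist[4][4];
  jc_dist_init(pd, dist);
  NumericVector lnl(3);
  NumericMatrix branch(3, 5);
  for (int topo = 0; topo < 3; ++topo) {
    const int p = CHERRY[topo][0], q = CHERRY[topo][1];
    const int r = FARPAIR[topo][0], s = FARPAIR[topo][1];
    double bl[5];
    bl[p] = clampd(dist[p][q] / 2.0, 1e-6, 5.0);
    bl[q] = bl[p];
    bl[r] = clampd(dist[r][s] / 2.0, 1e-6, 5.0);
    bl[s] = bl[r];
    double v = 0.25 * (dist[p][r] + dist[p][s] + dist[q][r] + dist[q][s]) -
               0.5 * (dist[p][q] + dist[r][s]);
    bl[4] = clampd(v, 1e-6, 5.0);
    lnl[topo] = optimise_topology(pd, topo, bl, false, tol, max_sweeps);
    for (int e = 0; e < 5; ++e) branch(topo, e) = bl[e];
  }
  return List::create(_["lnl"] = lnl, _["branch"] = branch,
                      _["n_patterns"] = (int)pd.cnt.size());
}

//' @noRd
// [[Rcpp::export(name = ".quartet_lnl_cpp")]]
double quartet_lnl_cpp(NumericVector counts256, int topo, NumericVector bl) {
  if (topo < 1 || topo > 3) stop("topo must be 1, 2 or 3");
  if (bl.size() != 5) stop("bl must have length 5");
  PatternData pd = unpack_counts(counts256);
  if (pd.cnt.empty()) stop("no comparable sites");
  double b[5];
  for (int i = 0; i < 5; ++i) b[i] = bl[i];
  return lnl_topology(pd, topo - 1, b);
}

//' @noRd
// [[Rcpp::export(name = ".quartet_star_lnl_cpp")]]
double quartet_star_lnl_cpp(NumericVector counts256, double tol = 1e-8) {
  PatternData pd = unpack_counts(counts256);
  if (pd.cnt.empty()) stop("no comparable sites");
  double dist[4][4];
  jc_dist_init(pd, dist);
  double bl[5];
  for (int i = 0; i < 4; ++i) {
    double m = 0.0;
    for (int j = 0; j < 4; ++j) if (j != i) m += dist[i][j];
    bl[i] = clampd(m / 6.0, 1e-6, 5.0);
  }
  bl[4] = 0.0;
  return optimise_topology(pd, 0, bl, true, tol, 60);
}
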