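// Constrained three-parameter decreasing sigmoid fit
//   E_fit(M) = a / (1 + exp(b * (M - c))),  a in [0, 200], b >= 0,
//   c in [-50, 150]
// The amplitude a is profiled out in closed form (linear least squares
// given the shape), leaving a 2-D search over (b, c) done by Nelder-Mead
// from multiple deterministic starts plus a coarse grid. Written in C++
// because the permutation test refits the curve thousands of times per
// association.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double B_LO = 0.0, B_HI = 100.0;
static const double C_LO = -50.0, C_HI = 150.0;
static const double A_LO = 0.0, A_HI = 200.0;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// SSE at (b, c) with the optimal clamped amplitude a
static double profiled_sse(double b, double c,
                           const std::vector<double>& M,
                           const std::vector<double>& E,
                           double& a_out) {
  b = clampd(b, B_LO, B_HI);
  c = clampd(c, C_LO, C_HI);
  const int n = (int)M.size();
  double num = 0.0, den = 0.0;
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    double z = b * (M[i] - c);
    double gi;
    if (z > 700.0) gi = 0.0;
    else if (z < -700.0) gi = 1.0;
    else gi = 1.0 / (1.0 + std::exp(z));
    g[i] = gi;
    num += E[i] * gi;
    den += gi * gi;
  }
  double a = (den > 0.0) ? num / den : 0.0;
  a = clampd(a, A_LO, A_HI);
  double sse = 0.0;
  for (int i = 0; i < n; ++i) {
    double r = a * g[i] - E[i];
    sse += r * r;
  }
  a_out = a;
  return sse;
}

struct FitOut { double a, b, c, sse; };

// 2-D Nelder-Mead on (b, c); coordinates clamped to the box after every
// move so the simplex cannot drift into the flat clamped exterior
static void nelder_mead(double b0, double c0,
                        const std::vector<double>& M,
                        const std::vector<double>& E,
                        FitOut& best) {
  const int max_iter = 200;
  const double tol = 1e-12;
  double px[3][2], pf[3], pa[3];
  double db = std::max(0.05, 0.5 * b0), dc = 10.0;
  px[0][0] = b0;      px[0][1] = c0;
  px[1][0] = b0 + db; px[1][1] = c0;
  px[2][0] = b0;      px[2][1] = c0 + dc;
  for (int i = 0; i < 3; ++i) {
    px[i][0] = clampd(px[i][0], B_LO, B_HI);
    px[i][1] = clampd(px[i][1], C_LO, C_HI);
    pf[i] = profiled_sse(px[i][0], px[i][1], M, E, pa[i]);
  }
  for (int it = 0; it < max_iter; ++it) {
    // order: 0 best, 2 worst
    for (int i = 0; i < 2; ++i)
      for (int j = i + 1; j < 3; ++j)
        if (pf[j] < pf[i]) {
          std::swap(pf[i], pf[j]); std::swap(pa[i], pa[j]);
          std::swap(px[i][0], px[j][0]); std::swap(px[i][1], px[j][1]);
        }
    if (pf[2] - pf[0] <= tol * (std::fabs(pf[0]) + tol)) break;
    double cb = 0.5 * (px[0][0] + px[1][0]);
    double cc = 0.5 * (px[0][1] + px[1][1]);
    // reflection
    double rb = clampd(cb + (cb - px[2][0]), B_LO, B_HI);
    double rc = clampd(cc + (cc - px[2][1]), C_LO, C_HI);
    double ra, rf = profiled_sse(rb, rc, M, E, ra);
    if (rf < pf[0]) {
      // expansion
      double eb = clampd(cb + 2.0 * (cb - px[2][0]), B_LO, B_HI);
      double ec = clampd(cc + 2.0 * (cc - px[2][1]), C_LO, C_HI);
      double ea, ef = profiled_sse(eb, ec, M, E, ea);
      if (ef < rf) { px[2][0] = eb; px[2][1] = ec; pf[2] = ef; pa[2] = ea; }
      else         { px[2][0] = rb; px[2][1] = rc; pf[2] = rf; pa[2] = ra; }
    } else if (rf < pf[1]) {
      px[2][0] = rb; px[2][1] = rc; pf[2] = rf; pa[2] = ra;
    } else {
      // contraction
      double kb = clampd(cb + 0.5 * (px[2][0] - cb), B_LO, B_HI);
      double kc = clampd(cc + 0.5 * (px[2][1] - cc), C_LO, C_HI);
      double ka, kf = profiled_sse(kb, kc, M, E, ka);
      if (kf < pf[2]) { px[2][0] = kb; px[2][1] = kc; pf[2] = kf; pa[2] = ka; }
      else {
        // shrink toward best
        for (int i = 1; i < 3; ++i) {
          px[i][0] = clampd(px[0][0] + 0.5 * (px[i][0] - px[0][0]), B_LO, B_HI);
          px[i][1] = clampd(px[0][1] + 0.5 * (px[i][1] - px[0][1]), C_LO, C_HI);
          pf[i] = profiled_sse(px[i][0], px[i][1], M, E, pa[i]);
        }
      }
    }
  }
  for (int i = 0; i < 3; ++i)
    if (pf[i] < best.sse) {
      best.sse = pf[i]; best.a = pa[i]; best.b = px[i][0]; best.c = px[i][1];
    }
}

static FitOut fit_one(const std::vector<double>& M,
                      const std::vector<double>& E,
                      const std::vector<double>& b_starts,
                      const std::vector<double>& c_starts) {
  FitOut best; best.sse = R_PosInf; best.a = 0; best.b = 0; best.c = 0;

  // coarse deterministic grid; the two best cells seed extra local searches
  static const double bgrid[9] = {0.0, 0.02, 0.05, 0.1, 0.2, 0.5, 1.0,
                                  2.0, 10.0};
  double mmin = *std::min_element(M.begin(), M.end());
  double mmax = *std::max_element(M.begin(), M.end());
  double g1b = 0, g1c = 0, g2b = 0, g2c = 0;
  double g1f = R_PosInf, g2f = R_PosInf;
  for (int ib = 0; ib < 9; ++ib) {
    for (int ic = 0; ic < 9; ++ic) {
      double c = mmin + (mmax - mmin) * ic / 8.0;
      double a, f = profiled_sse(bgrid[ib], c, M, E, a);
      if (f < g1f) {
        g2f = g1f; g2b = g1b; g2c = g1c;
        g1f = f; g1b = bgrid[ib]; g1c = c;
      } else if (f < g2f) {
        g2f = f; g2b = bgrid[ib]; g2c = c;
      }
      if (f < best.sse) { best.sse = f; best.a = a; best.b = bgrid[ib]; best.c = c; }
    }
  }
  // steep-transition candidates at the midpoints between sorted M values:
  // the SSE surface has many shallow local optima of near-step shape that
  // a coarse rectangular grid misses
  std::vector<double> ms(M);
  std::sort(ms.begin(), ms.end());
  double s1b = 0, s1c = 0, s1f = R_PosInf;
  static const double bsteep[3] = {0.5, 2.0, 20.0};
  for (int ib = 0; ib < 3; ++ib) {
    for (size_t ic = 0; ic + 1 < ms.size(); ++ic) {
      if (ms[ic + 1] <= ms[ic]) continue;
      double c = 0.5 * (ms[ic] + ms[ic + 1]);
      double a, f = profiled_sse(bsteep[ib], c, M, E, a);
      if (f < s1f) { s1f = f; s1b = bsteep[ib]; s1c = c; }
      if (f < best.sse) { best.sse = f; best.a = a; best.b = bsteep[ib]; best.c = c; }
    }
  }
  for (size_t i = 0; i < b_starts.size(); ++i)
    for (size_t j = 0; j < c_starts.size(); ++j)
      nelder_mead(b_starts[i], c_starts[j], M, E, best);
  nelder_mead(g1b, g1c, M, E, best);
  nelder_mead(g2b, g2c, M, E, best);
  if (s1f < R_PosInf) nelder_mead(s1b, s1c, M, E, best);
  return best;
}

static double r_statistic(const FitOut& fit,
                          const std::vector<double>& M,
                          const std::vector<double>& E,
                          double meanE) {
  const int n = (int)M.size();
  double ssr = 0.0;
  for (int i = 0; i < n; ++i) {
    double z = fit.b * (M[i] - fit.c);
    double gi;
    if (z > 700.0) gi = 0.0;
    else if (z < -700.0) gi = 1.0;
    else gi = 1.0 / (1.0 + std::exp(z));
    double d = fit.a * gi - meanE;
    ssr += d * d;
  }
  double tot = ssr + fit.sse;
  return tot > 0.0 ? ssr / tot : 0.0;
}

// [[Rcpp::export]]
List fit_sigmoid_cpp(NumericVector M, NumericVector E,
                     NumericVector b_starts, NumericVector c_starts) {
  std::vector<double> m = as<std::vector<double>>(M);
  std::vector<double> e = as<std::vector<double>>(E);
  std::vector<double> bs = as<std::vector<double>>(b_starts);
  std::vector<double> cs = as<std::vector<double>>(c_starts);
  FitOut fit = fit_one(m, e, bs, cs);
  double meanE = 0.0;
  for (double v : e) meanE += v;
  meanE /= (double)e.size();
  double R = r_statistic(fit, m, e, meanE);
  double ssr = 0.0;
  for (size_t i = 0; i < m.size(); ++i) {
    double z = fit.b * (m[i] - fit.c);
    double gi = z > 700.0 ? 0.0 : (z < -700.0 ? 1.0 : 1.0 / (1.0 + std::exp(z)));
    double d = fit.a * gi - meanE;
    ssr += d * d;
  }
  return List::create(_["a"] = fit.a, _["b"] = fit.b, _["c"] = fit.c,
                      _["sse"] = fit.sse, _["ssr"] = ssr, _["R"] = R);
}

// Permutation null distribution of R: each draw refits the curve (same
// multi-start search) on a uniform random permutation of M against fixed
// E. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List perm_null_cpp(NumericVector M, NumericVector E, int n_perm,
                   double r_obs, NumericVector b_starts,
                   NumericVector c_starts, bool keep_null) {
  const int n = M.size();
  std::vector<double> e = as<std::vector<double>>(E);
  std::vector<double> bs = as<std::vector<double>>(b_starts);
  std::vector<double> cs = as<std::vector<double>>(c_starts);
  double meanE = 0.0;
  for (double v : e) meanE += v;
  meanE /= (double)n;
  std::vector<double> mp(n);
  NumericVector rnull(keep_null ? n_perm : 0);
  int count = 0;
  for (int it = 0; it < n_perm; ++it) {
    IntegerVector idx = Rcpp::sample(n, n); // 1-based, without replacement
    for (int i = 0; i < n; ++i) mp[i] = M[idx[i] - 1];
    FitOut fit = fit_one(mp, e, bs, cs);
    double rm = r_statistic(fit, mp, e, meanE);
    if (rm >= r_obs) ++count;
    if (keep_null) rnull[it] = rm;
  }
  return List::create(_["count"] = count, _["r_null"] = rnull);
}
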