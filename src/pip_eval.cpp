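// Fast batch evaluation of symmetrized-monomial (PIP) bases.
//
// A basis is passed down as a flat term list: E is an (n_terms x n_vars)
// integer exponent matrix, fun_id maps each term to its basis function
// (1-based, terms of one function contiguous and ascending).  Each basis
// function is the sum of its orbit's monomial terms.  Orbit terms are
// summed in sorted value order so that the result is bitwise identical
// under any permutation of the variables that maps the orbit onto itself.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// powers y^0..y^maxdeg for every variable of one point
static inline void fill_powers(const double* y, int nv, int maxdeg,
                               std::vector<double>& pw) {
  for (int v = 0; v < nv; ++v) {
    double* p = &pw[v * (maxdeg + 1)];
    p[0] = 1.0;
    for (int k = 1; k <= maxdeg; ++k) p[k] = p[k - 1] * y[v];
  }
}

// replace y by its lexicographically minimal image under the group G
// (rows of G are 1-based variable permutations): every group image of y
// maps to the same canonical vector, so all downstream arithmetic is
// bitwise identical under group permutations of the input
static inline void canonicalize(double* y, int nv, const int* G, int ng,
                                double* best) {
  for (int v = 0; v < nv; ++v) best[v] = y[v];
  for (int g = 0; g < ng; ++g) {
    const int* p = G + (size_t)g * nv;
    int cmp = 0;
    for (int v = 0; v < nv; ++v) {
      double cand = y[p[v] - 1];
      if (cand < best[v]) { cmp = -1; break; }
      if (cand > best[v]) { cmp = 1; break; }
    }
    if (cmp < 0)
      for (int v = 0; v < nv; ++v) best[v] = y[p[v] - 1];
  }
  for (int v = 0; v < nv; ++v) y[v] = best[v];
}

// [[Rcpp::export]]
NumericMatrix cpp_pip_eval(NumericMatrix Y, IntegerMatrix E,
                           IntegerVector fun_id, int n_fun,
                           IntegerMatrix G) {
  const int n = Y.nrow(), nv = Y.ncol(), nt = E.nrow(), ng = G.nrow();
  if (nt != fun_id.size()) stop("fun_id length mismatch");
  NumericMatrix out(n, n_fun);
  int maxdeg = 0;
  for (int t = 0; t < nt; ++t)
    for (int v = 0; v < nv; ++v) maxdeg = std::max(maxdeg, E(t, v));
  std::vector<int> Gflat((size_t)ng * nv);
  for (int g = 0; g < ng; ++g)
    for (int v = 0; v < nv; ++v) Gflat[(size_t)g * nv + v] = G(g, v);
  std::vector<double> pw((size_t)nv * (maxdeg + 1));
  std::vector<double> yrow(nv), ybest(nv);
  for (int i = 0; i < n; ++i) {
    for (int v = 0; v < nv; ++v) yrow[v] = Y(i, v);
    canonicalize(yrow.data(), nv, Gflat.data(), ng, ybest.data());
    fill_powers(yrow.data(), nv, maxdeg, pw);
    for (int t = 0; t < nt; ++t) {
      double val = 1.0;
      for (int v = 0; v < nv; ++v) {
        int e = E(t, v);
        if (e) val *= pw[v * (maxdeg + 1) + e];
      }
      out(i, fun_id[t] - 1) += val;
    }
  }
  return out;
}

// per-point contribution c . p(y), evaluated at the group-canonicalized
// y so the value is bitwise invariant under group permutations
// [[Rcpp::export]]
NumericVector cpp_pip_contrib(NumericMatrix Y, IntegerMatrix E,
                              IntegerVector fun_id, int n_fun,
                              NumericVector coef, IntegerMatrix G) {
  if (coef.size() != n_fun) stop("coefficient length mismatch");
  const int n = Y.nrow(), nv = Y.ncol(), nt = E.nrow(), ng = G.nrow();
  int maxdeg = 0;
  for (int t = 0; t < nt; ++t)
    for (int v = 0; v < nv; ++v) maxdeg = std::max(maxdeg, E(t, v));
  std::vector<int> Gflat((size_t)ng * nv);
  for (int g = 0; g < ng; ++g)
    for (int v = 0; v < nv; ++v) Gflat[(size_t)g * nv + v] = G(g, v);
  std::vector<double> pw((size_t)nv * (maxdeg + 1));
  std::vector<double> yrow(nv), ybest(nv);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    for (int v = 0; v < nv; ++v) yrow[v] = Y(i, v);
    canonicalize(yrow.data(), nv, Gflat.data(), ng, ybest.data());
    fill_powers(yrow.data(), nv, maxdeg, pw);
    double total = 0.0;
    for (int t = 0; t < nt; ++t) {
      double val = 1.0;
      for (int v = 0; v < nv; ++v) {
        int e = E(t, v);
        if (e) val *= pw[v * (maxdeg + 1) + e];
      }
      total += coef[fun_id[t] - 1] * val;
    }
    out[i] = total;
  }
  return out;
}

// d(c . p)/dy for every point: (n x nv)
// [[Rcpp::export]]
NumericMatrix cpp_pip_dcontrib_dy(NumericMatrix Y, IntegerMatrix E,
                                  IntegerVector fun_id, NumericVector coef) {
  const int n = Y.nrow(), nv = Y.ncol(), nt = E.nrow();
  int maxdeg = 0;
  for (int t = 0; t < nt; ++t)
    for (int v = 0; v < nv; ++v) maxdeg = std::max(maxdeg, E(t, v));
  NumericMatrix out(n, nv);
  std::vector<double> pw((size_t)nv * (maxdeg + 1));
  std::vector<double> yrow(nv);
  for (int i = 0; i < n; ++i) {
    for (int v = 0; v < nv; ++v) yrow[v] = Y(i, v);
    fill_powers(yrow.data(), nv, maxdeg, pw);
    for (int t = 0; t < nt; ++t) {
      double c = coef[fun_id[t] - 1];
      if (c == 0.0) continue;
      for (int v = 0; v < nv; ++v) {
        int e = E(t, v);
        if (!e) continue;
        double d = e * pw[v * (maxdeg + 1) + (e - 1)];
        for (int w = 0; w < nv; ++w) {
          if (w == v) continue;
          int ew = E(t, w);
          if (ew) d *= pw[w * (maxdeg + 1) + ew];
        }
        out(i, v) += c * d;
      }
    }
  }
  return out;
}

// Jacobian of every basis function at a single point: (n_fun x nv)
// [[Rcpp::export]]
NumericMatrix cpp_pip_jacobian(NumericVector y, IntegerMatrix E,
                               IntegerVector fun_id, int n_fun) {
  const int nv = y.size(), nt = E.nrow();
  int maxdeg = 0;
  for (int t = 0; t < nt; ++t)
    for (int v = 0; v < nv; ++v) maxdeg = std::max(maxdeg, E(t, v));
  NumericMatrix out(n_fun, nv);
  std::vector<double> pw((size_t)nv * (maxdeg + 1));
  fill_powers(REAL(y), nv, maxdeg, pw);
  for (int t = 0; t < nt; ++t) {
    int f = fun_id[t] - 1;
    for (int v = 0; v < nv; ++v) {
      int e = E(t, v);
      if (!e) continue;
      double d = e * pw[v * (maxdeg + 1) + (e - 1)];
      for (int w = 0; w < nv; ++w) {
        if (w == v) continue;
        int ew = E(t, w);
        if (ew) d *= pw[w * (maxdeg + 1) + ew];
      }
      out(f, v) += d;
    }
  }
  return out;
}

// Full per-spec Cartesian gradient accumulation: chain rule through the
// Morse transform and the cutoff switch, scattered onto atoms.
// edges: (nv x 2) tuple-slot indices (1-based); tuples: (t x n_slots)
// atom indices (1-based).
// [[Rcpp::export]]
NumericMatrix cpp_spec_grad(NumericMatrix xyz, IntegerMatrix tuples,
                            IntegerMatrix edges, NumericMatrix Y,
                            NumericMatrix R, NumericMatrix smat,
                            NumericMatrix dsmat, NumericVector S,
                            IntegerMatrix E, IntegerVector fun_id,
                            NumericVector coef, double lambda,
                            bool need_sw, int n_atoms) {
  const int t_n = tuples.nrow(), nv = Y.ncol(), nt = E.nrow();
  NumericMatrix grad(n_atoms, 3);
  int maxdeg = 0;
  for (int t = 0; t < nt; ++t)
    for (int v = 0; v < nv; ++v) maxdeg = std::max(maxdeg, E(t, v));
  std::vector<double> pw((size_t)nv * (maxdeg + 1));
  std::vector<double> dPdy(nv);
  for (int i = 0; i < t_n; ++i) {
    for (int v = 0; v < nv; ++v) {
      double* p = &pw[v * (maxdeg + 1)];
      p[0] = 1.0;
      for (int k = 1; k <= maxdeg; ++k) p[k] = p[k - 1] * Y(i, v);
    }
    std::fill(dPdy.begin(), dPdy.end(), 0.0);
    double P = 0.0;
    for (int t = 0; t < nt; ++t) {
      double c = coef[fun_id[t] - 1];
      if (c == 0.0) continue;
      double val = 1.0;
      for (int v = 0; v < nv; ++v) {
        int e = E(t, v);
        if (e) val *= pw[v * (maxdeg + 1) + e];
      }
      P += c * val;
      for (int v = 0; v < nv; ++v) {
        int e = E(t, v);
        if (!e) continue;
        double d = e * pw[v * (maxdeg + 1) + (e - 1)];
        for (int w = 0; w < nv; ++w) {
          if (w == v) continue;
          int ew = E(t, w);
          if (ew) d *= pw[w * (maxdeg + 1) + ew];
        }
        dPdy[v] += c * d;
      }
    }
    for (int v = 0; v < nv; ++v) {
      double gr = S[i] * dPdy[v] * (-Y(i, v) / lambda);
      if (need_sw) {
        double others = 1.0;
        for (int w = 0; w < nv; ++w)
          if (w != v) others *= smat(i, w);
        gr += P * others * dsmat(i, v);
      }
      if (gr == 0.0) continue;
      int p = tuples(i, edges(v, 0) - 1) - 1;
      int q = tuples(i, edges(v, 1) - 1) - 1;
      double inv_r = 1.0 / R(i, v);
      for (int d = 0; d < 3; ++d) {
        double u = (xyz(p, d) - xyz(q, d)) * inv_r * gr;
        grad(p, d) += u;
        grad(q, d) -= u;
      }
    }
  }
  return grad;
}
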