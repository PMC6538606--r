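#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component machinery for suprathreshold sets of t-maps on the
// time-frequency plane.  Grids are stored column-major with frequency
// varying fastest (an nf x nt matrix flattened the R way); connectivity is
// 4-neighbourhood (edge-adjacent in frequency or time, no diagonals).

// Label the positive (t > thr) and negative (t < -thr) 4-connected
// components of one t-map.  Labels are 1..K in discovery order (column-major
// scan); positive and negative components share the label sequence.
// [[Rcpp::export]]
List cpp_cluster_label(NumericMatrix tmap, double thr) {
  const int nf = tmap.nrow(), nt = tmap.ncol(), n = nf * nt;
  const double *t = REAL(tmap);
  IntegerMatrix lab(nf, nt);
  int *L = INTEGER(lab);
  std::fill(L, L + n, 0);
  std::vector<double> mass;
  std::vector<int> sgn, size;
  std::vector<int> stack;
  stack.reserve(256);
  int k = 0;
  for (int c0 = 0; c0 < n; ++c0) {
    if (L[c0]) continue;
    const int s = (t[c0] > thr) ? 1 : ((t[c0] < -thr) ? -1 : 0);
    if (!s) continue;
    ++k;
    L[c0] = k;
    double m = 0.0;
    int sz = 0;
    stack.push_back(c0);
    while (!stack.empty()) {
      const int c = stack.back();
      stack.pop_back();
      m += t[c];
      ++sz;
      const int f = c % nf, ti = c / nf;
      int nb[4];
      int nn = 0;
      if (f > 0)      nb[nn++] = c - 1;
      if (f < nf - 1) nb[nn++] = c + 1;
      if (ti > 0)     nb[nn++] = c - nf;
      if (ti < nt - 1) nb[nn++] = c + nf;
      for (int q = 0; q < nn; ++q) {
        const int cc = nb[q];
        if (!L[cc] && ((s > 0) ? (t[cc] > thr) : (t[cc] < -thr))) {
          L[cc] = k;
          stack.push_back(cc);
        }
      }
    }
    mass.push_back(m);
    sgn.push_back(s);
    size.push_back(sz);
  }
  return List::create(_["labels"] = lab, _["mass"] = wrap(mass),
                      _["sign"] = wrap(sgn), _["n_cells"] = wrap(size));
}

// For a stack of t-maps (one column per relabelling; rows = grid cells of an
// nf x (nrow/nf) grid) return per column the largest positive cluster mass
// and the most negative cluster mass (0 when a sign has no cluster).
// [[Rcpp::export]]
NumericMatrix cpp_mass_extremes(NumericMatrix tmat, int nf, double thr) {
  const int ncell = tmat.nrow(), nlab = tmat.ncol();
  if (ncell % nf != 0) stop("grid size is not a multiple of nf");
  const int nt = ncell / nf;
  NumericMatrix out(nlab, 2);
  std::vector<int> mark(ncell, -1);
  std::vector<int> stack;
  stack.reserve(256);
  for (int l = 0; l < nlab; ++l) {
    const double *t = &tmat(0, l);
    double best_p = 0.0, best_n = 0.0;
    for (int c0 = 0; c0 < ncell; ++c0) {
      if (mark[c0] == l) continue;
      const int s = (t[c0] > thr) ? 1 : ((t[c0] < -thr) ? -1 : 0);
      if (!s) continue;
      mark[c0] = l;
      double m = 0.0;
      stack.push_back(c0);
      while (!stack.empty()) {
        const int c = stack.back();
        stack.pop_back();
        m += t[c];
        const int f = c % nf, ti = c / nf;
        int nb[4];
        int nn = 0;
        if (f > 0)      nb[nn++] = c - 1;
        if (f < nf - 1) nb[nn++] = c + 1;
        if (ti > 0)     nb[nn++] = c - nf;
        if (ti < nt - 1) nb[nn++] = c + nf;
        for (int q = 0; q < nn; ++q) {
          const int cc = nb[q];
          if (mark[cc] != l && ((s > 0) ? (t[cc] > thr) : (t[cc] < -thr))) {
            mark[cc] = l;
            stack.push_back(cc);
          }
        }
      }
      if (s > 0) {
        if (m > best_p) best_p = m;
      } else {
        if (m < best_n) best_n = m;
      }
    }
    out(l, 0) = best_p;
    out(l, 1) = best_n;
  }
  return out;
}

// Per column: sum of positive cluster masses exceeding crit, and sum of
// |negative cluster masses| exceeding crit (the "sum" per-pair aggregation).
// [[Rcpp::export]]
NumericMatrix cpp_mass_sums(NumericMatrix tmat, int nf, double thr,
                            double crit) {
  const int ncell = tmat.nrow(), nlab = tmat.ncol();
  if (ncell % nf != 0) stop("grid size is not a multiple of nf");
  const int nt = ncell / nf;
  NumericMatrix out(nlab, 2);
  std::vector<int> mark(ncell, -1);
  std::vector<int> stack;
  stack.reserve(256);
  for (int l = 0; l < nlab; ++l) {
    const double *t = &tmat(0, l);
    double sum_p = 0.0, sum_n = 0.0;
    for (int c0 = 0; c0 < ncell; ++c0) {
      if (mark[c0] == l) continue;
      const int s = (t[c0] > thr) ? 1 : ((t[c0] < -thr) ? -1 : 0);
      if (!s) continue;
      mark[c0] = l;
      double m = 0.0;
      stack.push_back(c0);
      while (!stack.empty()) {
        const int c = stack.back();
        stack.pop_back();
        m += t[c];
        const int f = c % nf, ti = c / nf;
        int nb[4];
        int nn = 0;
        if (f > 0)      nb[nn++] = c - 1;
        if (f < nf - 1) nb[nn++] = c + 1;
        if (ti > 0)     nb[nn++] = c - nf;
        if (ti < nt - 1) nb[nn++] = c + nf;
        for (int q = 0; q < nn; ++q) {
          const int cc = nb[q];
          if (mark[cc] != l && ((s > 0) ? (t[cc] > thr) : (t[cc] < -thr))) {
            mark[cc] = l;
            stack.push_back(cc);
          }
        }
      }
      if (s > 0 && m > crit) sum_p += m;
      if (s < 0 && -m > crit) sum_n += -m;
    }
    out(l, 0) = sum_p;
    out(l, 1) = sum_n;
  }
  return out;
}
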