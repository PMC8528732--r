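#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Dense two-phase primal simplex with Bland's rule for problems of the form
//
//   max  c'x   s.t.  A x = b,   lb <= x <= ub   (all bounds finite)
//
// which is the shape of every flux balance problem in this package
// (S v = 0 with boxed fluxes, maximise the biomass flux).  Variables are
// shifted to y = x - lb >= 0 and the upper bounds become explicit slack
// rows y_k + s_k = u_k, giving a standard-form tableau with artificial
// variables on the (sign-normalised) equality rows.  Bland's smallest-index
// rule makes the pivot sequence fully deterministic and cycle-free, so a
// fixed model always returns the same flux vector.
//
// status: 0 optimal, 1 infeasible, 2 unbounded, 3 iteration limit

// [[Rcpp::export]]
List lpSolveDense(NumericMatrix A, NumericVector b, NumericVector cobj,
                  NumericVector lb, NumericVector ub,
                  double tol = 1e-9, int maxit = 50000) {
  const int m = A.nrow(), n = A.ncol();
  const int nrow = m + n;          // constraint rows
  const int ncol = 2 * n + m + 1;  // y | s | artificial | rhs
  const int rhs = ncol - 1;
  const int obj = nrow;            // index of the reduced-cost row

  std::vector<double> T((size_t)(nrow + 1) * ncol, 0.0);
  auto at = [&](int i, int j) -> double& { return T[(size_t)i * ncol + j]; };

  // shifted right-hand side, rows sign-normalised so rhs >= 0
  double bscale = 0.0;
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int j = 0; j < n; ++j) s -= A(i, j) * lb[j];
    double sgn = (s < 0.0) ? -1.0 : 1.0;
    for (int j = 0; j < n; ++j) at(i, j) = sgn * A(i, j);
    at(i, 2 * n + i) = 1.0;
    at(i, rhs) = sgn * s;
    bscale += std::fabs(s);
  }
  for (int k = 0; k < n; ++k) {
    at(m + k, k) = 1.0;
    at(m + k, n + k) = 1.0;
    at(m + k, rhs) = ub[k] - lb[k];
  }

  std::vector<int> basis(nrow);
  std::vector<char> active(nrow, 1);
  for (int i = 0; i < m; ++i) basis[i] = 2 * n + i;
  for (int k = 0; k < n; ++k) basis[m + k] = n + k;

  int iters = 0;
  auto pivot = [&](int prow, int pcol) {
    double piv = at(prow, pcol);
    for (int j = 0; j < ncol; ++j) at(prow, j) /= piv;
    at(prow, pcol) = 1.0;  // kill roundoff on the pivot itself
    for (int i = 0; i <= obj; ++i) {
      if (i == prow || (i < nrow && !active[i])) continue;
      double f = at(i, pcol);
      if (f == 0.0) continue;
      for (int j = 0; j < ncol; ++j) at(i, j) -= f * at(prow, j);
      at(i, pcol) = 0.0;
    }
    basis[prow] = pcol;
  };

  // Bland ratio test; returns -1 when the column is unbounded
  auto leavingRow = [&](int pcol) {
    int prow = -1;
    double best = 0.0;
    for (int i = 0; i < nrow; ++i) {
      if (!active[i]) continue;
      double a = at(i, pcol);
      if (a <= tol) continue;
      double ratio = at(i, rhs) / a;
      if (prow < 0 || ratio < best - tol ||
          (ratio < best + tol && basis[i] < basis[prow]))
        { prow = i; best = ratio; }
    }
    return prow;
  };

  // artificial columns are barred from (re-)entering in both phases
  auto runPhase = [&](void) -> int {  // 0 done, 2 unbounded, 3 maxit
    for (;;) {
      if (++iters > maxit) return 3;
      int pcol = -1;
      for (int j = 0; j < 2 * n; ++j)
        if (at(obj, j) < -tol) { pcol = j; break; }
      if (pcol < 0) return 0;
      int prow = leavingRow(pcol);
      if (prow < 0) return 2;
      pivot(prow, pcol);
    }
  };

  // ---- phase 1: minimise the sum of artificials ----
  // cost 1 on each artificial; subtract the artificial-basic rows to get
  // the reduced-cost row (artificial columns come out exactly 0)
  for (int j = 0; j < ncol; ++j) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) s += at(i, j);
    at(obj, j) = -s;
  }
  for (int i = 0; i < m; ++i) at(obj, 2 * n + i) = 0.0;

  int rc = runPhase();
  if (rc == 3) return List::create(_["status"] = 3);
  double infeas = -at(obj, rhs);
  if (infeas > tol * (1.0 + bscale))
    return List::create(_["status"] = 1);

  // drive surviving artificials out of the basis (or drop redundant rows)
  for (int i = 0; i < nrow; ++i) {
    if (!active[i] || basis[i] < 2 * n) continue;
    int pcol = -1;
    for (int j = 0; j < 2 * n; ++j)
      if (std::fabs(at(i, j)) > tol) { pcol = j; break; }
    if (pcol < 0) { active[i] = 0; continue; }
    pivot(i, pcol);
  }

  // ---- phase 2: maximise c'y  (minimise -c'y) ----
  for (int j = 0; j < ncol; ++j) at(obj, j) = 0.0;
  for (int j = 0; j < n; ++j) at(obj, j) = -cobj[j];
  for (int i = 0; i < nrow; ++i) {
    if (!active[i] || basis[i] >= n) continue;
    double f = at(obj, basis[i]);
    if (f == 0.0) continue;
    for (int j = 0; j < ncol; ++j) at(obj, j) -= f * at(i, j);
    at(obj, basis[i]) = 0.0;
  }

  rc = runPhase();
  if (rc != 0) return List::create(_["status"] = rc);

  NumericVector x(n);
  for (int j = 0; j < n; ++j) x[j] = lb[j];
  for (int i = 0; i < nrow; ++i) {
    if (!active[i]) continue;
    if (basis[i] < n) {
      double y = at(i, rhs);
      double u = ub[basis[i]] - lb[basis[i]];
      if (y < 0.0) y = 0.0;
      if (y > u) y = u;
      x[basis[i]] = lb[basis[i]] + y;
    }
  }
  double objval = 0.0;
  for (int j = 0; j < n; ++j) objval += cobj[j] * x[j];

  return List::create(_["status"] = 0, _["objective"] = objval,
                      _["x"] = x, _["iterations"] = iters);
}
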