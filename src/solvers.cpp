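#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conjugate-gradient solve of the finite-volume conduction system.
//
// The system matrix is the weighted graph Laplacian defined by the face
// conductance list (i, j, g): A = D - W with D the diagonal of incident
// conductance sums.  It is symmetric positive semi-definite with null space
// spanned by the constant vector (pure Neumann problem); the right-hand
// side must sum to zero (net injected current zero).  The constant mode is
// projected out of the iterates, which fixes the zero-mean gauge.
//
// Jacobi (diagonal) preconditioning handles the strong tissue-conductivity
// contrast; convergence is measured as ||r|| / ||b||.
// [[Rcpp::export]]
List cg_laplacian_solve(const int n,
                        const IntegerVector& ei,
                        const IntegerVector& ej,
                        const NumericVector& eg,
                        const NumericVector& b,
                        const double tol = 1e-8,
                        const int maxit = 50000) {
  const R_xlen_t m = eg.size();
  if (ei.size() != m || ej.size() != m)
    stop("edge index/weight lengths differ");
  if (b.size() != n) stop("rhs length != n");

  std::vector<double> diag(n, 0.0);
  for (R_xlen_t k = 0; k < m; ++k) {
    const int a = ei[k] - 1, c = ej[k] - 1;
    if (a < 0 || a >= n || c < 0 || c >= n) stop("edge index out of range");
    diag[a] += eg[k];
    diag[c] += eg[k];
  }
  for (int i = 0; i < n; ++i)
    if (!(diag[i] > 0.0)) stop("isolated degree-of-freedom in the system");

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), Ap(n);
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) { r[i] = b[i]; bnorm += b[i] * b[i]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["relres"] = 0.0,
                        _["iterations"] = 0,
                        _["res_hist"] = NumericVector(0),
                        _["converged"] = true);

  auto project = [&](std::vector<double>& v) {
    double mu = 0.0;
    for (int i = 0; i < n; ++i) mu += v[i];
    mu /= n;
    for (int i = 0; i < n; ++i) v[i] -= mu;
  };
  project(r);

  std::vector<double> hist;
  hist.reserve(256);
  double rz = 0.0;
  for (int i = 0; i < n; ++i) { z[i] = r[i] / diag[i]; rz += r[i] * z[i]; }
  for (int i = 0; i < n; ++i) p[i] = z[i];

  double relres = 1.0;
  int it = 0;
  bool converged = false;
  for (it = 0; it < maxit; ++it) {
    // Ap = A p  (Laplacian apply over the edge list)
    for (int i = 0; i < n; ++i) Ap[i] = diag[i] * p[i];
    for (R_xlen_t k = 0; k < m; ++k) {
      const int a = ei[k] - 1, c = ej[k] - 1;
      const double g = eg[k];
      Ap[a] -= g * p[c];
      Ap[c] -= g * p[a];
    }
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0.0) break; // numerical breakdown on the semi-definite system
    const double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
    }
    project(r);
    for (int i = 0; i < n; ++i) rnorm += r[i] * r[i];
    rnorm = std::sqrt(rnorm);
    relres = rnorm / bnorm;
    hist.push_back(relres);
    if (relres <= tol) { converged = true; ++it; break; }
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = r[i] / diag[i];
      rz_new += r[i] * z[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  project(x); // zero-mean gauge

  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["relres"] = relres,
                      _["iterations"] = it,
                      _["res_hist"] = NumericVector(hist.begin(), hist.end()),
                      _["converged"] = converged);
}

// Apply the edge-list graph Laplacian: y = A x.
// [[Rcpp::export]]
NumericVector laplacian_apply(const int n,
                              const IntegerVector& ei,
                              const IntegerVector& ej,
                              const NumericVector& eg,
                              const NumericVector& x) {
  const R_xlen_t m = eg.size();
  if (x.size() != n) stop("x length != n");
  NumericVector y(n);
  for (R_xlen_t k = 0; k < m; ++k) {
    const int a = ei[k] - 1, c = ej[k] - 1;
    const double f = eg[k] * (x[a] - x[c]);
    y[a] += f;
    y[c] -= f;
  }
  return y;
}

// Thomas algorithm for a tridiagonal system; `lower` and `upper` have
// length n-1.  Used by the semi-implicit cable stepper.
// [[Rcpp::export]]
NumericVector thomas_solve(const NumericVector& lower,
                           const NumericVector& diag,
                           const NumericVector& upper,
                           const NumericVector& rhs) {
  const int n = diag.size();
  if (lower.size() != n - 1 || upper.size() != n - 1 || rhs.size() != n)
    stop("tridiagonal dimensions inconsistent");
  std::vector<double> c(n - 1), d(n);
  double m = diag[0];
  if (m == 0.0) stop("singular tridiagonal system");
  if (n > 1) c[0] = upper[0] / m;
  d[0] = rhs[0] / m;
  for (int i = 1; i < n; ++i) {
    m = diag[i] - lower[i - 1] * c[i - 1];
    if (m == 0.0) stop("singular tridiagonal system");
    if (i < n - 1) c[i] = upper[i] / m;
    d[i] = (rhs[i] - lower[i - 1] * d[i - 1]) / m;
  }
  NumericVector x(n);
  x[n - 1] = d[n - 1];
  for (int i = n - 2; i >= 0; --i) x[i] = d[i] - c[i] * x[i + 1];
  return x;
}
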