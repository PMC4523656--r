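#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <queue>
using namespace Rcpp;

// Preconditioned conjugate gradients for a symmetric positive-definite
// sparse matrix stored in compressed sparse column form (both triangles
// present, as in a Matrix::dgCMatrix). The preconditioner is symmetric
// Gauss-Seidel, M = (D + L) D^{-1} (D + U); because the matrix is
// symmetric, row j of the strict lower triangle can be read off column j.
static void sgs_apply(const IntegerVector& Ap, const IntegerVector& Ai,
                      const NumericVector& Ax, const NumericVector& diag,
                      const std::vector<double>& r, std::vector<double>& z,
                      std::vector<double>& work) {
  const int n = diag.size();
  // forward solve (D + L) y = r
  for (int j = 0; j < n; ++j) {
    double s = 0.0;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
      int i = Ai[k];
      if (i < j) s += Ax[k] * work[i];
    }
    work[j] = (r[j] - s) / diag[j];
  }
  // backward solve (D + U) z = D y
  for (int j = n - 1; j >= 0; --j) {
    double s = 0.0;
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) {
      int i = Ai[k];
      if (i > j) s += Ax[k] * z[i];
    }
    z[j] = (diag[j] * work[j] - s) / diag[j];
  }
}

static void spmv(const IntegerVector& Ap, const IntegerVector& Ai,
                 const NumericVector& Ax, const std::vector<double>& x,
                 std::vector<double>& y) {
  const int n = (int)x.size();
  std::fill(y.begin(), y.end(), 0.0);
  for (int j = 0; j < n; ++j) {
    const double xj = x[j];
    for (int k = Ap[j]; k < Ap[j + 1]; ++k) y[Ai[k]] += Ax[k] * xj;
  }
}

// [[Rcpp::export(name = ".pcg_sgs")]]
List pcg_sgs(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
             NumericVector b, double tol, int maxit) {
  const int n = b.size();
  NumericVector diag(n);
  for (int j = 0; j < n; ++j)
    for (int k = Ap[j]; k < Ap[j + 1]; ++k)
      if (Ai[k] == j) diag[j] = Ax[k];
  for (int j = 0; j < n; ++j)
    if (!(diag[j] > 0)) stop("non-positive diagonal entry at row %d", j + 1);

  std::vector<double> x(n, 0.0), r(n), z(n), p(n), q(n), work(n);
  double bnorm = 0.0;
  for (int j = 0; j < n; ++j) { r[j] = b[j]; bnorm += b[j] * b[j]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relative_residual"] = 0.0);

  sgs_apply(Ap, Ai, Ax, diag, r, z, work);
  double rho = 0.0;
  for (int j = 0; j < n; ++j) { p[j] = z[j]; rho += r[j] * z[j]; }

  double relres = 1.0;
  int it = 0;
  for (it = 1; it <= maxit; ++it) {
    spmv(Ap, Ai, Ax, p, q);
    double pq = 0.0;
    for (int j = 0; j < n; ++j) pq += p[j] * q[j];
    double alpha = rho / pq;
    double rnorm = 0.0;
    for (int j = 0; j < n; ++j) {
      x[j] += alpha * p[j];
      r[j] -= alpha * q[j];
      rnorm += r[j] * r[j];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) break;
    sgs_apply(Ap, Ai, Ax, diag, r, z, work);
    double rho_new = 0.0;
    for (int j = 0; j < n; ++j) rho_new += r[j] * z[j];
    double beta = rho_new / rho;
    rho = rho_new;
    for (int j = 0; j < n; ++j) p[j] = z[j] + beta * p[j];
  }
  if (it > maxit) it = maxit;

  NumericVector xout(n);
  for (int j = 0; j < n; ++j) xout[j] = x[j];
  return List::create(_["x"] = xout, _["iterations"] = it,
                      _["relative_residual"] = relres);
}

// 6-connected flood fill over a logical 3-D mask starting from 1-based
// linear seed indices; returns a logical mask of the reached component.
// [[Rcpp::export(name = ".flood_fill6")]]
LogicalVector flood_fill6(LogicalVector mask, IntegerVector dims,
                          IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  LogicalVector out(n);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t v = (R_xlen_t)seeds[s] - 1;
    if (v < 0 || v >= n) stop("seed index out of range");
    if (mask[v] && !out[v]) { out[v] = true; q.push(v); }
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int i = (int)(v % nx);
    int j = (int)((v / nx) % ny);
    int k = (int)(v / sz);
    if (i > 0 && mask[v - sx] && !out[v - sx]) { out[v - sx] = true; q.push(v - sx); }
    if (i < nx - 1 && mask[v + sx] && !out[v + sx]) { out[v + sx] = true; q.push(v + sx); }
    if (j > 0 && mask[v - sy] && !out[v - sy]) { out[v - sy] = true; q.push(v - sy); }
    if (j < ny - 1 && mask[v + sy] && !out[v + sy]) { out[v + sy] = true; q.push(v + sy); }
    if (k > 0 && mask[v - sz] && !out[v - sz]) { out[v - sz] = true; q.push(v - sz); }
    if (k < nz - 1 && mask[v + sz] && !out[v + sz]) { out[v + sz] = true; q.push(v + sz); }
  }
  return out;
}
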