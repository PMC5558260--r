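#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Jacobi-preconditioned conjugate gradients on a symmetric sparse matrix
// in CSC layout (dgCMatrix slots p, i, x). The matrix may be the singular
// pure-Neumann operator: the constant null-space mode is deflated from the
// preconditioned residual each iteration, which fixes the gauge.
// [[Rcpp::export]]
List pcg_csc(IntegerVector p, IntegerVector ri, NumericVector xv,
             NumericVector b, double tol, int maxit, bool deflate) {
  const int n = b.size();
  std::vector<double> x(n, 0.0), r(n), z(n), d(n), Ap(n), M(n);

  for (int col = 0; col < n; ++col) {
    double diag = 0.0;
    for (int k = p[col]; k < p[col + 1]; ++k)
      if (ri[k] == col) { diag = xv[k]; break; }
    M[col] = diag > 0.0 ? 1.0 / diag : 1.0;
  }

  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) { r[i] = b[i]; bnorm += b[i] * b[i]; }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0)
    return List::create(_["x"] = NumericVector(n), _["iterations"] = 0,
                        _["relres"] = 0.0, _["converged"] = true);

  auto matvec = [&](const std::vector<double>& v, std::vector<double>& out) {
    std::fill(out.begin(), out.end(), 0.0);
    for (int col = 0; col < n; ++col) {
      const double vc = v[col];
      if (vc == 0.0) continue;
      for (int k = p[col]; k < p[col + 1]; ++k)
        out[ri[k]] += xv[k] * vc;
    }
  };
  auto precond = [&](const std::vector<double>& rin,
                     std::vector<double>& zout) {
    double mean = 0.0;
    for (int i = 0; i < n; ++i) zout[i] = M[i] * rin[i];
    if (deflate) {
      for (int i = 0; i < n; ++i) mean += zout[i];
      mean /= n;
      for (int i = 0; i < n; ++i) zout[i] -= mean;
    }
  };

  precond(r, z);
  d = z;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) rz += r[i] * z[i];

  double relres = 1.0;
  int it = 0;
  bool converged = false;
  for (it = 1; it <= maxit; ++it) {
    matvec(d, Ap);
    double dAd = 0.0;
    for (int i = 0; i < n; ++i) dAd += d[i] * Ap[i];
    if (dAd <= 0.0) break;  // singular direction: stop
    const double alpha = rz / dAd;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * d[i];
      r[i] -= alpha * Ap[i];
      rnorm += r[i] * r[i];
    }
    relres = std::sqrt(rnorm) / bnorm;
    if (relres <= tol) { converged = true; break; }
    precond(r, z);
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) rz_new += r[i] * z[i];
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) d[i] = z[i] + beta * d[i];
  }

  if (deflate) {  // re-centre to the zero-mean gauge
    double mean = 0.0;
    for (int i = 0; i < n; ++i) mean += x[i];
    mean /= n;
    for (int i = 0; i < n; ++i) x[i] -= mean;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it, _["relres"] = relres,
                      _["converged"] = converged);
}
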