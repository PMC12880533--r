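#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// CSR container built from 0-based triplets; duplicate entries are summed.
struct CSR {
  int n;
  std::vector<int> ptr, col;
  std::vector<double> val;
};

static CSR build_csr(int n, const IntegerVector& ti, const IntegerVector& tj,
                     const NumericVector& tx) {
  CSR A;
  A.n = n;
  const int nnz_in = ti.size();
  std::vector<int> count(n + 1, 0);
  for (int k = 0; k < nnz_in; ++k) count[ti[k] + 1]++;
  std::vector<int> ptr(n + 1, 0);
  for (int r = 0; r < n; ++r) ptr[r + 1] = ptr[r] + count[r + 1];
  std::vector<int> col(nnz_in);
  std::vector<double> val(nnz_in);
  std::vector<int> pos(ptr.begin(), ptr.end() - 1);
  for (int k = 0; k < nnz_in; ++k) {
    int p = pos[ti[k]]++;
    col[p] = tj[k];
    val[p] = tx[k];
  }
  // sort each row by column and merge duplicates
  A.ptr.assign(n + 1, 0);
  std::vector<std::pair<int,double>> row;
  for (int r = 0; r < n; ++r) {
    row.clear();
    for (int p = ptr[r]; p < ptr[r + 1]; ++p) row.push_back({col[p], val[p]});
    std::sort(row.begin(), row.end());
    int m = 0;
    for (size_t q = 0; q < row.size(); ++q) {
      if (m > 0 && A.col.size() > 0 &&
          (int)A.col.size() > A.ptr[r] + m - 1 &&
          A.col[A.ptr[r] + m - 1] == row[q].first) {
        A.val[A.ptr[r] + m - 1] += row[q].second;
      } else {
        A.col.push_back(row[q].first);
        A.val.push_back(row[q].second);
        ++m;
      }
    }
    A.ptr[r + 1] = A.ptr[r] + m;
  }
  return A;
}

static void spmv(const CSR& A, const std::vector<double>& x,
                 std::vector<double>& y) {
  for (int r = 0; r < A.n; ++r) {
    double s = 0.0;
    for (int p = A.ptr[r]; p < A.ptr[r + 1]; ++p) s += A.val[p] * x[A.col[p]];
    y[r] = s;
  }
}

// In-place ILU(0): factors stored in lu.val with unit lower diagonal implied.
struct ILU0 {
  const CSR* A;
  std::vector<double> val;
  std::vector<int> diag;  // index of diagonal entry per row
  bool ok;
};

static ILU0 ilu0(const CSR& A) {
  ILU0 F;
  F.A = &A;
  F.val = A.val;
  F.diag.assign(A.n, -1);
  F.ok = true;
  for (int r = 0; r < A.n; ++r)
    for (int p = A.ptr[r]; p < A.ptr[r + 1]; ++p)
      if (A.col[p] == r) F.diag[r] = p;
  std::vector<int> colmap(A.n, -1);
  for (int r = 0; r < A.n; ++r) {
    if (F.diag[r] < 0) { F.ok = false; return F; }
    for (int p = A.ptr[r]; p < A.ptr[r + 1]; ++p) colmap[A.col[p]] = p;
    for (int p = A.ptr[r]; p < A.ptr[r + 1] && A.col[p] < r; ++p) {
      int c = A.col[p];
      double piv = F.val[F.diag[c]];
      if (piv == 0.0) { F.ok = false; return F; }
      double mult = F.val[p] / piv;
      F.val[p] = mult;
      for (int q = F.diag[c] + 1; q < A.ptr[c + 1]; ++q) {
        int idx = colmap[A.col[q]];
        if (idx >= 0) F.val[idx] -= mult * F.val[q];
      }
    }
    for (int p = A.ptr[r]; p < A.ptr[r + 1]; ++p) colmap[A.col[p]] = -1;
    if (F.val[F.diag[r]] == 0.0) { F.ok = false; return F; }
  }
  return F;
}

// Solve (LU) z = rhs with L unit-lower, U upper from ILU0.
static void ilu_solve(const ILU0& F, const std::vector<double>& rhs,
                      std::vector<double>& z) {
  const CSR& A = *F.A;
  z = rhs;
  for (int r = 0; r < A.n; ++r) {
    double s = z[r];
    for (int p = A.ptr[r]; A.col[p] < r; ++p) s -= F.val[p] * z[A.col[p]];
    z[r] = s;
  }
  for (int r = A.n - 1; r >= 0; --r) {
    double s = z[r];
    for (int p = F.diag[r] + 1; p < A.ptr[r + 1]; ++p)
      s -= F.val[p] * z[A.col[p]];
    z[r] = s / F.val[F.diag[r]];
  }
}

static double nrm2(const std::vector<double>& v) {
  double s = 0.0;
  for (double x : v) s += x * x;
  return std::sqrt(s);
}

// [[Rcpp::export(name = ".bicgstab_ilu0")]]
List bicgstab_ilu0(int n, IntegerVector ti, IntegerVector tj, NumericVector tx,
                   NumericVector b, NumericVector x0, double tol = 1e-8,
                   int maxit = 2000) {
  CSR A = build_csr(n, ti, tj, tx);
  ILU0 F = ilu0(A);
  if (!F.ok)
    stop("ILU(0) factorization broke down (zero pivot): the linear system is singular or ill-conditioned; check that at least one Dirichlet or Robin boundary condition is present");

  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> r(n), rhat(n), p(n, 0.0), v(n, 0.0), s(n), t(n),
      phat(n), shat(n), Ax(n);
  spmv(A, x, Ax);
  for (int i = 0; i < n; ++i) r[i] = b[i] - Ax[i];
  double bnorm = nrm2(std::vector<double>(b.begin(), b.end()));
  if (bnorm == 0.0) bnorm = 1.0;
  double resid = nrm2(r) / bnorm;
  rhat = r;
  double rho = 1.0, alpha = 1.0, omega = 1.0;
  int it = 0;
  while (resid > tol && it < maxit) {
    double rho1 = 0.0;
    for (int i = 0; i < n; ++i) rho1 += rhat[i] * r[i];
    if (rho1 == 0.0) break;
    if (it == 0) {
      p = r;
    } else {
      double beta = (rho1 / rho) * (alpha / omega);
      for (int i = 0; i < n; ++i) p[i] = r[i] + beta * (p[i] - omega * v[i]);
    }
    ilu_solve(F, p, phat);
    spmv(A, phat, v);
    double rv = 0.0;
    for (int i = 0; i < n; ++i) rv += rhat[i] * v[i];
    if (rv == 0.0) break;
    alpha = rho1 / rv;
    for (int i = 0; i < n; ++i) s[i] = r[i] - alpha * v[i];
    if (nrm2(s) / bnorm < tol) {
      for (int i = 0; i < n; ++i) x[i] += alpha * phat[i];
      resid = nrm2(s) / bnorm;
      ++it;
      break;
    }
    ilu_solve(F, s, shat);
    spmv(A, shat, t);
    double tt = 0.0, ts = 0.0;
    for (int i = 0; i < n; ++i) { tt += t[i] * t[i]; ts += t[i] * s[i]; }
    if (tt == 0.0) break;
    omega = ts / tt;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * phat[i] + omega * shat[i];
      r[i] = s[i] - omega * t[i];
    }
    rho = rho1;
    resid = nrm2(r) / bnorm;
    ++it;
    if (omega == 0.0) break;
  }
  // true residual
  spmv(A, x, Ax);
  for (int i = 0; i < n; ++i) r[i] = b[i] - Ax[i];
  double true_res = nrm2(r) / bnorm;
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["relres"] = true_res, _["iter"] = it,
                      _["converged"] = true_res <= tol * 10);
}
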