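#include <Rcpp.h>
#include <R_ext/BLAS.h>
#include <vector>
#include <cmath>
#include <cstring>

using namespace Rcpp;

// Element-by-element matrix-vector product w = K * u for a voxel mesh in
// which every element shares one 24x24 stiffness matrix Ke (uniform cube
// size, uniform material).  conn is 8 x nel, 1-based node ids; u and w are
// length 3*nnodes, node-major dof ordering (ux, uy, uz per node).
// Workspace holding the batched per-element vectors so that the 24x24
// products of all elements collapse into a single BLAS dgemm call.
struct EbeWork {
  std::vector<double> U, W;
  void resize(int nel) {
    U.resize((size_t)24 * nel);
    W.resize((size_t)24 * nel);
  }
};

static void ebe_matvec(const int* conn, int nel, const double* Ke,
                       const double* u, double* w, int ndof,
                       EbeWork& work) {
  std::memset(w, 0, sizeof(double) * ndof);
  double* U = work.U.data();
  double* W = work.W.data();
  for (int e = 0; e < nel; ++e) {
    const int* c = conn + 8 * e;
    double* ue = U + (size_t)24 * e;
    for (int a = 0; a < 8; ++a) {
      const int base = 3 * (c[a] - 1);
      ue[3 * a]     = u[base];
      ue[3 * a + 1] = u[base + 1];
      ue[3 * a + 2] = u[base + 2];
    }
  }
  {
    const int m = 24;
    const double one = 1.0, zero = 0.0;
    F77_CALL(dgemm)("N", "N", &m, &nel, &m, &one, Ke, &m, U, &m, &zero,
                    W, &m FCONE FCONE);
  }
  for (int e = 0; e < nel; ++e) {
    const int* c = conn + 8 * e;
    const double* we = W + (size_t)24 * e;
    for (int a = 0; a < 8; ++a) {
      const int base = 3 * (c[a] - 1);
      w[base]     += we[3 * a];
      w[base + 1] += we[3 * a + 1];
      w[base + 2] += we[3 * a + 2];
    }
  }
}

// [[Rcpp::export(name = ".feMatvec")]]
NumericVector fe_matvec(IntegerMatrix conn, NumericMatrix Ke, int nnodes,
                        NumericVector u) {
  const int nel = conn.ncol();
  const int ndof = 3 * nnodes;
  if (u.size() != ndof) stop("u has wrong length");
  NumericVector w(ndof);
  EbeWork work;
  work.resize(nel);
  ebe_matvec(conn.begin(), nel, Ke.begin(), u.begin(), w.begin(), ndof,
             work);
  return w;
}

// Jacobi-preconditioned conjugate gradients on the constrained system.
// Dirichlet dofs (0-based) carry prescribed values; they are eliminated by
// the standard trick: solve A x = f on free dofs with f = -K u0 and the
// operator K projected onto free dofs.  Returns full u = x + u0.
// [[Rcpp::export(name = ".fePCG")]]
List fe_pcg(IntegerMatrix conn, NumericMatrix Ke, int nnodes,
            IntegerVector fixedDof, NumericVector fixedVal,
            double tol, int maxIter) {
  const int nel = conn.ncol();
  const int ndof = 3 * nnodes;
  const int nfix = fixedDof.size();
  if (fixedVal.size() != nfix) stop("fixedDof/fixedVal length mismatch");

  std::vector<char> isfix(ndof, 0);
  std::vector<double> u0(ndof, 0.0);
  for (int i = 0; i < nfix; ++i) {
    const int d = fixedDof[i];
    if (d < 0 || d >= ndof) stop("fixed dof out of range");
    isfix[d] = 1;
    u0[d] = fixedVal[i];
  }

  // Jacobi diagonal of K (free dofs only are ever divided)
  std::vector<double> diag(ndof, 0.0);
  for (int e = 0; e < nel; ++e) {
    const int* c = &conn(0, e);
    for (int a = 0; a < 8; ++a) {
      const int base = 3 * (c[a] - 1);
      diag[base]     += Ke(3 * a,     3 * a);
      diag[base + 1] += Ke(3 * a + 1, 3 * a + 1);
      diag[base + 2] += Ke(3 * a + 2, 3 * a + 2);
    }
  }
  for (int i = 0; i < ndof; ++i)
    if (diag[i] <= 0.0) diag[i] = 1.0;  // unused or constrained dofs

  std::vector<double> f(ndof), x(ndof, 0.0), r(ndof), z(ndof), p(ndof),
      q(ndof);
  EbeWork work;
  work.resize(nel);

  // f = -K u0 on free dofs
  ebe_matvec(conn.begin(), nel, Ke.begin(), u0.data(), f.data(), ndof,
             work);
  double bnorm2 = 0.0;
  for (int i = 0; i < ndof; ++i) {
    f[i] = isfix[i] ? 0.0 : -f[i];
    bnorm2 += f[i] * f[i];
  }
  const double bnorm = std::sqrt(bnorm2);

  int iter = 0;
  double relres = 0.0;
  if (bnorm > 0.0) {
    std::memcpy(r.data(), f.data(), sizeof(double) * ndof);
    double rz = 0.0;
    for (int i = 0; i < ndof; ++i) {
      z[i] = r[i] / diag[i];
      rz += r[i] * z[i];
    }
    std::memcpy(p.data(), z.data(), sizeof(double) * ndof);
    relres = 1.0;
    for (iter = 1; iter <= maxIter; ++iter) {
      ebe_matvec(conn.begin(), nel, Ke.begin(), p.data(), q.data(), ndof,
                 work);
      double pq = 0.0;
      for (int i = 0; i < ndof; ++i) {
        if (isfix[i]) q[i] = 0.0;
        pq += p[i] * q[i];
      }
      if (pq <= 0.0) stop("PCG breakdown: operator not positive definite");
      const double alpha = rz / pq;
      double rnorm2 = 0.0;
      for (int i = 0; i < ndof; ++i) {
        x[i] += alpha * p[i];
        r[i] -= alpha * q[i];
        rnorm2 += r[i] * r[i];
      }
      relres = std::sqrt(rnorm2) / bnorm;
      if (relres <= tol) break;
      double rz_new = 0.0;
      for (int i = 0; i < ndof; ++i) {
        z[i] = r[i] / diag[i];
        rz_new += r[i] * z[i];
      }
      const double beta = rz_new / rz;
      rz = rz_new;
      for (int i = 0; i < ndof; ++i) p[i] = z[i] + beta * p[i];
      if (iter % 200 == 0) Rcpp::checkUserInterrupt();
    }
  }
  const bool converged = (bnorm == 0.0) || (relres <= tol);

  NumericVector u(ndof);
  for (int i = 0; i < ndof; ++i) u[i] = x[i] + u0[i];
  return List::create(_["u"] = u, _["iterations"] = iter,
                      _["relres"] = relres, _["converged"] = converged);
}

// 6-connected (face) component labeling of a 3D logical array stored in
// R's column-major order with dims = c(nx, ny, nz).  Labels are 1..ncomp in
// order of first (lexicographically smallest linear index) encounter, so
// component 1 contains the smallest foreground index.
// [[Rcpp::export(name = ".labelComponents6")]]
IntegerVector label_components6(LogicalVector mask, IntegerVector dims) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<int> queue;
  int next = 0;
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next;
    queue.clear();
    queue.push_back((int)start);
    labels[start] = next;
    while (!queue.empty()) {
      const R_xlen_t v = queue.back();
      queue.pop_back();
      const int i = (int)(v % nx);
      const int j = (int)((v / nx) % ny);
      const int k = (int)(v / sz);
      const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
      const bool ok[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1,
                          k > 0, k < nz - 1};
      for (int d = 0; d < 6; ++d) {
        if (!ok[d]) continue;
        const R_xlen_t w = nb[d];
        if (mask[w] && labels[w] == 0) {
          labels[w] = next;
          queue.push_back((int)w);
        }
      }
    }
  }
  labels.attr("ncomp") = next;
  return labels;
}
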