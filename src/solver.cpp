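#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstddef>

using namespace Rcpp;

// Region codes shared with R/geometry.R
enum Region { BLOOD = 1, MYO = 2, EPOS = 3, ENEG = 4, SHAFT = 5 };

static inline bool is_unknown(int r)   { return r == BLOOD || r == MYO; }
static inline bool is_electrode(int r) { return r == EPOS || r == ENEG; }

// Harmonic mean of two cell conductivities; zero if either side blocks flux.
static inline double harm(double a, double b) {
  return (a > 0.0 && b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
}

struct FaceSystem {
  std::vector<double> wx, wy, wz; // conductance to the +x/+y/+z neighbour
  std::vector<double> diag, b;    // diagonal and right-hand side
  std::ptrdiff_t nx, ny, nz, N;
};

// Assemble face conductances for the 7-point finite-volume stencil.
// Dirichlet electrode contributions are folded into diag/b; a Dirichlet
// coupling across half an electrode cell uses conductance 2*sigma (perfect
// conductor occupies the electrode half of the cell pair).
static FaceSystem assemble(const int* reg, const double* sig,
                           std::ptrdiff_t nx, std::ptrdiff_t ny, std::ptrdiff_t nz,
                           double v_pos, double v_neg, bool grounded) {
  FaceSystem S;
  S.nx = nx; S.ny = ny; S.nz = nz;
  S.N = nx * ny * nz;
  S.wx.assign(S.N, 0.0); S.wy.assign(S.N, 0.0); S.wz.assign(S.N, 0.0);
  S.diag.assign(S.N, 0.0); S.b.assign(S.N, 0.0);
  const std::ptrdiff_t sy = nx, sz = nx * ny;

  auto face = [&](std::ptrdiff_t p, std::ptrdiff_t q, std::vector<double>& w) {
    int rp = reg[p], rq = reg[q];
    if (is_unknown(rp) && is_unknown(rq)) {
      double v = harm(sig[p], sig[q]);
      w[p] = v;
      S.diag[p] += v;
      S.diag[q] += v;
    } else if (is_unknown(rp) && is_electrode(rq)) {
      double v = 2.0 * sig[p];
      S.diag[p] += v;
      S.b[p] += v * (rq == EPOS ? v_pos : v_neg);
    } else if (is_electrode(rp) && is_unknown(rq)) {
      double v = 2.0 * sig[q];
      S.diag[q] += v;
      S.b[q] += v * (rp == EPOS ? v_pos : v_neg);
    }
    // shaft or electrode-electrode faces carry no flux in the reduced system
  };

  for (std::ptrdiff_t k = 0; k < nz; ++k)
    for (std::ptrdiff_t j = 0; j < ny; ++j)
      for (std::ptrdiff_t i = 0; i < nx; ++i) {
        std::ptrdiff_t p = i + nx * (j + ny * k);
        if (i < nx - 1) face(p, p + 1,  S.wx);
        if (j < ny - 1) face(p, p + sy, S.wy);
        if (k < nz - 1) face(p, p + sz, S.wz);
        if (grounded && is_unknown(reg[p])) {
          // ghost node at phi = 0 half a cell outside each domain face
          int nb = (i == 0) + (i == nx - 1) + (j == 0) + (j == ny - 1) +
                   (k == 0) + (k == nz - 1);
          if (nb > 0) S.diag[p] += nb * 2.0 * sig[p];
        }
      }
  return S;
}

// y = A x restricted to unknown cells (non-unknown entries of x are zero).
static void matvec(const FaceSystem& S, const int* reg,
                   const double* x, double* y) {
  const std::ptrdiff_t nx = S.nx, ny = S.ny, nz = S.nz, sy = nx, sz = nx * ny;
  const double *wx = S.wx.data(), *wy = S.wy.data(), *wz = S.wz.data();
  const double *d = S.diag.data();
  for (std::ptrdiff_t k = 0; k < nz; ++k)
    for (std::ptrdiff_t j = 0; j < ny; ++j)
      for (std::ptrdiff_t i = 0; i < nx; ++i) {
        std::ptrdiff_t p = i + nx * (j + ny * k);
        if (!is_unknown(reg[p])) { y[p] = 0.0; continue; }
        double acc = d[p] * x[p];
        if (i > 0)      acc -= wx[p - 1]  * x[p - 1];
        if (i < nx - 1) acc -= wx[p]      * x[p + 1];
        if (j > 0)      acc -= wy[p - sy] * x[p - sy];
        if (j < ny - 1) acc -= wy[p]      * x[p + sy];
        if (k > 0)      acc -= wz[p - sz] * x[p - sz];
        if (k < nz - 1) acc -= wz[p]      * x[p + sz];
        y[p] = acc;
      }
}

// [[Rcpp::export]]
List fv_solve_cpp(IntegerVector region, NumericVector sigma, IntegerVector dims,
                  double v_pos, double v_neg, double tol, int maxit,
                  bool grounded, Nullable<NumericVector> x0 = R_NilValue) {
  const std::ptrdiff_t nx = dims[0], ny = dims[1], nz = dims[2];
  const std::ptrdiff_t N = nx * ny * nz;
  if ((std::ptrdiff_t)region.size() != N || (std::ptrdiff_t)sigma.size() != N)
    stop("region/sigma length does not match dims");
  const int* reg = INTEGER(region);
  const double* sig = REAL(sigma);

  FaceSystem S = assemble(reg, sig, nx, ny, nz, v_pos, v_neg, grounded);

  // Jacobi-preconditioned conjugate gradients, matrix-free; optional warm start
  std::vector<double> x(N, 0.0), r(N, 0.0), z(N, 0.0), p(N, 0.0), q(N, 0.0);
  std::vector<double> dinv(N, 0.0);
  double bnorm2 = 0.0;
  for (std::ptrdiff_t i = 0; i < N; ++i) {
    if (is_unknown(reg[i])) {
      dinv[i] = S.diag[i] > 0.0 ? 1.0 / S.diag[i] : 0.0;
      r[i] = S.b[i];
      bnorm2 += S.b[i] * S.b[i];
    }
  }
  if (bnorm2 == 0.0)
    stop("no electrode drive reaches the conductive domain (topology error)");
  if (x0.isNotNull()) {
    NumericVector xx(x0);
    if ((std::ptrdiff_t)xx.size() != N) stop("x0 length does not match dims");
    for (std::ptrdiff_t i = 0; i < N; ++i)
      if (is_unknown(reg[i]) && R_finite(xx[i])) x[i] = xx[i];
    matvec(S, reg, x.data(), q.data());
    for (std::ptrdiff_t i = 0; i < N; ++i)
      if (is_unknown(reg[i])) r[i] = S.b[i] - q[i];
  }

  double rz = 0.0, rnorm2_0 = 0.0;
  for (std::ptrdiff_t i = 0; i < N; ++i) {
    z[i] = r[i] * dinv[i]; p[i] = z[i]; rz += r[i] * z[i];
    rnorm2_0 += r[i] * r[i];
  }

  const double bnorm = std::sqrt(bnorm2);
  double relres = std::sqrt(rnorm2_0) / bnorm;
  int it = 0;
  for (it = 0; it < maxit && relres > tol; ++it) {
    matvec(S, reg, p.data(), q.data());
    double pq = 0.0;
    for (std::ptrdiff_t i = 0; i < N; ++i) pq += p[i] * q[i];
    if (pq <= 0.0) break; // singular/disconnected subsystem
    double alpha = rz / pq;
    double rnorm2 = 0.0;
    for (std::ptrdiff_t i = 0; i < N; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
      rnorm2 += r[i] * r[i];
    }
    relres = std::sqrt(rnorm2) / bnorm;
    if (relres <= tol) { ++it; break; }
    double rz_new = 0.0;
    for (std::ptrdiff_t i = 0; i < N; ++i) { z[i] = r[i] * dinv[i]; rz_new += r[i] * z[i]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (std::ptrdiff_t i = 0; i < N; ++i) p[i] = z[i] + beta * p[i];
  }

  NumericVector phi(N);
  for (std::ptrdiff_t i = 0; i < N; ++i) {
    int rg = reg[i];
    if (rg == EPOS) phi[i] = v_pos;
    else if (rg == ENEG) phi[i] = v_neg;
    else if (rg == SHAFT) phi[i] = NA_REAL;
    else phi[i] = x[i];
  }
  return List::create(_["phi"] = phi,
                      _["iterations"] = it,
                      _["relres"] = relres,
                      _["converged"] = relres <= tol);
}

// Electric-field magnitude in V/cm from phi (volts) on a grid with pitch
// spacing_mm. Central differences within a region, one-sided at region
// boundaries (falling back to any non-shaft neighbour when no same-region
// neighbour exists along an axis).
// [[Rcpp::export]]
NumericVector fv_gradient_cpp(NumericVector phi, IntegerVector region,
                              IntegerVector dims, double spacing_mm) {
  const std::ptrdiff_t nx = dims[0], ny = dims[1], nz = dims[2];
  const std::ptrdiff_t N = nx * ny * nz;
  const double* ph = REAL(phi);
  const int* reg = INTEGER(region);
  NumericVector out(N);
  const double h_cm = spacing_mm / 10.0;
  const std::ptrdiff_t stride[3] = {1, nx, nx * ny};

  for (std::ptrdiff_t k = 0; k < nz; ++k)
    for (std::ptrdiff_t j = 0; j < ny; ++j)
      for (std::ptrdiff_t i = 0; i < nx; ++i) {
        std::ptrdiff_t p = i + nx * (j + ny * k);
        if (reg[p] == SHAFT) { out[p] = NA_REAL; continue; }
        std::ptrdiff_t idx[3] = {i, j, k};
        std::ptrdiff_t n_ax[3] = {nx, ny, nz};
        double e2 = 0.0;
        for (int ax = 0; ax < 3; ++ax) {
          std::ptrdiff_t s = stride[ax];
          bool has_m = idx[ax] > 0, has_q = idx[ax] < n_ax[ax] - 1;
          std::ptrdiff_t m = p - s, q = p + s;
          bool same_m = has_m && reg[m] == reg[p];
          bool same_q = has_q && reg[q] == reg[p];
          double g;
          if (same_m && same_q) {
            g = (ph[q] - ph[m]) / (2.0 * h_cm);
          } else if (same_q) {
            g = (ph[q] - ph[p]) / h_cm;
          } else if (same_m) {
            g = (ph[p] - ph[m]) / h_cm;
          } else {
            bool ok_m = has_m && reg[m] != SHAFT && R_finite(ph[m]);
            bool ok_q = has_q && reg[q] != SHAFT && R_finite(ph[q]);
            if (ok_m && ok_q)      g = (ph[q] - ph[m]) / (2.0 * h_cm);
            else if (ok_q)         g = (ph[q] - ph[p]) / h_cm;
            else if (ok_m)         g = (ph[p] - ph[m]) / h_cm;
            else                   g = 0.0;
          }
          e2 += g * g;
        }
        out[p] = std::sqrt(e2);
      }
  return out;
}

// Net current (amperes) leaving each electrode through its faces into
// conductive cells. sigma in S/m, spacing in mm, phi in volts.
// [[Rcpp::export]]
List fv_electrode_current_cpp(NumericVector phi, IntegerVector region,
                              NumericVector sigma, IntegerVector dims,
                              double v_pos, double v_neg, double spacing_mm) {
  const std::ptrdiff_t nx = dims[0], ny = dims[1], nz = dims[2];
  const double* ph = REAL(phi);
  const int* reg = INTEGER(region);
  const double* sig = REAL(sigma);
  const std::ptrdiff_t stride[3] = {1, nx, nx * ny};
  const double h_m = spacing_mm * 1e-3; // face conductance = 2*sigma*h
  double ipos = 0.0, ineg = 0.0;

  for (std::ptrdiff_t k = 0; k < nz; ++k)
    for (std::ptrdiff_t j = 0; j < ny; ++j)
      for (std::ptrdiff_t i = 0; i < nx; ++i) {
        std::ptrdiff_t p = i + nx * (j + ny * k);
        if (!is_electrode(reg[p])) continue;
        double ve = reg[p] == EPOS ? v_pos : v_neg;
        std::ptrdiff_t idx[3] = {i, j, k};
        std::ptrdiff_t n_ax[3] = {nx, ny, nz};
        for (int ax = 0; ax < 3; ++ax) {
          for (int dir = -1; dir <= 1; dir += 2) {
            std::ptrdiff_t ii = idx[ax] + dir;
            if (ii < 0 || ii >= n_ax[ax]) continue;
            std::ptrdiff_t q = p + dir * stride[ax];
            if (!is_unknown(reg[q])) continue;
            double g = 2.0 * sig[q] * h_m;
            double cur = g * (ve - ph[q]);
            if (reg[p] == EPOS) ipos += cur; else ineg += cur;
          }
        }
      }
  return List::create(_["I_pos"] = ipos, _["I_neg"] = ineg);
}

// Face conductances of the assembled system (diagnostics/tests).
// [[Rcpp::export]]
List fv_faces_cpp(IntegerVector region, NumericVector sigma, IntegerVector dims) {
  const std::ptrdiff_t nx = dims[0], ny = dims[1], nz = dims[2];
  FaceSystem S = assemble(INTEGER(region), REAL(sigma), nx, ny, nz,
                          0.0, 0.0, false);
  return List::create(_["wx"] = NumericVector(S.wx.begin(), S.wx.end()),
                      _["wy"] = NumericVector(S.wy.begin(), S.wy.end()),
                      _["wz"] = NumericVector(S.wz.begin(), S.wz.end()));
}
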