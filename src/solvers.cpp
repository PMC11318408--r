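#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Steady-state 1-D reaction-diffusion with Michaelis-Menten consumption.
// Two geometries share the assembly: node 0 carries the Dirichlet supply
// value, the far boundary is closed (zero flux). Balances are written in
// flux form so the discrete solution conserves oxygen exactly (influx ==
// integrated consumption), which the cylindrical hypoxia-boundary scan
// relies on.
//
// The nonlinear system is solved by quasi-linearized Picard iteration: the
// reaction term M p/(p+Km) is frozen as c(p_old) * p with c = M/(p_old+Km),
// and the resulting tridiagonal system solved exactly. That system is an
// M-matrix with a non-negative source, so every iterate is strictly
// positive -- no clamping is ever needed and the iteration cannot stall on
// a projected step. Convergence is declared on the max node update, then
// verified on the true nonlinear residual.

namespace {

struct Tridiag {
  std::vector<double> sub, diag, sup, rhs;
  explicit Tridiag(int n) : sub(n), diag(n), sup(n), rhs(n) {}
  // Thomas algorithm; overwrites rhs with the solution.
  void solve() {
    const int n = static_cast<int>(diag.size());
    std::vector<double> c(n);
    c[0] = sup[0] / diag[0];
    rhs[0] /= diag[0];
    for (int i = 1; i < n; ++i) {
      const double m = diag[i] - sub[i] * c[i - 1];
      c[i] = sup[i] / m;
      rhs[i] = (rhs[i] - sub[i] * rhs[i - 1]) / m;
    }
    for (int i = n - 2; i >= 0; --i) rhs[i] -= c[i] * rhs[i + 1];
  }
};

// max |flux balance residual| of the nonlinear system at p
double residual_norm(const std::vector<double>& p,
                     const std::vector<double>& cond,
                     const std::vector<double>& vol, double M, double Km) {
  const int N = static_cast<int>(p.size());
  double worst = 0.0;
  for (int i = 1; i < N; ++i) {
    double flux = cond[i - 1] * (p[i - 1] - p[i]);
    if (i < N - 1) flux -= cond[i] * (p[i] - p[i + 1]);
    const double F = flux - vol[i] * M * p[i] / (p[i] + Km);
    worst = std::max(worst, std::fabs(F));
  }
  return worst;
}

// cond[i]: conductance of the face between nodes i and i+1 (D * area / h);
// vol[i]: control volume of node i. Geometry enters only through these.
std::vector<double> picard_solve(double boundary_po2,
                                 const std::vector<double>& cond,
                                 const std::vector<double>& vol, double M,
                                 double Km, double tol, int max_iter) {
  const int N = static_cast<int>(vol.size());
  const int n = N - 1;  // unknowns (node 0 is Dirichlet)
  std::vector<double> p(N, boundary_po2);
  if (M == 0.0) return p;  // no consumption: flat field, exactly the boundary

  for (int iter = 0; iter < max_iter; ++iter) {
    Tridiag A(n);
    for (int i = 1; i < N; ++i) {
      const int j = i - 1;
      const double c = vol[i] * M / (p[i] + Km);
      double d = -cond[i - 1] - c;
      if (i < N - 1) d -= cond[i];
      A.diag[j] = d;
      A.sub[j] = (j > 0) ? cond[i - 1] : 0.0;
      A.sup[j] = (i < N - 1) ? cond[i] : 0.0;
      A.rhs[j] = (j == 0) ? -cond[0] * boundary_po2 : 0.0;
    }
    A.solve();
    double upd = 0.0;
    for (int j = 0; j < n; ++j) {
      upd = std::max(upd, std::fabs(A.rhs[j] - p[j + 1]));
      p[j + 1] = A.rhs[j];
    }
    if (upd < tol) {
      // scale-aware residual guard against a stalled fixed point
      double scale = 0.0;
      for (size_t k = 0; k < cond.size(); ++k)
        scale = std::max(scale, cond[k]);
      const double res = residual_norm(p, cond, vol, M, Km);
      if (res <= 1e-6 * scale * std::max(boundary_po2, 1.0)) return p;
    }
  }
  stop("reaction-diffusion solver failed to converge after %d iterations "
       "(last max residual %g)", max_iter,
       residual_norm(p, cond, vol, M, Km));
  return p;  // not reached
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".planar_solve_cpp")]]
NumericVector planar_solve_cpp(double surface_po2, int n_layers, double h,
                               double D, double Km, double M,
                               double tol = 1e-6, int max_iter = 10000) {
  const int N = n_layers + 1;  // nodes 0..L
  std::vector<double> cond(N - 1, D / h), vol(N, h);
  vol[N - 1] = h / 2.0;  // closed-boundary node owns half a cell
  std::vector<double> p =
      picard_solve(surface_po2, cond, vol, M, Km, tol, max_iter);
  return NumericVector(p.begin(), p.end());
}

//' @noRd
// [[Rcpp::export(name = ".cyl_solve_cpp")]]
NumericVector cyl_solve_cpp(double capillary_po2, double r_in, double r_out,
                            int n_shells, double D, double Km, double M,
                            double tol = 1e-6, int max_iter = 10000) {
  const int N = n_shells + 1;
  const double h = (r_out - r_in) / n_shells;
  std::vector<double> r(N), cond(N - 1), vol(N);
  for (int i = 0; i < N; ++i) r[i] = r_in + i * h;
  // Per unit axial length and per radian: face area r_{i+1/2}, volume
  // (r_{i+1/2}^2 - r_{i-1/2}^2)/2; the outer node owns the half-cell up to R.
  for (int i = 0; i < N - 1; ++i) cond[i] = D * 0.5 * (r[i] + r[i + 1]) / h;
  for (int i = 1; i < N; ++i) {
    const double rm = 0.5 * (r[i] + r[i - 1]);
    const double rp = (i < N - 1) ? 0.5 * (r[i] + r[i + 1]) : r[i];
    vol[i] = 0.5 * (rp * rp - rm * rm);
  }
  vol[0] = 0.0;  // Dirichlet node, unused
  std::vector<double> p =
      picard_solve(capillary_po2, cond, vol, M, Km, tol, max_iter);
  return NumericVector(p.begin(), p.end());
}
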