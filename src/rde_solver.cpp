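#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Method-of-lines right-hand side for the Fisher-KPP reaction-diffusion
// equation on a node-centered uniform grid with zero-flux (Neumann)
// boundaries.  The diffusion term is a finite-volume five-point stencil with
// arithmetic face averaging of D: each node owns a control cell of width h
// (h/2 at the boundary, matching the trapezoid quadrature weights), so
// interior face fluxes cancel pairwise and the trapezoid-weighted total mass
// is conserved exactly (to rounding) when rho == 0.  The boundary half-cell
// form is equivalent to the classical ghost-node Neumann treatment.
static void rde_rhs(const double* n, double* dn,
                    const double* D, const double* rho, const double* kap,
                    int nx, int ny, double hx, double hy) {
  const double ihx2 = 1.0 / (hx * hx);
  const double ihy2 = 1.0 / (hy * hy);
  for (int j = 0; j < ny; ++j) {
    const double cy = (j == 0 || j == ny - 1) ? 2.0 : 1.0;  // 1/half-cell
    for (int i = 0; i < nx; ++i) {
      const int k = i + nx * j;
      const double cx = (i == 0 || i == nx - 1) ? 2.0 : 1.0;
      double fx = 0.0, fy = 0.0;
      // x-direction faces (flux = 0 across the domain boundary)
      if (i + 1 < nx) {
        const double Df = 0.5 * (D[k] + D[k + 1]);
        fx += Df * (n[k + 1] - n[k]) * ihx2;
      }
      if (i > 0) {
        const double Df = 0.5 * (D[k] + D[k - 1]);
        fx -= Df * (n[k] - n[k - 1]) * ihx2;
      }
      // y-direction faces
      if (j + 1 < ny) {
        const double Df = 0.5 * (D[k] + D[k + nx]);
        fy += Df * (n[k + nx] - n[k]) * ihy2;
      }
      if (j > 0) {
        const double Df = 0.5 * (D[k] + D[k - nx]);
        fy -= Df * (n[k] - n[k - nx]) * ihy2;
      }
      dn[k] = cx * fx + cy * fy + rho[k] * n[k] * (1.0 - n[k] / kap[k]);
    }
  }
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695,
                    e4 = 393.0 / 640, e5 = -92097.0 / 339200,
                    e6 = 187.0 / 2100, e7 = 1.0 / 40;

// [[Rcpp::export(name = ".solve_rde_cpp")]]
List solve_rde_cpp(NumericVector D, NumericVector rho, NumericVector kappa,
                   NumericVector n0, int nx, int ny, double hx, double hy,
                   NumericVector times, double rtol, double atol,
                   double max_step) {
  const int N = nx * ny;
  const int nt = times.size();
  if (D.size() != N || rho.size() != N || kappa.size() != N || n0.size() != N)
    stop("coefficient/initial fields do not match the grid size");

  NumericMatrix out(N, nt);
  std::vector<double> y(n0.begin(), n0.end());
  std::vector<double> ynew(N), yerr(N), ytmp(N);
  std::vector<double> k1(N), k2(N), k3(N), k4(N), k5(N), k6(N), k7(N);
  const double* Dp = D.begin();
  const double* rp = rho.begin();
  const double* kp = kappa.begin();

  long n_clipped = 0;
  double t = times[0];
  // store the initial slice (clip stray negatives in user input is caller's job)
  for (int k = 0; k < N; ++k) out(k, 0) = y[k];

  double dt = (times[nt - 1] - times[0]) / 100.0;
  if (!(dt > 0)) dt = 1e-3;
  if (dt > max_step) dt = max_step;

  bool have_k1 = false;
  for (int it = 1; it < nt; ++it) {
    const double t_target = times[it];
    while (t < t_target) {
      if (dt > max_step) dt = max_step;
      if (t + dt > t_target) dt = t_target - t;
      if (!have_k1) { rde_rhs(y.data(), k1.data(), Dp, rp, kp, nx, ny, hx, hy); have_k1 = true; }

      for (int k = 0; k < N; ++k) ytmp[k] = y[k] + dt * a21 * k1[k];
      rde_rhs(ytmp.data(), k2.data(), Dp, rp, kp, nx, ny, hx, hy);
      for (int k = 0; k < N; ++k) ytmp[k] = y[k] + dt * (a31 * k1[k] + a32 * k2[k]);
      rde_rhs(ytmp.data(), k3.data(), Dp, rp, kp, nx, ny, hx, hy);
      for (int k = 0; k < N; ++k) ytmp[k] = y[k] + dt * (a41 * k1[k] + a42 * k2[k] + a43 * k3[k]);
      rde_rhs(ytmp.data(), k4.data(), Dp, rp, kp, nx, ny, hx, hy);
      for (int k = 0; k < N; ++k) ytmp[k] = y[k] + dt * (a51 * k1[k] + a52 * k2[k] + a53 * k3[k] + a54 * k4[k]);
      rde_rhs(ytmp.data(), k5.data(), Dp, rp, kp, nx, ny, hx, hy);
      for (int k = 0; k < N; ++k) ytmp[k] = y[k] + dt * (a61 * k1[k] + a62 * k2[k] + a63 * k3[k] + a64 * k4[k] + a65 * k5[k]);
      rde_rhs(ytmp.data(), k6.data(), Dp, rp, kp, nx, ny, hx, hy);
      for (int k = 0; k < N; ++k)
        ynew[k] = y[k] + dt * (b1 * k1[k] + b3 * k3[k] + b4 * k4[k] + b5 * k5[k] + b6 * k6[k]);
      rde_rhs(ynew.data(), k7.data(), Dp, rp, kp, nx, ny, hx, hy);

      double err2 = 0.0;
      bool bad = false;
      for (int k = 0; k < N; ++k) {
        const double y5 = ynew[k];
        // embedded 4th-order estimate (k7 = f(t+dt, y5), FSAL stage)
        const double y4 = y[k] + dt * (e1 * k1[k] + e3 * k3[k] + e4 * k4[k] +
                                       e5 * k5[k] + e6 * k6[k] + e7 * k7[k]);
        const double sc = atol + rtol * std::max(std::fabs(y[k]), std::fabs(y5));
        const double e = (y5 - y4) / sc;
        err2 += e * e;
        if (!std::isfinite(y5)) bad = true;
      }
      if (bad) stop("reaction-diffusion solver diverged (non-finite state at t = %f)", t);
      const double err = std::sqrt(err2 / N);

      if (err <= 1.0) {
        t += dt;
        std::swap(y, ynew);
        std::swap(k1, k7);  // FSAL
        have_k1 = true;
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        dt *= std::min(5.0, std::max(0.2, fac));
      } else {
        double fac = 0.9 * std::pow(err, -0.2);
        dt *= std::max(0.2, fac);
        if (dt < 1e-12) stop("reaction-diffusion solver step size underflow at t = %f", t);
      }
      Rcpp::checkUserInterrupt();
    }
    // clip tiny negative undershoots at output times, counting them
    for (int k = 0; k < N; ++k) {
      double v = y[k];
      if (v < 0) { v = 0.0; ++n_clipped; y[k] = 0.0; have_k1 = false; }
      out(k, it) = v;
    }
  }

  return List::create(_["values"] = out, _["n_clipped"] = (double)n_clipped);
}
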