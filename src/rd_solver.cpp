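#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Axisymmetric Keller-Segel + Monod solver on a uniform radial grid.
//
// Fields: rho (cells/mL) and c (mM) at cell centers r_i = (i + 1/2) dr,
// i = 0..N-1, over [0, R]. Finite-volume update in conservation form:
//
//   d rho / dt = -(1/r) d(r Frho)/dr + g(rho, c)
//   d c   / dt = -(1/r) d(r Fc)/dr   - g(rho, c)/Y
//
// with Frho = -Db drho/dr + u rho, u = chi(c) dc/dr,
// chi(c) = k0 * KD / (KD + c)^2 (receptor law), Fc = -Dc dc/dr,
// g = kg rho c / (Kg + c) (Monod). No-flux at r = 0 and r = R.
//
// Diffusion by central differences, chemotactic advection by first-order
// upwinding on the face velocity (positivity-robust for Keller-Segel).
// Explicit time stepping with an adaptive step limited by the diffusive
// stability bound, the advective CFL, and a consumption limiter that
// keeps c non-negative.

// [[Rcpp::export(name = ".rd_integrate_cpp")]]
List rd_integrate_cpp(NumericVector rho0, NumericVector c0,
                      double dr, double t_end,
                      double Db, double Dc, double k0, double KD,
                      double kg, double Kg, double Y,
                      NumericVector save_times,
                      double cfl = 0.4, double max_steps = 5e7,
                      bool radial = true, double stop_rho = -1.0) {
  const int N = rho0.size();
  if (c0.size() != N) stop("rho0 and c0 must have equal length");
  const int nsave = save_times.size();

  std::vector<double> rho(rho0.begin(), rho0.end());
  std::vector<double> c(c0.begin(), c0.end());
  std::vector<double> rho_new(N), c_new(N);
  std::vector<double> Frho(N + 1, 0.0), Fc(N + 1, 0.0);

  // face radii r_{i-1/2} = i*dr, cell radii r_i = (i+1/2)*dr;
  // planar (slab) geometry uses unit metric factors
  std::vector<double> rf(N + 1), rc(N);
  for (int i = 0; i <= N; ++i) rf[i] = radial ? i * dr : 1.0;
  for (int i = 0; i < N; ++i) rc[i] = radial ? (i + 0.5) * dr : 1.0;

  NumericMatrix rho_out(N, nsave), c_out(N, nsave);
  NumericVector t_out(nsave);

  double t = 0.0;
  int isave = 0;
  long long step = 0;

  // record t = 0 if requested
  while (isave < nsave && save_times[isave] <= 1e-14) {
    for (int i = 0; i < N; ++i) { rho_out(i, isave) = rho[i]; c_out(i, isave) = c[i]; }
    t_out[isave] = 0.0;
    ++isave;
  }

  const double dt_diff = (Db + Dc > 0.0)
    ? cfl * 0.5 * dr * dr / std::max(Db, Dc)
    : R_PosInf;

  while (t < t_end - 1e-14) {
    // face fluxes
    double umax = 0.0;
    for (int j = 1; j < N; ++j) {  // interior faces; boundary faces stay 0
      const double dcdr = (c[j] - c[j - 1]) / dr;
      const double cf = 0.5 * (c[j] + c[j - 1]);
      const double chi = k0 * KD / ((KD + cf) * (KD + cf));
      const double u = chi * dcdr;
      if (std::fabs(u) > umax) umax = std::fabs(u);
      const double upw = (u > 0.0) ? rho[j - 1] : rho[j];
      Frho[j] = -Db * (rho[j] - rho[j - 1]) / dr + u * upw;
      Fc[j]   = -Dc * (c[j] - c[j - 1]) / dr;
    }

    double dt = std::min(dt_diff, t_end - t);
    if (umax > 0.0) dt = std::min(dt, cfl * dr / umax);
    if (isave < nsave && t + dt > save_times[isave]) dt = save_times[isave] - t;

    // conservative update; the Monod consumption uses an exponential
    // (Patankar-type) step, c -> c e^{-lambda dt} with
    // lambda = kg rho / ((Kg + c) Y), which is unconditionally
    // positive, and growth is credited as exactly Y times the nutrient
    // consumed so the mass-balance identity holds to roundoff
    for (int i = 0; i < N; ++i) {
      const double divR = (rf[i + 1] * Frho[i + 1] - rf[i] * Frho[i]) / (rc[i] * dr);
      const double divC = (rf[i + 1] * Fc[i + 1] - rf[i] * Fc[i]) / (rc[i] * dr);
      double dc_react = 0.0;
      if (c[i] > 0.0 && rho[i] > 0.0) {
        const double lambda = kg * rho[i] / ((Kg + c[i]) * Y);
        dc_react = c[i] * (-std::expm1(-lambda * dt));
      }
      rho_new[i] = rho[i] + dt * (-divR) + Y * dc_react;
      c_new[i]   = c[i] + dt * (-divC) - dc_react;
      if (c_new[i] < 0.0) c_new[i] = 0.0;  // diffusion roundoff only
    }
    rho.swap(rho_new);
    c.swap(c_new);
    t += dt;
    ++step;

    while (isave < nsave && t >= save_times[isave] - 1e-12) {
      for (int i = 0; i < N; ++i) { rho_out(i, isave) = rho[i]; c_out(i, isave) = c[i]; }
      t_out[isave] = t;
      ++isave;
    }
    if (step > (long long)max_steps)
      stop("time stepping exceeded max_steps (%g) at t = %g h", max_steps, t);
    if (step % 4096 == 0) checkUserInterrupt();
    // optional early stop: the leading tail of the colony has reached
    // the outermost cell, so later front positions would be
    // wall-contaminated anyway
    if (stop_rho > 0.0 && rho[N - 1] > stop_rho) break;
  }

  if (isave < nsave) {
    // truncate the outputs to the snapshots actually recorded
    NumericMatrix rho_tr(N, isave), c_tr(N, isave);
    NumericVector t_tr(isave);
    for (int j = 0; j < isave; ++j) {
      t_tr[j] = t_out[j];
      for (int i = 0; i < N; ++i) { rho_tr(i, j) = rho_out(i, j); c_tr(i, j) = c_out(i, j); }
    }
    return List::create(_["rho"] = rho_tr, _["c"] = c_tr,
                        _["t"] = t_tr, _["steps"] = (double)step,
                        _["stopped_early"] = true);
  }
  return List::create(_["rho"] = rho_out, _["c"] = c_out,
                      _["t"] = t_out, _["steps"] = (double)step,
                      _["stopped_early"] = false);
}

// Circle accumulation for the circular Hough transform: for each edge
// pixel and each candidate radius, votes are cast on the circle of that
// radius around the pixel (Bresenham-like parametric sampling).

// [[Rcpp::export(name = ".hough_circle_cpp")]]
NumericVector hough_circle_cpp(IntegerVector ex, IntegerVector ey,
                               int nx, int ny, NumericVector radii) {
  const int ne = ex.size(), nr = radii.size();
  NumericVector acc(nx * ny * nr);  // column-major [x, y, r]
  for (int k = 0; k < nr; ++k) {
    const double r = radii[k];
    const int nth = std::max(16, (int)std::ceil(2.0 * M_PI * r));
    const double w = 1.0 / nth;
    for (int e = 0; e < ne; ++e) {
      for (int a = 0; a < nth; ++a) {
        const double th = 2.0 * M_PI * a / nth;
        const int cx = (int)std::lround(ex[e] - r * std::cos(th));
        const int cy = (int)std::lround(ey[e] - r * std::sin(th));
        if (cx >= 0 && cx < nx && cy >= 0 && cy < ny)
          acc[cx + nx * (cy + (long long)ny * k)] += w;
      }
    }
  }
  acc.attr("dim") = IntegerVector::create(nx, ny, nr);
  return acc;
}
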