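#include <Rcpp.h>
using namespace Rcpp;

// Explicit FTCS relaxation of dC/dt = D lap(C) - sink on a periodic lattice.
// vmax: per-pixel maximum sink rate in concentration units per second (>= 0).
// km:   Michaelis constant in concentration units; km == 0 selects the
//       zeroth-order (constant-rate) sink used for oxygen.
// Vessel pixels are clamped to c_vessel after every step (Dirichlet sources)
// and concentrations are floored at zero.
// The sweep may be restricted to the sub-box [r0,r1]x[c0,c1] (0-based,
// inclusive): pixels outside keep their values and act as frozen boundary
// data, which is exact up to the diffusive screening length. With the box
// equal to the whole grid this is the plain periodic scheme.
// Convergence: max over swept pixels of |dC| / (|C| + eps) < tol each step.
static List relax_ftcs_impl(NumericMatrix conc, NumericVector vmax, double km,
                            LogicalVector vessel, double c_vessel,
                            double alpha, double dt, double tol, int max_iter,
                            int r0, int r1, int c0, int c1) {
  const int nr = conc.nrow(), nc = conc.ncol(), n = nr * nc;
  if ((int)vmax.size() != n) stop("consumption field size mismatch");
  if ((int)vessel.size() != n) stop("vessel mask size mismatch");
  if (alpha > 0.25) stop("unitless diffusion number exceeds stability bound 0.25");
  if (r0 < 0 || c0 < 0 || r1 >= nr || c1 >= nc || r0 > r1 || c0 > c1)
    stop("invalid relaxation box");
  std::vector<double> cur(conc.begin(), conc.end());
  std::vector<double> nxt(cur);
  int iter = 0;
  bool converged = false;
  // The raw per-step change understates the distance to the fixed point by
  // a factor 1/(1 - rho), rho being the decay rate of the slowest excited
  // mode; rho is estimated online from successive change ratios so that
  // tol bounds the residual relative distance, not just the step size.
  double prevmax = -1.0, rho = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    double maxrel = 0.0;
    for (int j = c0; j <= c1; ++j) {
      const int jm = (j == 0 ? nc - 1 : j - 1), jp = (j == nc - 1 ? 0 : j + 1);
      const double *colC = &cur[(size_t)j * nr];
      const double *colW = &cur[(size_t)jm * nr];
      const double *colE = &cur[(size_t)jp * nr];
      const double *vm = &vmax[(size_t)j * nr];
      const int *vs = &vessel[(size_t)j * nr];
      double *out = &nxt[(size_t)j * nr];
      for (int i = r0; i <= r1; ++i) {
        const int im = (i == 0 ? nr - 1 : i - 1), ip = (i == nr - 1 ? 0 : i + 1);
        const double c = colC[i];
        double v;
        if (vs[i]) {
          v = c_vessel;
        } else {
          const double f = (km > 0.0) ? vm[i] * c / (km + c) : vm[i];
          v = c + alpha * (colC[im] + colC[ip] + colW[i] + colE[i] - 4.0 * c)
                - dt * f;
          if (v < 0.0) v = 0.0;
        }
        out[i] = v;
        const double d = std::fabs(v - c) / (std::fabs(c) + 1e-30);
        if (d > maxrel) maxrel = d;
      }
    }
    // copy the swept box back (double buffering within the box only)
    for (int j = c0; j <= c1; ++j)
      std::copy(nxt.data() + (size_t)j * nr + r0,
                nxt.data() + (size_t)j * nr + r1 + 1,
                cur.data() + (size_t)j * nr + r0);
    if (maxrel == 0.0) { converged = true; ++iter; break; }
    if (prevmax > 0.0) {
      double r = maxrel / prevmax;
      if (r > 0.999999) r = 0.999999;
      if (r < 0.0) r = 0.0;
      rho = 0.9 * rho + 0.1 * r;  // smoothed decay-rate estimate
    }
    prevmax = maxrel;
    if (maxrel < tol * (1.0 - rho)) { converged = true; ++iter; break; }
  }
  NumericMatrix out(nr, nc);
  std::copy(cur.begin(), cur.end(), out.begin());
  return List::create(_["conc"] = out, _["iters"] = iter,
                      _["converged"] = converged);
}

// [[Rcpp::export]]
List relax_ftcs_cpp(NumericMatrix conc, NumericVector vmax, double km,
                    LogicalVector vessel, double c_vessel,
                    double alpha, double dt, double tol, int max_iter) {
  return relax_ftcs_impl(conc, vmax, km, vessel, c_vessel, alpha, dt, tol,
                         max_iter, 0, conc.nrow() - 1, 0, conc.ncol() - 1);
}

// [[Rcpp::export]]
List relax_ftcs_box_cpp(NumericMatrix conc, NumericVector vmax, double km,
                        LogicalVector vessel, double c_vessel,
                        double alpha, double dt, double tol, int max_iter,
                        int r0, int r1, int c0, int c1) {
  return relax_ftcs_impl(conc, vmax, km, vessel, c_vessel, alpha, dt, tol,
                         max_iter, r0, r1, c0, c1);
}

// One bare FTCS step (no clamping, no flooring) used by diffusionStep and
// the mass-conservation property tests; sink passed as a precomputed
// rate lattice in concentration units per second.
// [[Rcpp::export]]
NumericMatrix ftcs_step_cpp(NumericMatrix conc, NumericMatrix rate,
                            double alpha, double dt) {
  const int nr = conc.nrow(), nc = conc.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jm = (j == 0 ? nc - 1 : j - 1), jp = (j == nc - 1 ? 0 : j + 1);
    for (int i = 0; i < nr; ++i) {
      const int im = (i == 0 ? nr - 1 : i - 1), ip = (i == nr - 1 ? 0 : i + 1);
      const double c = conc(i, j);
      out(i, j) = c + alpha * (conc(im, j) + conc(ip, j) + conc(i, jm) + conc(i, jp)
                               - 4.0 * c) - dt * rate(i, j);
    }
  }
  return out;
}
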