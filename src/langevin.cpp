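#include <Rcpp.h>
using namespace Rcpp;

// Force (-dW/dz, kT/Angstrom) for the supported ground-truth potential kinds.
// kind: 0 = square well (gradient zero a.e.; wall forces are not representable
//           and simulation across the walls is documented as unsupported),
//       1 = harmonic, 2 = sum of Gaussian wells (double-well family),
//       3 = tabulated (force precomputed on the grid by central differences in
//           R, linearly interpolated here).
static inline double truth_force(double z, int kind, const NumericVector& par,
                                 const NumericVector& gz, const NumericVector& gF) {
  switch (kind) {
  case 0:
    return 0.0;
  case 1: // par = (stiffness, center)
    return -par[0] * (z - par[1]);
  case 2: { // par = (d1, c1, w1, d2, c2, w2, ...): W = sum -d exp(-(z-c)^2/(2w^2))
    double f = 0.0;
    int nw = par.size() / 3;
    for (int i = 0; i < nw; ++i) {
      double d = par[3 * i], c = par[3 * i + 1], w = par[3 * i + 2];
      double u = (z - c) / w;
      f += -d * u / w * std::exp(-0.5 * u * u);
    }
    return f;
  }
  case 3: { // piecewise-linear interpolation of grid forces
    int n = gz.size();
    if (z <= gz[0]) return gF[0];
    if (z >= gz[n - 1]) return gF[n - 1];
    int lo = 0, hi = n - 1;
    while (hi - lo > 1) {
      int mid = (lo + hi) / 2;
      if (gz[mid] <= z) lo = mid; else hi = mid;
    }
    double t = (z - gz[lo]) / (gz[hi] - gz[lo]);
    return gF[lo] + t * (gF[hi] - gF[lo]);
  }
  }
  return 0.0;
}

// Overdamped Langevin (Euler-Maruyama) in a 1D potential, energies in kT.
//   z <- z + D*dt*F(z,t) + sqrt(2*D*dt)*xi,  xi ~ N(0,1) from R's RNG stream.
// Optional harmonic umbrella bias 0.5*k_s*(z-z0)^2 and optional flat-bottom
// restraint 0.5*k_fb*(z-b(t))^2 for z > b(t), with b(t) ramped linearly from
// b_start to b_end over t_ramp then held. Positions are reflected at finite
// domain boundaries. Samples are recorded every s_save steps.
// [[Rcpp::export(name = ".langevin_cpp")]]
NumericVector langevin_cpp(int kind, NumericVector par,
                           NumericVector grid_z, NumericVector grid_F,
                           bool has_bias, double bias_k, double bias_z0,
                           bool has_fb, double fb_k, double fb_bstart,
                           double fb_bend, double fb_tramp,
                           double D, double dt, double n_steps_d, int s_save,
                           double z_init, double dom_lo, double dom_hi) {
  long long n_steps = (long long) n_steps_d;
  long long n_save = n_steps / s_save;
  NumericVector out(n_save);
  double z = z_init;
  double amp = std::sqrt(2.0 * D * dt);
  double Ddt = D * dt;
  long long isave = 0;
  for (long long step = 1; step <= n_steps; ++step) {
    double F = truth_force(z, kind, par, grid_z, grid_F);
    if (has_bias) F += -bias_k * (z - bias_z0);
    if (has_fb) {
      double t = (step - 1) * dt;
      double b = (fb_tramp > 0.0 && t < fb_tramp)
        ? fb_bstart + (fb_bend - fb_bstart) * (t / fb_tramp)
        : fb_bend;
      if (z > b) F += -fb_k * (z - b);
    }
    z += Ddt * F + amp * R::norm_rand();
    // reflect at finite domain edges
    if (R_finite(dom_lo) || R_finite(dom_hi)) {
      for (int guard = 0; guard < 64; ++guard) {
        if (R_finite(dom_lo) && z < dom_lo) { z = 2.0 * dom_lo - z; continue; }
        if (R_finite(dom_hi) && z > dom_hi) { z = 2.0 * dom_hi - z; continue; }
        break;
      }
    }
    if (step % s_save == 0) out[isave++] = z;
  }
  return out;
}
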