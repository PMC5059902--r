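#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Overdamped Euler-Maruyama stepping of n magnetosomes on [0, L] (nm).
// Forces (pN): midcell-directed active transport of magnitude Fs with a
// dead-band of one force-free step around L/2; nearest-neighbour collinear
// point-dipole attraction, active only while the surface gap is at most
// cutoff_gap; hard-sphere exclusion enforced after each step by symmetric
// projection of overlapping neighbour pairs back to contact.
// Particles must enter sorted by position; sub-nm steps preserve the order.
// noise holds standard-normal deviates, one row per particle, one column
// per step, so the caller owns the RNG (seeding, mirroring).
// [[Rcpp::export(name = ".sim_core")]]
NumericMatrix sim_core(NumericVector x0, NumericVector diam, NumericVector mom,
                       double L, double D, double gamma, double Fs,
                       double dt, int nsteps, int save_every,
                       double cutoff_gap, NumericMatrix noise) {
  const int n = x0.size();
  const int nsave = nsteps / save_every + 1;
  NumericMatrix out(n, nsave);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> f(n);
  const double half = L / 2.0;
  const double v0 = Fs / gamma;
  const double dead = v0 * dt;
  const double sig = std::sqrt(2.0 * D * dt);

  for (int i = 0; i < n; ++i) out(i, 0) = x[i];
  int isave = 1;

  for (int s = 0; s < nsteps; ++s) {
    double fmax = 0.0;
    for (int i = 0; i < n; ++i) {
      double dx = half - x[i];
      f[i] = (std::fabs(dx) > dead) ? (dx > 0 ? Fs : -Fs) : 0.0;
    }
    for (int i = 0; i + 1 < n; ++i) {
      double contact = 0.5 * (diam[i] + diam[i + 1]);
      double r = x[i + 1] - x[i];
      if (r - contact <= cutoff_gap) {
        double rr = (r < contact) ? contact : r;  // capped at contact
        double fm = 6.0e41 * mom[i] * mom[i + 1] / (rr * rr * rr * rr);
        f[i] += fm;
        f[i + 1] -= fm;
      }
    }
    for (int i = 0; i < n; ++i) {
      if (std::fabs(f[i]) > fmax) fmax = std::fabs(f[i]);
      x[i] += (f[i] / gamma) * dt + sig * noise(i, s);
      if (!std::isfinite(x[i]))
        stop("non-finite position at step %d: dt = %g is too large for max force %g pN",
             s + 1, dt, fmax);
      double lo = 0.5 * diam[i], hi = L - 0.5 * diam[i];
      if (x[i] < lo) x[i] = 2.0 * lo - x[i];
      if (x[i] > hi) x[i] = 2.0 * hi - x[i];
      if (x[i] < lo) x[i] = lo;
      if (x[i] > hi) x[i] = hi;
    }
    // steric projection, centre-of-mass preserving per pair; iterate until
    // no overlap remains (a compressed chain needs several sweeps)
    bool moved = true;
    int pass = 0;
    while (moved && pass < 200) {
      moved = false;
      ++pass;
      for (int i = 0; i + 1 < n; ++i) {
        double contact = 0.5 * (diam[i] + diam[i + 1]);
        double r = x[i + 1] - x[i];
        if (r < contact - 1e-9) {
          double mid = 0.5 * (x[i] + x[i + 1]);
          x[i] = mid - 0.5 * contact;
          x[i + 1] = mid + 0.5 * contact;
          moved = true;
        }
      }
      for (int i = 0; i < n; ++i) {
        double lo = 0.5 * diam[i], hi = L - 0.5 * diam[i];
        if (x[i] < lo) { x[i] = lo; moved = true; }
        if (x[i] > hi) { x[i] = hi; moved = true; }
      }
    }
    if ((s + 1) % save_every == 0) {
      for (int i = 0; i < n; ++i) out(i, isave) = x[i];
      ++isave;
    }
  }
  return out;
}
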