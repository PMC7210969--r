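#include <Rcpp.h>
using namespace Rcpp;

// Overdamped (inertia-free) Langevin integrator for a harmonic bead-spring
// network under constant external forces:
//   dx = (F/gamma) dt + sqrt(2 kT dt / gamma) * N(0,1)
// Euler-Maruyama; uses R's RNG so set.seed() governs reproducibility.
// Bond indices are 0-based. Returns recorded frames and a rupture flag
// (some bond exceeded ruptureLength at a recorded step).
// [[Rcpp::export(name = ".langevinRun")]]
List langevinRun(NumericMatrix coords,
                 IntegerVector bondI, IntegerVector bondJ,
                 NumericVector bondK, NumericVector bondR0,
                 NumericVector extFz,
                 double gamma, double kT, double dt,
                 int nSteps, int recordEvery, double ruptureLength) {
  const int n = coords.nrow();
  const int nb = bondI.size();
  std::vector<double> x(n), y(n), z(n);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  std::vector<double> fx(n), fy(n), fz(n);
  const double mob = dt / gamma;
  const double noise = std::sqrt(2.0 * kT * dt / gamma);
  const int nFrames = nSteps / recordEvery;
  NumericVector frames(Dimension(nFrames, n, 3));
  bool ruptured = false;
  double maxLen2 = ruptureLength * ruptureLength;
  int rec = 0;
  for (int step = 1; step <= nSteps; ++step) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int i = 0; i < n; ++i) fz[i] = extFz[i];
    for (int b = 0; b < nb; ++b) {
      const int i = bondI[b], j = bondJ[b];
      const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
      const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (len < 1e-12) continue;
      const double fmag = bondK[b] * (len - bondR0[b]) / len;
      fx[i] += fmag * dx; fy[i] += fmag * dy; fz[i] += fmag * dz;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy; fz[j] -= fmag * dz;
    }
    for (int i = 0; i < n; ++i) {
      x[i] += mob * fx[i] + noise * norm_rand();
      y[i] += mob * fy[i] + noise * norm_rand();
      z[i] += mob * fz[i] + noise * norm_rand();
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]))
        stop("runtime error: coordinate divergence at step %d; "
             "use a smaller timestep", step);
    }
    if (step % recordEvery == 0) {
      for (int i = 0; i < n; ++i) {
        frames[rec + nFrames * i] = x[i];
        frames[rec + nFrames * (n + i)] = y[i];
        frames[rec + nFrames * (2 * n + i)] = z[i];
      }
      if (!ruptured) {
        for (int b = 0; b < nb; ++b) {
          const int i = bondI[b], j = bondJ[b];
          const double dx = x[j] - x[i], dy = y[j] - y[i], dz = z[j] - z[i];
          if (dx * dx + dy * dy + dz * dz > maxLen2) { ruptured = true; break; }
        }
      }
      ++rec;
    }
  }
  return List::create(Named("frames") = frames,
                      Named("ruptured") = ruptured);
}
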