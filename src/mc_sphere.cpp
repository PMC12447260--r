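#include <Rcpp.h>
using namespace Rcpp;

// Reflecting random walk inside a sphere of radius r (elastic specular
// reflection approximated by radial fold-back, valid for steps << r).
// Returns sums of (z - z0)^2 and (z - z0)^4 at the requested record steps
// so the caller can form the one-axis MSD and its standard error.
// Uses R's RNG: seed via set.seed() before calling.
// [[Rcpp::export]]
List mc_sphere_walk_cpp(double r, double d, int n_walkers, double dt,
                        IntegerVector record_steps) {
  int n_rec = record_steps.size();
  int n_steps = record_steps[n_rec - 1];
  double sd = std::sqrt(2.0 * d * dt);
  double r2 = r * r;

  std::vector<double> x(n_walkers), y(n_walkers), z(n_walkers), z0(n_walkers);
  RNGScope scope;

  // uniform initial positions in the ball, by rejection
  for (int i = 0; i < n_walkers; ++i) {
    double xi, yi, zi;
    do {
      xi = (2.0 * unif_rand() - 1.0) * r;
      yi = (2.0 * unif_rand() - 1.0) * r;
      zi = (2.0 * unif_rand() - 1.0) * r;
    } while (xi * xi + yi * yi + zi * zi > r2);
    x[i] = xi; y[i] = yi; z[i] = zi; z0[i] = zi;
  }

  NumericVector sum2(n_rec), sum4(n_rec);
  int rec_idx = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int i = 0; i < n_walkers; ++i) {
      double xi = x[i] + norm_rand() * sd;
      double yi = y[i] + norm_rand() * sd;
      double zi = z[i] + norm_rand() * sd;
      double rho2 = xi * xi + yi * yi + zi * zi;
      if (rho2 > r2) {
        double rho = std::sqrt(rho2);
        double f = (2.0 * r - rho) / rho;  // fold back across the surface
        if (f < 0.0) f = 0.0;              // pathological overshoot guard
        xi *= f; yi *= f; zi *= f;
      }
      x[i] = xi; y[i] = yi; z[i] = zi;
    }
    while (rec_idx < n_rec && record_steps[rec_idx] == s) {
      double s2 = 0.0, s4 = 0.0;
      for (int i = 0; i < n_walkers; ++i) {
        double dz = z[i] - z0[i];
        double dz2 = dz * dz;
        s2 += dz2;
        s4 += dz2 * dz2;
      }
      sum2[rec_idx] = s2;
      sum4[rec_idx] = s4;
      ++rec_idx;
    }
  }
  return List::create(_["sum2"] = sum2, _["sum4"] = sum4,
                      _["n"] = n_walkers);
}
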