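#include <Rcpp.h>
using namespace Rcpp;

// BAOAB Langevin integrator for the harmonic bond network.
// Units: nm, ps, g/mol, kJ/mol. Uses R's RNG (seed controlled from R).
// Bond energy is gamma * (d - d0)^2, i.e. force constant 2*gamma.
// [[Rcpp::export]]
List cpp_langevin_baoab(NumericMatrix X0,
                        IntegerVector bi_, IntegerVector bj_,
                        NumericVector gamma_, NumericVector d0_,
                        NumericVector mass_,     // g/mol (already scaled)
                        double dt, double c1, NumericVector sigma_,
                        NumericMatrix Fext_, LogicalVector fixed_,
                        int nSteps, int recordEvery, double kT) {
  const int N = X0.nrow();
  const int nb = bi_.size();
  std::vector<double> x(3 * N), v(3 * N), f(3 * N), fext(3 * N);
  std::vector<double> gam(gamma_.begin(), gamma_.end());
  std::vector<double> d0(d0_.begin(), d0_.end());
  std::vector<int> bi(bi_.begin(), bi_.end());
  std::vector<int> bj(bj_.begin(), bj_.end());
  std::vector<double> hdtm(N), sig(N);
  std::vector<char> fix(N);
  for (int i = 0; i < N; ++i) {
    for (int c = 0; c < 3; ++c) {
      x[3 * i + c] = X0(i, c);
      fext[3 * i + c] = Fext_(i, c);
    }
    hdtm[i] = 0.5 * dt / mass_[i];
    sig[i] = sigma_[i];
    fix[i] = fixed_[i] ? 1 : 0;
  }

  RNGScope scope;
  // Maxwell-Boltzmann initial velocities (zero when kT == 0)
  for (int i = 0; i < N; ++i) {
    double s = (kT > 0.0) ? std::sqrt(kT / mass_[i]) : 0.0;
    for (int c = 0; c < 3; ++c)
      v[3 * i + c] = fix[i] ? 0.0 : s * norm_rand();
  }

  const int nFrames = nSteps / recordEvery + 1;
  NumericVector frames(static_cast<R_xlen_t>(nFrames) * N * 3);
  double *fr = REAL(frames);
  NumericVector epotTrace(nFrames);
  int fi = 0;
  for (int k = 0; k < 3 * N; ++k) fr[k] = x[k];

  auto computeForces = [&]() -> double {
    std::copy(fext.begin(), fext.end(), f.begin());
    double ep = 0.0;
    for (int b = 0; b < nb; ++b) {
      const int i3 = 3 * bi[b], j3 = 3 * bj[b];
      const double dx = x[i3] - x[j3];
      const double dy = x[i3 + 1] - x[j3 + 1];
      const double dz = x[i3 + 2] - x[j3 + 2];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      const double dev = d - d0[b];
      ep += gam[b] * dev * dev;
      const double fac = -2.0 * gam[b] * dev / d;
      f[i3] += fac * dx;     f[j3] -= fac * dx;
      f[i3 + 1] += fac * dy; f[j3 + 1] -= fac * dy;
      f[i3 + 2] += fac * dz; f[j3 + 2] -= fac * dz;
    }
    return ep;
  };

  epotTrace[0] = computeForces();
  int divergedAt = 0;
  const double cnoise = std::sqrt(1.0 - c1 * c1);

  for (int step = 1; step <= nSteps; ++step) {
    for (int i = 0; i < N; ++i) {
      if (fix[i]) continue;
      const double h = hdtm[i];
      for (int c = 0; c < 3; ++c) {
        v[3 * i + c] += h * f[3 * i + c];
        x[3 * i + c] += 0.5 * dt * v[3 * i + c];
      }
    }
    for (int i = 0; i < N; ++i) {
      if (fix[i]) continue;
      const double cs = cnoise * sig[i];
      for (int c = 0; c < 3; ++c) {
        v[3 * i + c] = c1 * v[3 * i + c] + cs * norm_rand();
        x[3 * i + c] += 0.5 * dt * v[3 * i + c];
      }
    }
    const double ep = computeForces();
    for (int i = 0; i < N; ++i) {
      if (fix[i]) continue;
      const double h = hdtm[i];
      for (int c = 0; c < 3; ++c) v[3 * i + c] += h * f[3 * i + c];
    }
    if (step % recordEvery == 0) {
      bool bad = false;
      for (int k = 0; k < 3 * N; ++k)
        if (!std::isfinite(x[k]) || std::fabs(x[k]) > 1e6) { bad = true; break; }
      if (bad) { divergedAt = step; break; }
      ++fi;
      std::copy(x.begin(), x.end(), fr + static_cast<R_xlen_t>(fi) * N * 3);
      epotTrace[fi] = ep;
    }
  }

  return List::create(_["frames"] = frames, _["nFrames"] = fi + 1,
                      _["epot"] = epotTrace, _["divergedAt"] = divergedAt);
}
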