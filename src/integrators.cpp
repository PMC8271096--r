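#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Delayed-network stochastic Heun integrators.
//
// Both integrators keep the full state history in memory so delayed terms
// are read by direct indexing; the pre-history is constant at the random
// initial state. Noise is drawn from R's RNG via unif_rand(), so
// set.seed() on the R side makes trajectories bit-reproducible. The Heun
// scheme evaluates the deterministic drift at the current state and at
// the Euler predictor; the uniform noise increment is added after the
// corrector, scaled by sqrt(dt) (diffusion convention) or dt.
//
// Layout note: the history buffer interleaves the two per-oscillator
// components (sin/cos of the phase, or Re/Im of z) so one delayed read
// touches a single cache line. The predictor state is written into the
// next history slot before stage 2, which lets zero-delay entries read
// the predictor through the same indexing path as delayed entries; the
// slot is overwritten with the corrected state afterwards.

// Kuramoto phase network with pairwise delays:
//   dphi_j/dt = 2*pi*f_j + sum_n wc_jn * sin(phi_n(t - tau_jn) - phi_j) + noise
// wc must already contain C/N * w. The observable is sin(phi_j).
// [[Rcpp::export]]
List sim_phase_cpp(NumericVector f, NumericMatrix wc, IntegerMatrix dsteps,
                   double dt, int n_total, int n_trans,
                   double noise_amp, bool noise_sqrtdt) {
  const int N = f.size();
  const double twopi = 2.0 * M_PI;
  const double nscale = noise_sqrtdt ? std::sqrt(dt) : dt;

  std::vector<double> w(N * N);
  std::vector<ptrdiff_t> doff(N * N); // delayed-read slot offset: 2*d*N
  int maxd = 0;
  for (int j = 0; j < N; ++j)
    for (int n = 0; n < N; ++n) {
      w[(size_t)j * N + n] = wc(j, n);
      const int dn = dsteps(j, n);
      if (dn > maxd) maxd = dn;
      doff[(size_t)j * N + n] = 2 * (ptrdiff_t)dn * N;
    }

  // interleaved (sin, cos) history, slot t at buf + 2*t*N
  std::vector<double> buf(2 * (size_t)(n_total + 1) * N);
  std::vector<double> phi(N), k1(N), php(N);

  GetRNGstate();
  for (int j = 0; j < N; ++j) phi[j] = twopi * unif_rand();
  for (int j = 0; j < N; ++j) {
    buf[2 * j] = std::sin(phi[j]);
    buf[2 * j + 1] = std::cos(phi[j]);
  }

  bool diverged = false;
  int div_step = -1;

  for (int t = 0; t < n_total; ++t) {
    const double *cur = &buf[2 * (size_t)t * N];
    double *nxt = &buf[2 * (size_t)(t + 1) * N];
    const bool early = t <= maxd; // pre-history clamping needed
    // stage 1: drift at current state, delayed reads at t - d
    for (int j = 0; j < N; ++j) {
      const double sj = cur[2 * j], cj = cur[2 * j + 1];
      const double *wj = &w[(size_t)j * N];
      const ptrdiff_t *oj = &doff[(size_t)j * N];
      double acc = 0.0;
      if (early) {
        for (int n = 0; n < N; ++n) {
          ptrdiff_t off = 2 * (ptrdiff_t)t * N + 2 * n - oj[n];
          if (off < 2 * n) off = 2 * n; // constant pre-history
          acc += wj[n] * (buf[off] * cj - buf[off + 1] * sj);
        }
      } else {
        const double *base = &buf[2 * (size_t)t * N];
        for (int n = 0; n < N; ++n) {
          const double *p = base + 2 * n - oj[n];
          acc += wj[n] * (p[0] * cj - p[1] * sj);
        }
      }
      k1[j] = twopi * f[j] + acc;
      php[j] = phi[j] + dt * k1[j];
    }
    // predictor into the next slot so stage 2 indexes uniformly
    for (int j = 0; j < N; ++j) {
      nxt[2 * j] = std::sin(php[j]);
      nxt[2 * j + 1] = std::cos(php[j]);
    }
    // stage 2: drift at predictor, delayed reads at (t+1) - d
    for (int j = 0; j < N; ++j) {
      const double sj = nxt[2 * j], cj = nxt[2 * j + 1];
      const double *wj = &w[(size_t)j * N];
      const ptrdiff_t *oj = &doff[(size_t)j * N];
      double acc = 0.0;
      if (early) {
        for (int n = 0; n < N; ++n) {
          ptrdiff_t off = 2 * (ptrdiff_t)(t + 1) * N + 2 * n - oj[n];
          if (off < 2 * n) off = 2 * n;
          acc += wj[n] * (buf[off] * cj - buf[off + 1] * sj);
        }
      } else {
        const double *base = nxt;
        for (int n = 0; n < N; ++n) {
          const double *p = base + 2 * n - oj[n];
          acc += wj[n] * (p[0] * cj - p[1] * sj);
        }
      }
      const double k2 = twopi * f[j] + acc;
      double eta = noise_amp > 0.0 ? (2.0 * unif_rand() - 1.0) * noise_amp : 0.0;
      phi[j] += 0.5 * dt * (k1[j] + k2) + eta * nscale;
    }
    for (int j = 0; j < N; ++j) {
      nxt[2 * j] = std::sin(phi[j]);
      nxt[2 * j + 1] = std::cos(phi[j]);
    }
    if ((t & 1023) == 0) {
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(phi[j])) { diverged = true; div_step = t + 1; }
      if (diverged) break;
    }
  }
  PutRNGstate();

  if (!diverged)
    for (int j = 0; j < N; ++j)
      if (!std::isfinite(phi[j])) { diverged = true; div_step = n_total; }

  const int n_ret = n_total - n_trans;
  NumericMatrix out(diverged ? 0 : n_ret, N);
  if (!diverged)
    for (int r = 0; r < n_ret; ++r) {
      const double *row = &buf[2 * (size_t)(n_trans + 1 + r) * N];
      for (int j = 0; j < N; ++j) out(r, j) = row[2 * j];
    }
  return List::create(_["observable"] = out, _["diverged"] = diverged,
                      _["step"] = div_step);
}

// Hopf limit-cycle network, z_j = x_j + i y_j:
//   dz_j/dt = (a_j + i*2*pi*f_j - |z_j|^2) z_j
//             + sum_n wc_jn (z_n(t - tau_jn) - z_j) + noise
// wc must already contain C/N * w. The observable is x_j = Re(z_j).
// Noise is drawn independently for the real and imaginary parts.
// [[Rcpp::export]]
List sim_hopf_cpp(NumericVector f, NumericVector a, NumericMatrix wc,
                  IntegerMatrix dsteps, double dt, int n_total, int n_trans,
                  double noise_amp, bool noise_sqrtdt) {
  const int N = f.size();
  const double twopi = 2.0 * M_PI;
  const double nscale = noise_sqrtdt ? std::sqrt(dt) : dt;

  std::vector<double> w(N * N);
  std::vector<ptrdiff_t> doff(N * N); // delayed-read slot offset: 2*d*N
  std::vector<double> rs(N, 0.0); // row sums of wc: the -z_j coupling term
  int maxd = 0;
  for (int j = 0; j < N; ++j)
    for (int n = 0; n < N; ++n) {
      w[(size_t)j * N + n] = wc(j, n);
      const int dn = dsteps(j, n);
      if (dn > maxd) maxd = dn;
      doff[(size_t)j * N + n] = 2 * (ptrdiff_t)dn * N;
      rs[j] += wc(j, n);
    }

  // interleaved (x, y) history
  std::vector<double> buf(2 * (size_t)(n_total + 1) * N);
  std::vector<double> x(N), y(N), k1x(N), k1y(N);

  GetRNGstate();
  // uniform in the unit disk via the polar transform (no rejection)
  for (int j = 0; j < N; ++j) {
    const double r = std::sqrt(unif_rand());
    const double th = twopi * unif_rand();
    x[j] = r * std::cos(th);
    y[j] = r * std::sin(th);
    buf[2 * j] = x[j];
    buf[2 * j + 1] = y[j];
  }

  bool diverged = false;
  int div_step = -1;

  for (int t = 0; t < n_total; ++t) {
    double *nxt = &buf[2 * (size_t)(t + 1) * N];
    const bool early = t <= maxd;
    for (int j = 0; j < N; ++j) {
      const double *wj = &w[(size_t)j * N];
      const ptrdiff_t *oj = &doff[(size_t)j * N];
      double accx = 0.0, accy = 0.0;
      if (early) {
        for (int n = 0; n < N; ++n) {
          ptrdiff_t off = 2 * (ptrdiff_t)t * N + 2 * n - oj[n];
          if (off < 2 * n) off = 2 * n;
          accx += wj[n] * buf[off];
          accy += wj[n] * buf[off + 1];
        }
      } else {
        const double *base = &buf[2 * (size_t)t * N];
        for (int n = 0; n < N; ++n) {
          const double *p = base + 2 * n - oj[n];
          accx += wj[n] * p[0];
          accy += wj[n] * p[1];
        }
      }
      const double r2 = x[j] * x[j] + y[j] * y[j];
      const double om = twopi * f[j];
      k1x[j] = (a[j] - r2) * x[j] - om * y[j] + accx - rs[j] * x[j];
      k1y[j] = (a[j] - r2) * y[j] + om * x[j] + accy - rs[j] * y[j];
      nxt[2 * j] = x[j] + dt * k1x[j];
      nxt[2 * j + 1] = y[j] + dt * k1y[j];
    }
    for (int j = 0; j < N; ++j) {
      const double *wj = &w[(size_t)j * N];
      const ptrdiff_t *oj = &doff[(size_t)j * N];
      double accx = 0.0, accy = 0.0;
      if (early) {
        for (int n = 0; n < N; ++n) {
          ptrdiff_t off = 2 * (ptrdiff_t)(t + 1) * N + 2 * n - oj[n];
          if (off < 2 * n) off = 2 * n;
          accx += wj[n] * buf[off];
          accy += wj[n] * buf[off + 1];
        }
      } else {
        for (int n = 0; n < N; ++n) {
          const double *p = nxt + 2 * n - oj[n];
          accx += wj[n] * p[0];
          accy += wj[n] * p[1];
        }
      }
      const double xp = nxt[2 * j], yp = nxt[2 * j + 1];
      const double r2 = xp * xp + yp * yp;
      const double om = twopi * f[j];
      const double k2x = (a[j] - r2) * xp - om * yp + accx - rs[j] * xp;
      const double k2y = (a[j] - r2) * yp + om * xp + accy - rs[j] * yp;
      double ex = 0.0, ey = 0.0;
      if (noise_amp > 0.0) {
        ex = (2.0 * unif_rand() - 1.0) * noise_amp;
        ey = (2.0 * unif_rand() - 1.0) * noise_amp;
      }
      x[j] += 0.5 * dt * (k1x[j] + k2x) + ex * nscale;
      y[j] += 0.5 * dt * (k1y[j] + k2y) + ey * nscale;
    }
    for (int j = 0; j < N; ++j) {
      nxt[2 * j] = x[j];
      nxt[2 * j + 1] = y[j];
    }
    if ((t & 255) == 0) {
      for (int j = 0; j < N; ++j)
        if (!std::isfinite(x[j]) || !std::isfinite(y[j])) {
          diverged = true;
          div_step = t + 1;
        }
      if (diverged) break;
    }
  }
  PutRNGstate();

  if (!diverged)
    for (int j = 0; j < N; ++j)
      if (!std::isfinite(x[j]) || !std::isfinite(y[j])) {
        diverged = true;
        div_step = n_total;
      }

  const int n_ret = n_total - n_trans;
  NumericMatrix outx(diverged ? 0 : n_ret, N);
  NumericMatrix outy(diverged ? 0 : n_ret, N);
  if (!diverged)
    for (int r = 0; r < n_ret; ++r) {
      const double *row = &buf[2 * (size_t)(n_trans + 1 + r) * N];
      for (int j = 0; j < N; ++j) {
        outx(r, j) = row[2 * j];
        outy(r, j) = row[2 * j + 1];
      }
    }
  return List::create(_["observable"] = outx, _["imag"] = outy,
                      _["diverged"] = diverged, _["step"] = div_step);
}
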