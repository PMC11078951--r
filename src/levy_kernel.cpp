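#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "rng.h"

using namespace Rcpp;

// Chambers-Mallows-Stuck draw from a symmetric alpha-stable law SaS(alpha, scale)
static inline double sas_draw(Xoshiro &rng, double alpha, double scale) {
  if (alpha == 2.0) return scale * std::sqrt(2.0) * rng.norm();
  const double U = M_PI * (rng.unif() - 0.5);
  const double E = rng.expo();
  const double t1 = std::sin(alpha * U) / std::pow(std::cos(U), 1.0 / alpha);
  const double t2 = std::pow(std::cos(U - alpha * U) / E, (1.0 - alpha) / alpha);
  return scale * t1 * t2;
}

// [[Rcpp::export(name = ".rsas")]]
NumericVector rsas(int n, double alpha, double scale, int seed) {
  if (alpha <= 1.0 || alpha > 2.0) stop("tail index must lie in (1, 2]");
  Xoshiro rng((uint64_t)seed * 0xA24BAED4ULL + 3ULL);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sas_draw(rng, alpha, scale);
  return out;
}

static inline double torus_d2(double ax, double ay, double bx, double by,
                              double L) {
  double dx = std::fabs(ax - bx);
  if (dx > L / 2) dx = L - dx;
  double dy = std::fabs(ay - by);
  if (dy > L / 2) dy = L - dy;
  return dx * dx + dy * dy;
}

static inline double wrap(double x, double L) {
  // map into [-L/2, L/2)
  double w = x + L / 2;
  w -= L * std::floor(w / L);
  return w - L / 2;
}

// Euler-Maruyama integration of the Levy walker with momentum in a
// potential-well landscape, plus inhomogeneous-Poisson (Bernoulli-per-step)
// spike counts for a set of observer neurons, accumulated in fixed windows.
//
// wells: matrix with columns (x, y, depth) where depth = D_s + D_a;
// the drift inside a well is -grad(rho) * pref with
// rho_i = depth_i * (d^2/sigma_p^2 - 1) for d < sigma_p, 0 outside.
// The rate field is A_r * exp(-d_walker^2 / (2 sigma_r^2)) + A0(x) with the
// baseline boost 0.2 * Da1 * (1 - d1^2/sigma_p^2) inside the first well.
//
// [[Rcpp::export(name = ".levy_kernel")]]
List levy_kernel(int n_steps, double dt, double alpha, double gamma_,
                 double beta, NumericMatrix wells, double sigma_p,
                 double pref, NumericVector nx, NumericVector ny,
                 double A_r, double sigma_r, double A_b, double Da1,
                 double L, int window_steps, double x0, double y0,
                 int keep_traj_every, int seed) {
  Xoshiro rng((uint64_t)seed * 0xD1B54A32ULL + 7ULL);
  const int n_wells = wells.nrow();
  const int n_neu = nx.size();
  const int n_win = window_steps > 0 ? n_steps / window_steps : 0;
  const double sas_scale = std::pow(gamma_ * dt, 1.0 / alpha);
  const double sp2 = sigma_p * sigma_p;
  const double inv2sr2 = 1.0 / (2.0 * sigma_r * sigma_r);

  // per-neuron baseline rate (depends only on neuron position)
  std::vector<double> A0(n_neu, A_b);
  if (Da1 > 0 && n_wells > 0) {
    for (int j = 0; j < n_neu; ++j) {
      const double d21 = torus_d2(nx[j], ny[j], wells(0, 0), wells(0, 1), L);
      if (d21 < sp2) A0[j] = A_b - 0.2 * Da1 * (d21 / sp2 - 1.0);
    }
  }

  IntegerMatrix counts(std::max(n_win, 0), n_neu);
  const int n_keep = keep_traj_every > 0 ? n_steps / keep_traj_every : 0;
  NumericMatrix traj(n_keep, 2);

  double x = x0, y = y0, vx = 0.0, vy = 0.0;

  for (int s = 0; s < n_steps; ++s) {
    // drift from the landscape at the current position
    double bx = 0.0, by = 0.0;
    for (int w = 0; w < n_wells; ++w) {
      double dx = x - wells(w, 0);
      if (dx > L / 2) dx -= L; else if (dx < -L / 2) dx += L;
      double dy = y - wells(w, 1);
      if (dy > L / 2) dy -= L; else if (dy < -L / 2) dy += L;
      const double d2 = dx * dx + dy * dy;
      if (d2 < sp2) {
        const double g = -2.0 * wells(w, 2) / sp2 * pref;
        bx += g * dx;
        by += g * dy;
      }
    }
    // spike counts before moving (rates from current walker position)
    if (window_steps > 0) {
      const int win = s / window_steps;
      if (win < n_win) {
        for (int j = 0; j < n_neu; ++j) {
          const double d2w = torus_d2(nx[j], ny[j], x, y, L);
          const double rate = A_r * std::exp(-d2w * inv2sr2) + A0[j];
          if (rng.unif() < rate * dt) counts(win, j) += 1;
        }
      }
    }
    if (keep_traj_every > 0 && s % keep_traj_every == 0) {
      const int r = s / keep_traj_every;
      if (r < n_keep) { traj(r, 0) = x; traj(r, 1) = y; }
    }
    // Euler-Maruyama step
    x += gamma_ * bx * dt + beta * vx * dt + sas_draw(rng, alpha, sas_scale);
    y += gamma_ * by * dt + beta * vy * dt + sas_draw(rng, alpha, sas_scale);
    vx += beta * bx * dt;
    vy += beta * by * dt;
    x = wrap(x, L);
    y = wrap(y, L);
    if (!std::isfinite(x) || !std::isfinite(y))
      stop("walker diverged at step %d", s);
  }

  return List::create(_["counts"] = counts, _["traj"] = traj);
}
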