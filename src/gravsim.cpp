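#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gravitational field of the (inhibition-discounted) support masses at
// focus (ax, ay): E = sum_j (x_j - a) * mu_j / (2*pi*(||x_j - a||^2 + eps))
static inline void field_sum(const double *px, const double *py,
                             const double *mu, int n, double eps,
                             double ax, double ay,
                             double &ex, double &ey) {
  double sx = 0.0, sy = 0.0;
  for (int j = 0; j < n; ++j) {
    double dx = px[j] - ax;
    double dy = py[j] - ay;
    double w = mu[j] / (dx * dx + dy * dy + eps);
    sx += dx * w;
    sy += dy * w;
  }
  ex = sx / (2.0 * M_PI);
  ey = sy / (2.0 * M_PI);
}

// Operator-split fixed-step integration of the damped Newtonian focus
// dynamics coupled to the inhibition-of-return field. Mirrors the R
// reference loop in simulate_attention(engine = "r") step for step.
// [[Rcpp::export(name = ".grav_sim_cpp")]]
List grav_sim_cpp(NumericVector sup_px, NumericVector sup_py,
                  NumericVector sup_mu, IntegerVector sup_idx,
                  int h, int w, double lam, double beta,
                  double sigma_ior, double eps, double dt,
                  int n_steps, double time_scale,
                  NumericVector a0, NumericVector v0) {
  const int n = sup_mu.size();
  const double *px = REAL(sup_px), *py = REAL(sup_py);
  std::vector<double> mu_eff(n);
  NumericMatrix I(h, w);
  std::vector<double> gx(w), gy(h);
  const double decay = std::exp(-beta * dt);
  const double inv2s2 = (sigma_ior > 0) ? 1.0 / (2.0 * sigma_ior * sigma_ior)
                                        : 0.0;

  NumericMatrix out(n_steps + 1, 5);
  double ax = a0[0], ay = a0[1], vx = v0[0], vy = v0[1];
  out(0, 0) = 0.0;
  out(0, 1) = ax; out(0, 2) = ay;
  out(0, 3) = vx * time_scale; out(0, 4) = vy * time_scale;

  for (int k = 1; k <= n_steps; ++k) {
    // freeze the effective mass over the step
    if (beta > 0) {
      for (int j = 0; j < n; ++j) {
        int idx = sup_idx[j] - 1;           // column-major linear index
        mu_eff[j] = sup_mu[j] * (1.0 - I[idx]);
      }
    } else {
      for (int j = 0; j < n; ++j) mu_eff[j] = sup_mu[j];
    }
    const double *me = mu_eff.data();

    // one RK4 step of (a' = v, v' = -lam v + E(a))
    double ex, ey;
    field_sum(px, py, me, n, eps, ax, ay, ex, ey);
    double k1ax = vx, k1ay = vy;
    double k1vx = -lam * vx + ex, k1vy = -lam * vy + ey;

    double a2x = ax + 0.5 * dt * k1ax, a2y = ay + 0.5 * dt * k1ay;
    double v2x = vx + 0.5 * dt * k1vx, v2y = vy + 0.5 * dt * k1vy;
    field_sum(px, py, me, n, eps, a2x, a2y, ex, ey);
    double k2ax = v2x, k2ay = v2y;
    double k2vx = -lam * v2x + ex, k2vy = -lam * v2y + ey;

    double a3x = ax + 0.5 * dt * k2ax, a3y = ay + 0.5 * dt * k2ay;
    double v3x = vx + 0.5 * dt * k2vx, v3y = vy + 0.5 * dt * k2vy;
    field_sum(px, py, me, n, eps, a3x, a3y, ex, ey);
    double k3ax = v3x, k3ay = v3y;
    double k3vx = -lam * v3x + ex, k3vy = -lam * v3y + ey;

    double a4x = ax + dt * k3ax, a4y = ay + dt * k3ay;
    double v4x = vx + dt * k3vx, v4y = vy + dt * k3vy;
    field_sum(px, py, me, n, eps, a4x, a4y, ex, ey);
    double k4ax = v4x, k4ay = v4y;
    double k4vx = -lam * v4x + ex, k4vy = -lam * v4y + ey;

    ax += dt / 6.0 * (k1ax + 2.0 * k2ax + 2.0 * k3ax + k4ax);
    ay += dt / 6.0 * (k1ay + 2.0 * k2ay + 2.0 * k3ay + k4ay);
    vx += dt / 6.0 * (k1vx + 2.0 * k2vx + 2.0 * k3vx + k4vx);
    vy += dt / 6.0 * (k1vy + 2.0 * k2vy + 2.0 * k3vy + k4vy);

    if (!std::isfinite(ax) || !std::isfinite(ay) ||
        !std::isfinite(vx) || !std::isfinite(vy)) {
      stop("simulation diverged at step %d", k);
    }

    // wall clamp with outward-velocity zeroing
    if (ax < 0) { ax = 0; if (vx < 0) vx = 0; }
    if (ax > w - 1) { ax = w - 1; if (vx > 0) vx = 0; }
    if (ay < 0) { ay = 0; if (vy < 0) vy = 0; }
    if (ay > h - 1) { ay = h - 1; if (vy > 0) vy = 0; }

    // exact exponential relaxation of I toward the bump at the focus
    if (beta > 0) {
      for (int c = 0; c < w; ++c) {
        double d = c - ax;
        gx[c] = std::exp(-d * d * inv2s2);
      }
      for (int r = 0; r < h; ++r) {
        double d = r - ay;
        gy[r] = std::exp(-d * d * inv2s2);
      }
      for (int c = 0; c < w; ++c) {
        double gxc = gx[c];
        for (int r = 0; r < h; ++r) {
          double g = gy[r] * gxc;
          I(r, c) = g + (I(r, c) - g) * decay;
        }
      }
    }

    out(k, 0) = k * dt / time_scale;
    out(k, 1) = ax; out(k, 2) = ay;
    out(k, 3) = vx * time_scale; out(k, 4) = vy * time_scale;
  }
  return List::create(_["traj"] = out, _["I"] = I);
}
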