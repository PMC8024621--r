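// Adaptive integrator for the noisy delayed Kuramoto system
//
//   dtheta_i/dt = omega_i + sum_j Wg[i][j] sin(theta_j(t - tau_ij) - theta_i(t))
//
// with additive Gaussian phase noise applied at fixed macro-steps
// (Euler-Maruyama). The deterministic delay differential equation is advanced
// inside each macro-step with the embedded Bogacki-Shampine 3(2) pair; the
// delayed state is evaluated by cubic Hermite interpolation on the dense
// history of accepted steps. All times are in ms, rates in rad/ms; Wg already
// contains the coupling prefactor.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Edge {
  int j;        // source node index
  double w;     // coupling weight (rad/ms, prefactor included)
  double tau;   // transmission delay (ms)
  mutable int hint; // last history interval used for this edge
};

class History {
public:
  explicit History(int n) : n_(n) {}
  void reserve(size_t m) {
    t_.reserve(m);
    th_.reserve(m * n_);
    f_.reserve(m * n_);
  }
  void push(double t, const std::vector<double>& th, const std::vector<double>& f) {
    t_.push_back(t);
    th_.insert(th_.end(), th.begin(), th.end());
    f_.insert(f_.end(), f.begin(), f.end());
  }
  // overwrite the state/derivative of the most recent entry (post-noise jump)
  void rewrite_last(const std::vector<double>& th, const std::vector<double>& f) {
    size_t off = (t_.size() - 1) * n_;
    for (int i = 0; i < n_; ++i) {
      th_[off + i] = th[i];
      f_[off + i] = f[i];
    }
  }
  // theta_j at time s; s <= last recorded time except for sub-step lags,
  // where we fall back on linear extrapolation from the last entry.
  double eval(int j, double s, int& hint, const std::vector<double>& theta0) const {
    if (s <= 0.0) return theta0[j];
    const int m = static_cast<int>(t_.size());
    if (s >= t_[m - 1]) {
      size_t off = (m - 1) * static_cast<size_t>(n_);
      return th_[off + j] + f_[off + j] * (s - t_[m - 1]);
    }
    int k = hint;
    if (k < 0) k = 0;
    if (k > m - 2) k = m - 2;
    while (k + 1 < m - 1 && t_[k + 1] <= s) ++k;
    while (k > 0 && t_[k] > s) --k;
    hint = k;
    const double t0 = t_[k], t1 = t_[k + 1];
    const double h = t1 - t0;
    size_t o0 = static_cast<size_t>(k) * n_ + j;
    size_t o1 = o0 + n_;
    if (h <= 0.0) return th_[o1];
    const double u = (s - t0) / h;
    const double u2 = u * u, u3 = u2 * u;
    return (2.0 * u3 - 3.0 * u2 + 1.0) * th_[o0]
         + (u3 - 2.0 * u2 + u) * h * f_[o0]
         + (-2.0 * u3 + 3.0 * u2) * th_[o1]
         + (u3 - u2) * h * f_[o1];
  }
private:
  int n_;
  std::vector<double> t_, th_, f_;
};

} // namespace

// [[Rcpp::export]]
List dde_kuramoto_cpp(const NumericMatrix& Wg,
                      const NumericMatrix& tau,
                      const NumericVector& omega,
                      const NumericVector& theta0,
                      double noise_step_sd,
                      double t_end,
                      double t_record_start,
                      double record_dt,
                      double abs_tol,
                      double rel_tol,
                      double min_step) {
  const int n = Wg.nrow();
  if (Wg.ncol() != n || tau.nrow() != n || tau.ncol() != n)
    stop("coupling and delay matrices must be square and conformable");

  // incoming edges per node: row i of Wg holds inputs to i from j
  std::vector<std::vector<Edge> > edges(n);
  double min_pos_tau = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double w = Wg(i, j);
      if (w != 0.0) {
        Edge e;
        e.j = j;
        e.w = w;
        e.tau = tau(i, j);
        e.hint = 0;
        edges[i].push_back(e);
        if (e.tau > 0.0 && e.tau < min_pos_tau) min_pos_tau = e.tau;
      }
    }
  }

  const int n_macro = static_cast<int>(std::floor(t_end / record_dt + 0.5));
  if (std::fabs(n_macro * record_dt - t_end) > 1e-6 * record_dt)
    stop("t_end must be a whole number of recording steps");
  const int rec_from = static_cast<int>(std::floor(t_record_start / record_dt + 0.5));
  const int n_rec = n_macro - rec_from + 1;
  if (n_rec < 1) stop("recording window is empty");

  std::vector<double> th0(theta0.begin(), theta0.end());
  std::vector<double> y(th0), ynew(n), ytmp(n), k1(n), k2(n), k3(n), k4(n), errv(n);

  History hist(n);
  hist.reserve(static_cast<size_t>(n_macro) * 3 + 8);

  // right-hand side; delayed lookups go through the dense history
  auto rhs = [&](double t, const std::vector<double>& th, std::vector<double>& out) {
    for (int i = 0; i < n; ++i) {
      double s = omega[i];
      const double thi = th[i];
      const std::vector<Edge>& ei = edges[i];
      for (size_t e = 0; e < ei.size(); ++e) {
        const Edge& ed = ei[e];
        double thj = (ed.tau <= 0.0)
          ? th[ed.j]
          : hist.eval(ed.j, t - ed.tau, ed.hint, th0);
        s += ed.w * std::sin(thj - thi);
      }
      out[i] = s;
    }
  };

  double t = 0.0;
  rhs(t, y, k1);
  hist.push(t, y, k1);

  double h = record_dt / 4.0;
  if (min_pos_tau < h) h = min_pos_tau;
  if (h < min_step) h = min_step;

  long n_accept = 0, n_reject = 0;
  NumericMatrix out(n, n_rec);
  NumericVector out_times(n_rec);
  if (rec_from == 0) {
    for (int i = 0; i < n; ++i) out(i, 0) = y[i];
    out_times[0] = 0.0;
  }

  const double noise_on = noise_step_sd > 0.0 ? 1.0 : 0.0;

  for (int m = 1; m <= n_macro; ++m) {
    const double t_target = m * record_dt;
    while (t < t_target - 1e-9 * record_dt) {
      double hstep = h;
      if (hstep > min_pos_tau) hstep = min_pos_tau; // avoid lag overlap
      if (hstep < min_step) hstep = min_step;
      if (hstep > t_target - t) hstep = t_target - t;

      // Bogacki-Shampine 3(2), FSAL
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.5 * hstep * k1[i];
      rhs(t + 0.5 * hstep, ytmp, k2);
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + 0.75 * hstep * k2[i];
      rhs(t + 0.75 * hstep, ytmp, k3);
      for (int i = 0; i < n; ++i)
        ynew[i] = y[i] + hstep * (2.0 / 9.0 * k1[i] + 1.0 / 3.0 * k2[i] + 4.0 / 9.0 * k3[i]);
      rhs(t + hstep, ynew, k4);

      double err2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = hstep * (-5.0 / 72.0 * k1[i] + 1.0 / 12.0 * k2[i]
                            + 1.0 / 9.0 * k3[i] - 1.0 / 8.0 * k4[i]);
        double ay = std::fabs(y[i]), an = std::fabs(ynew[i]);
        double sc = abs_tol + rel_tol * (ay > an ? ay : an);
        double r = e / sc;
        err2 += r * r;
      }
      double errnorm = std::sqrt(err2 / n);
      if (!std::isfinite(errnorm))
        stop("non-finite state at t = %f ms", t);

      if (errnorm <= 1.0 || hstep <= min_step * (1.0 + 1e-12)) {
        t += hstep;
        y = ynew;
        k1 = k4; // FSAL
        hist.push(t, y, k1);
        ++n_accept;
      } else {
        ++n_reject;
      }
      double fac = 0.9 * std::pow(errnorm > 1e-10 ? errnorm : 1e-10, -1.0 / 3.0);
      if (fac < 0.2) fac = 0.2;
      if (fac > 5.0) fac = 5.0;
      h = hstep * fac;
      if (h < min_step) h = min_step;
      if (h > record_dt) h = record_dt;
    }
    t = t_target;

    if (noise_on > 0.0) {
      for (int i = 0; i < n; ++i) y[i] += noise_step_sd * norm_rand();
      rhs(t, y, k1);
      hist.rewrite_last(y, k1);
    }

    if (m >= rec_from) {
      const int col = m - rec_from;
      for (int i = 0; i < n; ++i) out(i, col) = y[i];
      out_times[col] = t_target;
    }
  }

  return List::create(_["times"] = out_times,
                      _["phases"] = out,
                      _["n_accepted"] = static_cast<double>(n_accept),
                      _["n_rejected"] = static_cast<double>(n_reject));
}
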