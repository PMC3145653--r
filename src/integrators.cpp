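// Adaptive Dormand-Prince RK5(4) integration of sigmoidal regulatory
// networks dX_i/dt = gamma_i * (F(sigma_i * W_i) - X_i), with
// piecewise-constant external signals and optional steady-state early exit.
// The batch entry points exist because the population layer integrates
// 10^4-10^5 cells per experiment; everything else is thin plumbing.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

inline double logistic(double u) { return 1.0 / (1.0 + std::exp(-u)); }

// One cell's realized network: n dynamic species, ns external signals,
// weight matrix W is n x (n + ns), column-major, species columns first.
struct Net {
  int n, ns;
  const double *gamma, *sigma, *beta, *W;

  void rhs(const double* x, const double* s, double* dx) const {
    for (int i = 0; i < n; ++i) {
      double w = beta[i];
      for (int j = 0; j < n; ++j)  w += W[i + n * j] * x[j];
      for (int k = 0; k < ns; ++k) w += W[i + n * (n + k)] * s[k];
      dx[i] = gamma[i] * (logistic(sigma[i] * w) - x[i]);
    }
  }
};

// Dormand-Prince coefficients (5th-order solution, embedded 4th for error).
const double A21 = 1.0 / 5.0;
const double A31 = 3.0 / 40.0, A32 = 9.0 / 40.0;
const double A41 = 44.0 / 45.0, A42 = -56.0 / 15.0, A43 = 32.0 / 9.0;
const double A51 = 19372.0 / 6561.0, A52 = -25360.0 / 2187.0,
             A53 = 64448.0 / 6561.0, A54 = -212.0 / 729.0;
const double A61 = 9017.0 / 3168.0, A62 = -355.0 / 33.0,
             A63 = 46732.0 / 5247.0, A64 = 49.0 / 176.0,
             A65 = -5103.0 / 18656.0;
const double B1 = 35.0 / 384.0, B3 = 500.0 / 1113.0, B4 = 125.0 / 192.0,
             B5 = -2187.0 / 6784.0, B6 = 11.0 / 84.0;
const double E1 = B1 - 5179.0 / 57600.0, E3 = B3 - 7571.0 / 16695.0,
             E4 = B4 - 393.0 / 640.0, E5 = B5 + 92097.0 / 339200.0,
             E6 = B6 - 187.0 / 2100.0, E7 = -1.0 / 40.0;

struct Integrator {
  const Net& net;
  double rtol, atol, ss_tol, max_dt;
  // output sink: if out != nullptr, states at out_times are recorded either
  // one row per time (cell_row < 0) or into row cell_row with time-major,
  // species-fastest column blocks (batch mode).
  NumericMatrix* out;
  const NumericVector* out_times;
  int cell_row, iout;
  std::vector<double> k1, k2, k3, k4, k5, k6, k7, xt, xnew;
  bool converged;
  double t_stop;

  Integrator(const Net& net_, double rtol_, double atol_, double ss_tol_)
      : net(net_), rtol(rtol_), atol(atol_), ss_tol(ss_tol_), max_dt(5.0),
        out(nullptr), out_times(nullptr), cell_row(-1), iout(0),
        k1(net_.n), k2(net_.n), k3(net_.n), k4(net_.n), k5(net_.n),
        k6(net_.n), k7(net_.n), xt(net_.n), xnew(net_.n),
        converged(false), t_stop(NA_REAL) {}

  double inf_norm(const std::vector<double>& v) const {
    double m = 0.0;
    for (double z : v) m = std::max(m, std::fabs(z));
    return m;
  }

  void record_upto(double t, const std::vector<double>& x) {
    if (out == nullptr) return;
    while (iout < out_times->size() && (*out_times)[iout] <= t + 1e-12) {
      if (cell_row >= 0) {
        for (int i = 0; i < net.n; ++i)
          (*out)(cell_row, iout * net.n + i) = x[i];
      } else {
        for (int i = 0; i < net.n; ++i) (*out)(iout, i) = x[i];
      }
      ++iout;
    }
  }

  // Integrate one segment [t, t_b] at constant signals s.  allow_ss:
  // steady-state early exit permitted (only in the final segment, where the
  // signals no longer change).
  void segment(std::vector<double>& x, double& t, double t_b, const double* s,
               bool allow_ss) {
    const int n = net.n;
    net.rhs(x.data(), s, k1.data());
    double dt = std::min(0.05, t_b - t);
    if (dt <= 0) return;
    int rejects_guard = 0;

    while (t < t_b - 1e-12) {
      if (allow_ss && ss_tol > 0 && inf_norm(k1) < ss_tol) {
        converged = true;
        t_stop = t;
        return;
      }
      dt = std::min(dt, t_b - t);
      if (out != nullptr && iout < out_times->size() &&
          (*out_times)[iout] > t + 1e-12)
        dt = std::min(dt, (*out_times)[iout] - t);

      for (int i = 0; i < n; ++i) xt[i] = x[i] + dt * A21 * k1[i];
      net.rhs(xt.data(), s, k2.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + dt * (A31 * k1[i] + A32 * k2[i]);
      net.rhs(xt.data(), s, k3.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + dt * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
      net.rhs(xt.data(), s, k4.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + dt * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] +
                             A54 * k4[i]);
      net.rhs(xt.data(), s, k5.data());
      for (int i = 0; i < n; ++i)
        xt[i] = x[i] + dt * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                             A64 * k4[i] + A65 * k5[i]);
      net.rhs(xt.data(), s, k6.data());
      for (int i = 0; i < n; ++i)
        xnew[i] = x[i] + dt * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                               B5 * k5[i] + B6 * k6[i]);
      net.rhs(xnew.data(), s, k7.data());

      double err = 0.0;
      for (int i = 0; i < n; ++i) {
        double e = dt * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                         E6 * k6[i] + E7 * k7[i]);
        double sc = atol + rtol * std::max(std::fabs(x[i]),
                                           std::fabs(xnew[i]));
        err = std::max(err, std::fabs(e) / sc);
      }

      if (err <= 1.0 || dt <= 1e-12) {
        t += dt;
        x = xnew;
        k1 = k7;  // first-same-as-last
        record_upto(t, x);
        double fac = (err > 0) ? 0.9 * std::pow(err, -0.2) : 5.0;
        dt *= std::min(5.0, std::max(0.2, fac));
        dt = std::min(dt, max_dt);
        rejects_guard = 0;
        for (int i = 0; i < n; ++i)
          if (!std::isfinite(x[i])) stop("non-finite state in integration");
      } else {
        dt *= std::max(0.1, 0.9 * std::pow(err, -0.2));
        if (++rejects_guard > 200) stop("integration step failure");
      }
    }
  }

  // Full piecewise-constant schedule run on [0, t_end].
  void run(std::vector<double>& x, const NumericVector& seg_start,
           const NumericMatrix& seg_vals, double t_end,
           const NumericVector& times, NumericMatrix* out_, int row = -1) {
    out = out_;
    out_times = &times;
    cell_row = row;
    iout = 0;
    converged = false;
    t_stop = NA_REAL;
    double t = 0.0;
    record_upto(0.0, x);
    std::vector<double> s(std::max(1, net.ns));
    const int nseg = seg_start.size();
    for (int k = 0; k < nseg && t < t_end - 1e-12; ++k) {
      double t_b = (k + 1 < nseg) ? std::min(seg_start[k + 1], t_end) : t_end;
      if (t_b <= t) continue;
      for (int j = 0; j < net.ns; ++j) s[j] = seg_vals(k, j);
      bool last = (k + 1 == nseg) || seg_start[k + 1] >= t_end;
      segment(x, t, t_b, s.data(), last);
      if (converged) break;
    }
    if (!converged) t_stop = std::min(t, t_end);
    // steady (or final) value fills any remaining sample times
    record_upto(t_end + 1.0, x);
  }
};

Net unpack_row(const NumericMatrix& cells, int row, int n, int ns,
               std::vector<double>& buf) {
  const int npar = 3 * n + n * (n + ns);
  buf.resize(npar);
  for (int j = 0; j < npar; ++j) buf[j] = cells(row, j);
  Net net;
  net.n = n;
  net.ns = ns;
  net.gamma = buf.data();
  net.sigma = buf.data() + n;
  net.beta = buf.data() + 2 * n;
  net.W = buf.data() + 3 * n;
  return net;
}

}  // namespace

// [[Rcpp::export]]
List cpp_integrate(NumericVector gamma, NumericVector sigma,
                   NumericVector beta, NumericMatrix W, NumericVector x0,
                   NumericVector seg_start, NumericMatrix seg_vals,
                   double t_end, NumericVector out_times, double rtol,
                   double atol, double ss_tol) {
  const int n = gamma.size();
  Net net{n, (int)seg_vals.ncol(), gamma.begin(), sigma.begin(), beta.begin(),
          W.begin()};
  Integrator integ(net, rtol, atol, ss_tol);
  std::vector<double> x(x0.begin(), x0.end());
  NumericMatrix out(out_times.size(), n);
  if (t_end > 0) {
    integ.run(x, seg_start, seg_vals, t_end, out_times, &out);
  } else {
    for (int k = 0; k < out_times.size(); ++k)
      for (int i = 0; i < n; ++i) out(k, i) = x[i];
    integ.t_stop = 0.0;
  }
  return List::create(_["states"] = out,
                      _["final"] = NumericVector(x.begin(), x.end()),
                      _["converged"] = integ.converged,
                      _["t_stop"] = integ.t_stop);
}

// Many cells (rows of packed parameters [gamma, sigma, beta, vec(W)]), one
// shared schedule; returns each cell's final state and convergence flag.
// x0 has either one row (shared) or one row per cell.
// [[Rcpp::export]]
List cpp_settle_cells(NumericMatrix cells, int n, int ns,
                      NumericVector seg_start, NumericMatrix seg_vals,
                      double t_end, NumericMatrix x0, double rtol,
                      double atol, double ss_tol) {
  const int ncell = cells.nrow();
  NumericMatrix finals(ncell, n);
  LogicalVector conv(ncell);
  NumericVector no_times(0);
  std::vector<double> buf;
  for (int c = 0; c < ncell; ++c) {
    Net net = unpack_row(cells, c, n, ns, buf);
    Integrator integ(net, rtol, atol, ss_tol);
    std::vector<double> x(n);
    for (int i = 0; i < n; ++i) x[i] = x0(x0.nrow() > 1 ? c : 0, i);
    if (t_end > 0) integ.run(x, seg_start, seg_vals, t_end, no_times, nullptr);
    for (int i = 0; i < n; ++i) finals(c, i) = x[i];
    conv[c] = integ.converged;
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["final"] = finals, _["converged"] = conv);
}

// Batch time-course: states returned as an ncell x (ntimes*n) matrix with
// species-fastest column blocks per sample time.
// [[Rcpp::export]]
List cpp_timecourse_cells(NumericMatrix cells, int n, int ns,
                          NumericVector seg_start, NumericMatrix seg_vals,
                          double t_end, NumericMatrix x0,
                          NumericVector out_times, double rtol, double atol,
                          double ss_tol) {
  const int ncell = cells.nrow();
  NumericMatrix out(ncell, out_times.size() * n);
  LogicalVector conv(ncell);
  std::vector<double> buf;
  for (int c = 0; c < ncell; ++c) {
    Net net = unpack_row(cells, c, n, ns, buf);
    Integrator integ(net, rtol, atol, ss_tol);
    std::vector<double> x(n);
    for (int i = 0; i < n; ++i) x[i] = x0(x0.nrow() > 1 ? c : 0, i);
    if (t_end > 0)
      integ.run(x, seg_start, seg_vals, t_end, out_times, &out, c);
    conv[c] = integ.converged;
    if (c % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["states"] = out, _["converged"] = conv);
}
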