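// Compiled right-hand sides of the full (2n+2) and reduced (2n+1) systems
// and an adaptive Dormand-Prince 5(4) integrator with fixed-grid sampling.
// Phases are integrated unwrapped; the coupling functions reduce their
// arguments internally.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double PI_ = 3.14159265358979323846;

// reduce to [-pi, pi)
static inline double reduce_angle(double x) {
  double y = x - 2.0 * PI_ * std::floor((x + PI_) / (2.0 * PI_));
  if (y >= PI_) y = -PI_;
  return y;
}

// f on one period; log-form powering keeps nu up to several hundred stable
static inline double f_eval1(double x, double nu) {
  double y = reduce_angle(x);
  double s = (y > 0) - (y < 0);
  double ay = std::fabs(y);
  if (ay <= 0.0 || ay >= PI_) return 0.0;
  double u = std::exp(nu * std::log(PI_ - ay) - (nu - 1.0) * std::log(PI_));
  return s * std::sin(u);
}

static inline double h_eval1(double x, double mu, double sigma) {
  double ay = std::fabs(reduce_angle(x));
  if (ay >= mu) return 0.0;
  double r = ay / mu;
  return std::exp(sigma * std::log1p(-r * r));
}

struct WtaPars {
  int n;
  double b, alpha, beta, gamma, c, nu, mu, sigma;
  std::vector<double> omega;
};

static WtaPars unpack_pars(const List& pars) {
  WtaPars P;
  P.n = as<int>(pars["n"]);
  P.b = as<double>(pars["b"]);
  P.alpha = as<double>(pars["alpha"]);
  P.beta = as<double>(pars["beta"]);
  P.gamma = as<double>(pars["gamma"]);
  P.c = as<double>(pars["c"]);
  P.nu = as<double>(pars["nu"]);
  P.mu = as<double>(pars["mu"]);
  P.sigma = as<double>(pars["sigma"]);
  NumericVector om = pars["omega"];
  P.omega.assign(om.begin(), om.end());
  return P;
}

// full system, y = (theta0, theta_1..n, omega0, a_1..n), length 2n+2
static void rhs_full_c(const double* y, double* dy, const WtaPars& P) {
  const int n = P.n;
  const double theta0 = y[0], omega0 = y[n + 1];
  const double* theta = y + 1;
  const double* a = y + n + 2;
  double S = 0.0;
  for (int j = 0; j < n; ++j) S += a[j] * f_eval1(theta[j] - theta0, P.nu);
  S /= n;
  dy[0] = omega0 + S;
  dy[n + 1] = P.alpha * S;
  for (int i = 0; i < n; ++i) {
    dy[1 + i] = P.omega[i] + P.b * std::sin(theta0 - theta[i]);
    dy[n + 2 + i] = P.beta * (-a[i] + P.c +
                              P.gamma * h_eval1(theta[i] - theta0, P.mu, P.sigma));
  }
}

// reduced system, y = (phi_1..n, omega0, a_1..n), length 2n+1
static void rhs_reduced_c(const double* y, double* dy, const WtaPars& P) {
  const int n = P.n;
  const double omega0 = y[n];
  const double* phi = y;
  const double* a = y + n + 1;
  double S = 0.0;
  for (int j = 0; j < n; ++j) S += a[j] * f_eval1(phi[j], P.nu);
  S /= n;
  for (int i = 0; i < n; ++i) {
    dy[i] = P.omega[i] - omega0 - P.b * std::sin(phi[i]) - S;
    dy[n + 1 + i] = P.beta * (-a[i] + P.c +
                              P.gamma * h_eval1(phi[i], P.mu, P.sigma));
  }
  dy[n] = P.alpha * S;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(std::string system, NumericVector y, List pars) {
  WtaPars P = unpack_pars(pars);
  NumericVector dy(y.size());
  if (system == "full") {
    if ((int)y.size() != 2 * P.n + 2) stop("state length must be 2n+2");
    rhs_full_c(y.begin(), dy.begin(), P);
  } else {
    if ((int)y.size() != 2 * P.n + 1) stop("state length must be 2n+1");
    rhs_reduced_c(y.begin(), dy.begin(), P);
  }
  return dy;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// [[Rcpp::export(name = ".integrate_cpp")]]
NumericMatrix integrate_cpp(std::string system, NumericVector y0, List pars,
                            double t_end, double rtol, double atol,
                            double sample_dt) {
  WtaPars P = unpack_pars(pars);
  const bool full = (system == "full");
  const int dim = full ? 2 * P.n + 2 : 2 * P.n + 1;
  if ((int)y0.size() != dim) stop("state length does not match system/params");
  if (t_end < 0) stop("t_end must be >= 0");
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive");
  if (sample_dt <= 0) stop("sample_dt must be positive");

  auto rhs = [&](const double* y, double* dy) {
    if (full) rhs_full_c(y, dy, P); else rhs_reduced_c(y, dy, P);
  };

  const int nsamp = (int)std::floor(t_end / sample_dt + 1e-9) + 1;
  // last sample is t_end itself even if not on the dt grid
  const bool extra = std::fabs((nsamp - 1) * sample_dt - t_end) > 1e-9;
  NumericMatrix out(nsamp + (extra ? 1 : 0), dim + 1);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), ytmp(dim), ynew(dim), err(dim);

  int row = 0;
  out(row, 0) = 0.0;
  for (int j = 0; j < dim; ++j) out(row, j + 1) = y[j];
  ++row;
  if (t_end == 0) return out;

  double t = 0.0, h = std::min(1e-3, sample_dt);
  double t_next = sample_dt;
  rhs(y.data(), k1.data());
  bool have_k1 = true;
  long nstep = 0;
  const long max_steps = 100000000L;

  while (t < t_end) {
    if (++nstep > max_steps)
      stop("integration failed: step limit reached at t = %f", t);
    if (t + h > t_next) h = t_next - t;
    if (!have_k1) { rhs(y.data(), k1.data()); have_k1 = true; }

    for (int j = 0; j < dim; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
    rhs(ytmp.data(), k2.data());
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    rhs(ytmp.data(), k3.data());
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    rhs(ytmp.data(), k4.data());
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                            a54 * k4[j]);
    rhs(ytmp.data(), k5.data());
    for (int j = 0; j < dim; ++j)
      ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                            a64 * k4[j] + a65 * k5[j]);
    rhs(ytmp.data(), k6.data());
    for (int j = 0; j < dim; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
    rhs(ynew.data(), k7.data());

    double errnorm = 0.0;
    for (int j = 0; j < dim; ++j) {
      double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                      e6 * k6[j] + e7 * k7[j]);
      double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      double q = e / sc;
      errnorm += q * q;
    }
    errnorm = std::sqrt(errnorm / dim);

    if (!std::isfinite(errnorm))
      stop("integration failed: non-finite state at t = %f", t);

    if (errnorm <= 1.0) { // accept
      t += h;
      y.swap(ynew);
      k1.swap(k7); // FSAL
      have_k1 = true;
      if (std::fabs(t - t_next) < 1e-12 * std::max(1.0, t_next)) {
        out(row, 0) = t_next > t_end ? t_end : t_next;
        for (int j = 0; j < dim; ++j) out(row, j + 1) = y[j];
        ++row;
        t = t_next; // land exactly on the grid
        t_next = (row < nsamp) ? row * sample_dt : t_end;
        if (t_next > t_end) t_next = t_end;
        if (row >= out.nrow()) break;
      }
    } else {
      have_k1 = true; // k1 still valid at unchanged t, y
    }
    double fac = 0.9 * std::pow(std::max(errnorm, 1e-10), -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-12)
      stop("integration failed: step size underflow at t = %f", t);
  }
  return out;
}
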