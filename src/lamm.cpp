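#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Bernoulli function B(x) = x / (exp(x) - 1), numerically stable for
// |x| small (Taylor) and x large (expm1 underflow-safe). Used by the
// Scharfetter-Gummel exponential-fitting flux.
static inline double bernoulli(double x) {
  if (std::fabs(x) < 1e-10) return 1.0 - 0.5 * x;
  if (x > 700.0) return 0.0;                 // exp(x) overflows; B -> 0
  if (x < -700.0) return -x;                 // B(-|x|) -> |x|
  return x / std::expm1(x);
}

// One backward-Euler step of the radial finite-volume system.
// Nodes r[0..n-1] uniform on [m, b]; control volume "masses" are
// w[i] = r[i] * h (half cells at the ends). Face flux between i and i+1:
//   J = (D * r_f / h) * (B(-Pe) C_i - B(Pe) C_{i+1}),  Pe = s w^2 r_f h / D.
// Zero flux at both ends. The resulting matrix is an M-matrix, so the
// scheme is positivity preserving and conserves sum(w_i C_i) exactly.
static void be_step(const std::vector<double>& r,
                    const std::vector<double>& w,
                    const std::vector<double>& aL,   // precomputed face coefs
                    const std::vector<double>& aR,
                    double dt,
                    const std::vector<double>& cin,
                    std::vector<double>& cout,
                    std::vector<double>& dl,
                    std::vector<double>& dd,
                    std::vector<double>& du,
                    std::vector<double>& rhs) {
  const int n = (int)r.size();
  for (int i = 0; i < n; ++i) {
    dd[i] = w[i] / dt;
    rhs[i] = w[i] / dt * cin[i];
    dl[i] = 0.0;
    du[i] = 0.0;
  }
  for (int f = 0; f < n - 1; ++f) {
    // flux J_f = aL[f] * C_f - aR[f] * C_{f+1} leaves cell f, enters f+1
    dd[f]     += aL[f];
    du[f]     -= aR[f];
    dd[f + 1] += aR[f];
    dl[f + 1] -= aL[f];
  }
  // Thomas algorithm
  for (int i = 1; i < n; ++i) {
    double mfac = dl[i] / dd[i - 1];
    dd[i] -= mfac * du[i - 1];
    rhs[i] -= mfac * rhs[i - 1];
  }
  cout[n - 1] = rhs[n - 1] / dd[n - 1];
  for (int i = n - 2; i >= 0; --i)
    cout[i] = (rhs[i] - du[i] * cout[i + 1]) / dd[i];
}

// [[Rcpp::export(name = ".lamm_solve_cpp")]]
NumericMatrix lamm_solve_cpp(double s, double D, double meniscus,
                             double bottom, double omega,
                             NumericVector times, double loading,
                             int n_radii, double tol, int max_steps) {
  if (!(bottom > meniscus)) stop("bottom must exceed meniscus");
  if (!(D > 0)) stop("diffusion coefficient must be positive");
  const int n = n_radii;
  const double h = (bottom - meniscus) / (n - 1);
  std::vector<double> r(n), w(n);
  for (int i = 0; i < n; ++i) {
    r[i] = meniscus + i * h;
    w[i] = r[i] * h;
  }
  w[0] *= 0.5;
  w[n - 1] *= 0.5;

  // face coefficients, independent of dt
  std::vector<double> aL(n - 1), aR(n - 1);
  const double om2 = omega * omega;
  for (int f = 0; f < n - 1; ++f) {
    double rf = 0.5 * (r[f] + r[f + 1]);
    double v = s * om2 * rf;          // radial advection velocity at the face
    double pe = v * h / D;
    double g = D * rf / h;
    aL[f] = g * bernoulli(-pe);
    aR[f] = g * bernoulli(pe);
  }

  const int nt = times.size();
  NumericMatrix out(nt, n);
  std::vector<double> c(n, loading), c1(n), c2(n), chalf(n);
  std::vector<double> dl(n), dd(n), du(n), rhs(n);

  // initial adaptive step: resolve the fastest face timescale
  double peak = 1e-30;
  for (int f = 0; f < n - 1; ++f)
    peak = std::max(peak, (aL[f] + aR[f]) / std::min(w[f], w[f + 1]));
  double dt = 0.1 / peak;
  double t = 0.0;
  long steps = 0;

  for (int k = 0; k < nt; ++k) {
    double target = times[k];
    if (target < t) stop("output times must be non-decreasing");
    while (t < target * (1 - 1e-12) && target - t > 1e-12) {
      double dtk = std::min(dt, target - t);
      bool accepted = false;
      while (!accepted) {
        be_step(r, w, aL, aR, dtk, c, c1, dl, dd, du, rhs);
        be_step(r, w, aL, aR, 0.5 * dtk, c, chalf, dl, dd, du, rhs);
        be_step(r, w, aL, aR, 0.5 * dtk, chalf, c2, dl, dd, du, rhs);
        // weighted RMS difference between one full and two half steps
        double num = 0.0, den = 0.0;
        for (int i = 0; i < n; ++i) {
          double d = c1[i] - c2[i];
          num += w[i] * d * d;
          den += w[i];
        }
        double err = std::sqrt(num / den) / std::max(loading, 1e-300);
        ++steps;
        if (steps > max_steps)
          stop("Lamm solver step control failed to converge within %d steps "
               "(local error %g, dt %g); refine tolerance or grid", max_steps,
               err, dtk);
        if (err <= tol || dtk <= 1e-9 * std::max(1.0, target)) {
          c = c2;
          t += dtk;
          accepted = true;
          double fac = (err > 0) ? 0.9 * std::sqrt(tol / err) : 5.0;
          if (fac < 0.2) fac = 0.2;
          if (fac > 5.0) fac = 5.0;
          dt = dtk * fac;
        } else {
          double fac = 0.9 * std::sqrt(tol / err);
          if (fac < 0.1) fac = 0.1;
          dtk *= fac;
        }
      }
    }
    for (int i = 0; i < n; ++i) out(k, i) = c[i];
  }
  out.attr("radii_step") = h;
  out.attr("n_steps") = (double)steps;
  return out;
}
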