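#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of the mother wavelet, parameterized on u in [0, 1]
// over its support; zero outside. `psi` is sampled on a uniform grid.
static inline double psi_at(const double *psi, const int n, const double u) {
  if (u <= 0.0 || u >= 1.0) return 0.0;
  const double pos = u * (n - 1);
  const int i0 = (int)pos;
  const double fr = pos - i0;
  return psi[i0] + fr * (psi[i0 + 1] - psi[i0]);
}

// Add one component A * psi(u_peak + (k - c)/sigma) into `out` (1-based k).
static void add_component(double *out, const int window,
                          const double A, const double tau, const double sigma,
                          const double *psi, const int n, const double upeak) {
  if (A == 0.0 || sigma <= 0.0) return;
  const double c = window / 2.0 + tau;  // 1-based index of the extremum
  // k range where u in (0, 1)
  int k1 = (int)std::ceil(c - upeak * sigma);
  int k2 = (int)std::floor(c + (1.0 - upeak) * sigma);
  if (k1 < 1) k1 = 1;
  if (k2 > window) k2 = window;
  for (int k = k1; k <= k2; ++k) {
    const double u = upeak + (k - c) / sigma;
    out[k - 1] += A * psi_at(psi, n, u);
  }
}

// [[Rcpp::export]]
NumericVector cpp_render_component(double A, double tau, double sigma,
                                   int window, NumericVector psi, double upeak) {
  NumericVector out(window);
  add_component(REAL(out), window, A, tau, sigma, REAL(psi), psi.size(), upeak);
  return out;
}

// par = c(A_1..A_N, tau_1..tau_N, sigma_1..sigma_N)
// [[Rcpp::export]]
NumericVector cpp_synthesize(NumericVector par, int window,
                             NumericVector psi, double upeak) {
  const int N = par.size() / 3;
  NumericVector out(window);
  for (int i = 0; i < N; ++i)
    add_component(REAL(out), window, par[i], par[N + i], par[2 * N + i],
                  REAL(psi), psi.size(), upeak);
  return out;
}

// Composite objective J = w1 * (1 - r) + w2 * NMSE for each row of X
// (rows are parameter vectors in the layout above). Target statistics are
// passed precomputed: tmean, tsd_num = sqrt(sum((t - tmean)^2)), sst = sum(t^2).
// [[Rcpp::export]]
NumericVector cpp_swarm_objective(NumericMatrix X, NumericVector target,
                                  int window, NumericVector psi, double upeak,
                                  double w1, double w2) {
  const int pop = X.nrow(), D = X.ncol(), N = D / 3;
  const int n = psi.size();
  const double *t = REAL(target);
  double tmean = 0.0, sst = 0.0;
  for (int k = 0; k < window; ++k) { tmean += t[k]; sst += t[k] * t[k]; }
  tmean /= window;
  double tvar = 0.0;
  for (int k = 0; k < window; ++k) tvar += (t[k] - tmean) * (t[k] - tmean);
  const double tsd = std::sqrt(tvar);

  NumericVector J(pop);
  std::vector<double> buf(window);
  for (int p = 0; p < pop; ++p) {
    std::fill(buf.begin(), buf.end(), 0.0);
    for (int i = 0; i < N; ++i)
      add_component(buf.data(), window, X(p, i), X(p, N + i), X(p, 2 * N + i),
                    REAL(psi), n, upeak);
    double cmean = 0.0;
    for (int k = 0; k < window; ++k) cmean += buf[k];
    cmean /= window;
    double cv = 0.0, cc = 0.0, se = 0.0;
    for (int k = 0; k < window; ++k) {
      const double dc = buf[k] - cmean;
      cv += dc * dc;
      cc += dc * (t[k] - tmean);
      const double d = t[k] - buf[k];
      se += d * d;
    }
    double r = 0.0;
    if (cv > 0.0 && tvar > 0.0) r = cc / (std::sqrt(cv) * tsd);
    const double nmse = se / sst;
    double val = w1 * (1.0 - r) + w2 * nmse;
    if (!std::isfinite(val)) val = R_PosInf;
    J[p] = val;
  }
  return J;
}
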