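#include <Rcpp.h>
using namespace Rcpp;

// Conjugate Gibbs sampler for the Gaussian local-level (random-walk)
// model with replicate observations and missing years:
//   x_t = x_{t-1} + w_t,  w_t ~ N(0, Q)
//   y_{i,t} = x_t + v_{i,t},  v_{i,t} ~ N(0, R)
// States are drawn jointly by forward-filter backward-sampling over the
// full year grid (years with n_t = 0 contribute no observation update);
// Q and R are drawn from their conditional inverse-gamma posteriors.
// Uses R's RNG so results are reproducible under set.seed().
//
// Per-year sufficient statistics: n_t (count), s_t (sum), ss_t (sum of
// squares). Returns kept draws as a matrix with columns x_1..x_T, Q, R.

static inline double rinvgamma(double shape, double rate) {
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export(name = ".gibbs_local_level")]]
NumericMatrix gibbs_local_level(NumericVector n_t, NumericVector s_t,
                                NumericVector ss_t, double m0, double C0,
                                double aQ, double bQ, double aR, double bR,
                                double Q_init, double R_init,
                                int n_iter, int burn_in, int thin,
                                bool fix_Q, double Q_fixed,
                                bool fix_R, double R_fixed) {
  const int T = n_t.size();
  if (thin < 1) thin = 1;
  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix out(n_keep, T + 2);

  std::vector<double> m(T), C(T), x(T);
  double Q = fix_Q ? Q_fixed : Q_init;
  double R = fix_R ? R_fixed : R_init;
  double N_obs = 0.0;
  for (int t = 0; t < T; ++t) N_obs += n_t[t];

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // forward filter
    double a = m0, P = C0;
    for (int t = 0; t < T; ++t) {
      if (t > 0) { a = m[t - 1]; P = C[t - 1] + Q; }
      if (n_t[t] > 0.0) {
        double prec = 1.0 / P + n_t[t] / R;
        m[t] = (a / P + s_t[t] / R) / prec;
        C[t] = 1.0 / prec;
      } else {
        m[t] = a;
        C[t] = P;
      }
    }
    // backward sample
    x[T - 1] = R::rnorm(m[T - 1], std::sqrt(C[T - 1]));
    for (int t = T - 2; t >= 0; --t) {
      double prec = 1.0 / C[t] + 1.0 / Q;
      double mu = (m[t] / C[t] + x[t + 1] / Q) / prec;
      x[t] = R::rnorm(mu, std::sqrt(1.0 / prec));
    }
    // variance updates
    if (!fix_Q) {
      double ssq = 0.0;
      for (int t = 1; t < T; ++t) {
        double d = x[t] - x[t - 1];
        ssq += d * d;
      }
      Q = rinvgamma(aQ + 0.5 * (T - 1), bQ + 0.5 * ssq);
    }
    if (!fix_R) {
      double sse = 0.0;
      for (int t = 0; t < T; ++t)
        if (n_t[t] > 0.0)
          sse += ss_t[t] - 2.0 * x[t] * s_t[t] + n_t[t] * x[t] * x[t];
      if (sse < 0.0) sse = 0.0;  // guard against cancellation
      R = rinvgamma(aR + 0.5 * N_obs, bR + 0.5 * sse);
    }
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int t = 0; t < T; ++t) out(kept, t) = x[t];
      out(kept, T) = Q;
      out(kept, T + 1) = R;
      ++kept;
    }
  }
  return out;
}
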