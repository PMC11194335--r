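#include <Rcpp.h>
using namespace Rcpp;

// Gibbs sampler for multi-kernel Bayesian ridge regression on standardised
// marker data, parameterised in marker-effect space:
//
//   y_i = mu_{env(i)} + x_{acc(i)}' b0 [+ x_{acc(i)}' b_{env(i)}] + e_i
//
// b0 ~ N(0, I s2b[0]) is shared across environments; when env_specific is
// true each environment j additionally carries b_j ~ N(0, I s2b[j]).
// Variances carry scaled-inverse-chi-square priors (df0, S0b) / (dfe, S0e);
// intercepts are flat.  Sampling marker effects one at a time with an
// in-place residual update keeps the per-iteration cost at
// O(sum over kernels of n_kernel_obs * p).
//
// On the standardised-X scale the genetic variance of kernel m is
// s2u[m] = p * s2b[m] (since diag(XX'/p) ~ 1), which is what gets reported.
//
// All randomness comes from R's RNG so set.seed() gives bit-identical chains.

static inline double rinvchisq(double df, double scale) {
  // draw from scaled-inverse-chi-square(df, scale)
  return df * scale / R::rchisq(df);
}

// [[Rcpp::export(name = ".gibbs_ridge")]]
List gibbs_ridge(NumericVector y,
                 IntegerVector acc,   // 0-based row of X per observation
                 IntegerVector env,   // 0-based environment per observation
                 NumericMatrix X,     // n_acc x p standardised marker matrix
                 int n_env,
                 bool env_specific,
                 int n_iter, int burn_in, int thin,
                 double df0, NumericVector S0b,
                 double dfe, double S0e,
                 bool fix_var,
                 NumericVector init_s2b, double init_s2e) {
  const int n = y.size();
  const int p = X.ncol();
  const int n_acc = X.nrow();
  const int n_kern = env_specific ? (1 + n_env) : 1;
  const double* Xp = REAL(X);
  const int* envp = INTEGER(env);
  const int* accp = INTEGER(acc);

  // per-kernel observation lists: kernel 0 sees everything, kernel m > 0
  // the observations of environment m-1.  For each kernel keep the
  // observation index and the corresponding X row side by side so the
  // marker loop is a flat double-gather.
  std::vector< std::vector<int> > obs_of(n_kern), row_of(n_kern);
  for (int i = 0; i < n; ++i) {
    obs_of[0].push_back(i);
    row_of[0].push_back(accp[i]);
    if (env_specific) {
      obs_of[1 + envp[i]].push_back(i);
      row_of[1 + envp[i]].push_back(accp[i]);
    }
  }

  std::vector<int> env_n(n_env, 0);
  for (int i = 0; i < n; ++i) env_n[envp[i]]++;

  // per-kernel, per-marker column sum of squares (constant)
  std::vector<double> xtx((size_t)p * n_kern);
  for (int m = 0; m < n_kern; ++m) {
    const std::vector<int>& rw = row_of[m];
    const size_t nm = rw.size();
    for (int k = 0; k < p; ++k) {
      const double* xk = Xp + (size_t)k * n_acc;
      double s = 0.0;
      for (size_t q = 0; q < nm; ++q) { double v = xk[rw[q]]; s += v * v; }
      xtx[(size_t)m * p + k] = s;
    }
  }

  // state
  std::vector<double> b((size_t)p * n_kern, 0.0);
  std::vector<double> mu(n_env, 0.0), e(n);
  for (int i = 0; i < n; ++i) {
    mu[envp[i]] += y[i];
  }
  for (int j = 0; j < n_env; ++j) mu[j] /= env_n[j];
  for (int i = 0; i < n; ++i) e[i] = y[i] - mu[envp[i]];

  std::vector<double> s2b(init_s2b.begin(), init_s2b.end());
  double s2e = init_s2e;

  // accumulators
  std::vector<double> b_sum((size_t)p * n_kern, 0.0);
  std::vector<double> mu_sum(n_env, 0.0);
  int n_keep = 0;
  for (int it = burn_in; it < n_iter; ++it)
    if ((it - burn_in) % thin == 0) ++n_keep;

  // retained draws: mu_1..mu_J, s2u0[, s2u1..s2uJ], s2e, r2_1..r2_J
  const int n_cols = n_env + n_kern + 1 + n_env;
  NumericMatrix samples(n_keep, n_cols);
  int keep_i = 0;

  for (int it = 0; it < n_iter; ++it) {
    // --- intercepts (flat prior) ---
    for (int j = 0; j < n_env; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) if (envp[i] == j) s += e[i];
      double d = s / env_n[j] + sqrt(s2e / env_n[j]) * norm_rand();
      for (int i = 0; i < n; ++i) if (envp[i] == j) e[i] -= d;
      mu[j] += d;
    }

    // --- marker effects, kernel by kernel ---
    for (int m = 0; m < n_kern; ++m) {
      const int* ob = obs_of[m].data();
      const int* rw = row_of[m].data();
      const size_t nm = obs_of[m].size();
      const double lambda = s2e / s2b[m];
      double* bm = b.data() + (size_t)m * p;
      const double* xtxm = xtx.data() + (size_t)m * p;
      for (int k = 0; k < p; ++k) {
        const double* xk = Xp + (size_t)k * n_acc;
        const double b_old = bm[k];
        double rhs = xtxm[k] * b_old;
        for (size_t q = 0; q < nm; ++q) rhs += xk[rw[q]] * e[ob[q]];
        const double c = xtxm[k] + lambda;
        const double b_new = rhs / c + sqrt(s2e / c) * norm_rand();
        const double d = b_new - b_old;
        if (d != 0.0)
          for (size_t q = 0; q < nm; ++q) e[ob[q]] -= xk[rw[q]] * d;
        bm[k] = b_new;
      }
    }

    // --- variance components ---
    if (!fix_var) {
      for (int m = 0; m < n_kern; ++m) {
        const double* bm = b.data() + (size_t)m * p;
        double ssb = 0.0;
        for (int k = 0; k < p; ++k) ssb += bm[k] * bm[k];
        s2b[m] = rinvchisq(df0 + p, (ssb + df0 * S0b[m]) / (df0 + p));
      }
      double sse = 0.0;
      for (int i = 0; i < n; ++i) sse += e[i] * e[i];
      s2e = rinvchisq(dfe + n, (sse + dfe * S0e) / (dfe + n));
    }

    // --- bookkeeping ---
    if (it >= burn_in && (it - burn_in) % thin == 0) {
      for (size_t q = 0; q < b.size(); ++q) b_sum[q] += b[q];
      for (int j = 0; j < n_env; ++j) mu_sum[j] += mu[j];
      int c = 0;
      for (int j = 0; j < n_env; ++j) samples(keep_i, c++) = mu[j];
      for (int m = 0; m < n_kern; ++m) samples(keep_i, c++) = p * s2b[m];
      samples(keep_i, c++) = s2e;
      for (int j = 0; j < n_env; ++j) {
        double g = p * s2b[0] + (env_specific ? p * s2b[1 + j] : 0.0);
        samples(keep_i, c++) = g / (g + s2e);
      }
      ++keep_i;
    }
    if (it % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix b_mean(p, n_kern);
  for (int m = 0; m < n_kern; ++m)
    for (int k = 0; k < p; ++k)
      b_mean(k, m) = b_sum[(size_t)m * p + k] / n_keep;
  NumericVector mu_mean(n_env);
  for (int j = 0; j < n_env; ++j) mu_mean[j] = mu_sum[j] / n_keep;

  return List::create(_["b_mean"] = b_mean,
                      _["mu_mean"] = mu_mean,
                      _["samples"] = samples,
                      _["n_keep"] = n_keep);
}
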