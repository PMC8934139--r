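#include <Rcpp.h>
using namespace Rcpp;

// Model codes (keep in sync with R/models.R):
// 1 linear  a + s*b*x
// 2 power   a + s*b*x^g
// 3 hill    a + s*b*x^g/(c^g + x^g)
// 4 exp2    a*exp(s*b*x)
// 5 exp3    a*exp(s*(b*x)^g)
// 6 exp4    a*(c - (c-1)*exp(-b*x))
// 7 exp5    a*(c - (c-1)*exp(-(b*x)^g))
// theta layouts (constrained scale, direction s passed separately):
//   1: a,b   2: a,b,g   3: a,b,g,c   4: a,b   5: a,b,g   6: a,b,c   7: a,b,c,g
// exp4/exp5 encode direction through c (c>1 increasing, 0<c<1 decreasing).

static double dr_mean_one(const int model, const double *th, const double x,
                          const int dir) {
  switch (model) {
  case 1: return th[0] + dir * th[1] * x;
  case 2: return th[0] + dir * th[1] * std::pow(x, th[2]);
  case 3: {
    const double xg = std::pow(x, th[2]);
    const double cg = std::pow(th[3], th[2]);
    return th[0] + dir * th[1] * xg / (cg + xg);
  }
  case 4: return th[0] * std::exp(dir * th[1] * x);
  case 5: return th[0] * std::exp(dir * std::pow(th[1] * x, th[2]));
  case 6: return th[0] * (th[2] - (th[2] - 1.0) * std::exp(-th[1] * x));
  case 7:
    return th[0] *
           (th[2] - (th[2] - 1.0) * std::exp(-std::pow(th[1] * x, th[3])));
  }
  return NA_REAL;
}

// [[Rcpp::export]]
NumericVector cpp_dr_mean(const int model, const NumericVector theta,
                          const NumericVector x, const int dir) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dr_mean_one(model, theta.begin(), x[i], dir);
  return out;
}

static int n_theta(const int model) {
  switch (model) {
  case 1: case 4: return 2;
  case 2: case 5: case 6: return 3;
  case 3: case 7: return 4;
  }
  return 0;
}

// hyper layout: a_mean, a_sd, b_scale, g_lo, g_hi, c_lo, c_hi,
//               sigma_scale, a_positive (0/1), c_scale
// c prior: uniform on (c_lo, c_hi] when c_scale <= 0, otherwise
// half-normal on |c - 1| with scale c_scale (truncated to the bounds) --
// an effect-scaled prior for the exp4/exp5 plateau ratio.
static double log_prior(const int model, const double *th, const double sigma,
                        const NumericVector &hyper) {
  const double a_mean = hyper[0], a_sd = hyper[1], b_scale = hyper[2];
  const double g_lo = hyper[3], g_hi = hyper[4];
  const double c_lo = hyper[5], c_hi = hyper[6];
  const double sigma_scale = hyper[7];
  const bool a_pos = hyper[8] > 0.5;
  const double c_scale = hyper.size() > 9 ? hyper[9] : 0.0;
  const int k = n_theta(model);

  const double a = th[0], b = th[1];
  if (sigma <= 0.0 || b <= 0.0) return R_NegInf;
  if (a_pos && a <= 0.0) return R_NegInf;

  double lp = R::dnorm(a, a_mean, a_sd, 1);
  if (a_pos) lp -= R::pnorm(a_mean / a_sd, 0.0, 1.0, 1, 1); // truncation to a>0
  lp += R::dnorm(b, 0.0, b_scale, 1) + M_LN2;               // half-normal
  lp += R::dnorm(sigma, 0.0, sigma_scale, 1) + M_LN2;

  // shape g: uniform [g_lo, g_hi]; position in theta differs by model
  double g = NA_REAL, c = NA_REAL;
  if (model == 2 || model == 5) g = th[2];
  if (model == 3) { g = th[2]; c = th[3]; }
  if (model == 6) c = th[2];
  if (model == 7) { c = th[2]; g = th[3]; }
  if (k >= 3 && !ISNA(g)) {
    if (g < g_lo || g > g_hi) return R_NegInf;
    lp -= std::log(g_hi - g_lo);
  }
  if (!ISNA(c)) {
    if (c <= c_lo || c > c_hi) return R_NegInf;
    if (c_scale > 0.0 && (model == 6 || model == 7))
      lp += R::dnorm(std::fabs(c - 1.0), 0.0, c_scale, 1) + M_LN2;
    else
      lp -= std::log(c_hi - c_lo);
  }
  return lp;
}

static double log_lik(const int model, const double *th, const double sigma,
                      const NumericVector &x, const NumericVector &y,
                      const int dir) {
  const int n = x.size();
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    const double m = dr_mean_one(model, th, x[i], dir);
    if (!R_finite(m)) return R_NegInf;
    ll += R::dnorm(y[i], m, sigma, 1);
  }
  return ll;
}

// [[Rcpp::export]]
double cpp_dr_loglik(const int model, const NumericVector theta,
                     const double sigma, const NumericVector x,
                     const NumericVector y, const int dir) {
  return log_lik(model, theta.begin(), sigma, x, y, dir);
}

// Cholesky factor (lower) of a small SPD matrix with a ridge; returns
// false if the factorization fails even after boosting the ridge.
static bool chol_lower(std::vector<double> &A, const int d) {
  for (int j = 0; j < d; ++j) {
    double s = A[j * d + j];
    for (int p = 0; p < j; ++p) s -= A[j * d + p] * A[j * d + p];
    if (s <= 0.0) return false;
    A[j * d + j] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double t = A[i * d + j];
      for (int p = 0; p < j; ++p) t -= A[i * d + p] * A[j * d + p];
      A[i * d + j] = t / A[j * d + j];
    }
  }
  return true;
}

// Adaptive random-walk Metropolis. State = (theta, sigma). Phase 1
// (first half of warmup): component-wise proposals with per-parameter
// step adaptation toward 44% acceptance. Phase 2 (second half of warmup
// onward): joint multivariate-normal proposals whose covariance is the
// running empirical covariance of the chain (Haario-style), with a
// global scale adapted toward 23% acceptance during warmup and frozen
// afterwards. The joint phase is what lets strongly correlated
// parameter ridges (e.g. b and g in the power/exponential models) mix.
// Uses R's RNG so set.seed() on the R side fixes the chain.
// [[Rcpp::export]]
List cpp_sample_posterior(const int model, const NumericVector x,
                          const NumericVector y, const int dir,
                          const NumericVector hyper, const int iterations,
                          const int warmup, const NumericVector init,
                          const NumericVector init_step) {
  const int k = n_theta(model);
  const int npar = k + 1; // + sigma
  std::vector<double> state(init.begin(), init.end());
  std::vector<double> lstep(npar);
  for (int j = 0; j < npar; ++j) lstep[j] = std::log(init_step[j]);

  double lp_cur = log_prior(model, state.data(), state[k], hyper) +
                  log_lik(model, state.data(), state[k], x, y, dir);
  if (!R_finite(lp_cur)) stop("invalid initial values for MCMC");

  const int n_keep = iterations - warmup;
  const int phase1_end = warmup / 2;
  NumericMatrix draws(n_keep, npar);
  NumericVector lp_out(n_keep);
  std::vector<int> acc(npar, 0), tot(npar, 0), acc_batch(npar, 0);
  const int batch_size = 50;

  // running moments for the joint-proposal covariance
  std::vector<double> mean(npar, 0.0), m2(npar * npar, 0.0);
  long n_mom = 0;
  std::vector<double> chol(npar * npar, 0.0), prop(npar), z(npar);
  bool have_chol = false;
  double lscale = std::log(2.38 / std::sqrt((double)npar));
  int acc_joint_batch = 0, tot_joint_batch = 0;

  GetRNGstate();
  for (int it = 0; it < iterations; ++it) {
    const bool joint = have_chol && it >= phase1_end;
    if (joint) {
      const double s = std::exp(lscale);
      for (int j = 0; j < npar; ++j) z[j] = norm_rand();
      for (int i = 0; i < npar; ++i) {
        double t = 0.0;
        for (int j = 0; j <= i; ++j) t += chol[i * npar + j] * z[j];
        prop[i] = state[i] + s * t;
      }
      double lp_new = log_prior(model, prop.data(), prop[k], hyper);
      if (R_finite(lp_new))
        lp_new += log_lik(model, prop.data(), prop[k], x, y, dir);
      if (R_finite(lp_new) && lp_new - lp_cur > std::log(unif_rand())) {
        state = prop;
        lp_cur = lp_new;
        ++acc[0]; ++acc_joint_batch;
      }
      ++tot[0]; ++tot_joint_batch;
      if (it < warmup && tot_joint_batch >= batch_size) {
        lscale += 0.6 * ((double)acc_joint_batch / tot_joint_batch - 0.234);
        if (lscale < -10.0) lscale = -10.0;
        if (lscale > 4.0) lscale = 4.0;
        acc_joint_batch = 0; tot_joint_batch = 0;
      }
    } else {
      for (int j = 0; j < npar; ++j) {
        const double old = state[j];
        state[j] = old + std::exp(lstep[j]) * norm_rand();
        const double lp_new =
            log_prior(model, state.data(), state[k], hyper) +
            log_lik(model, state.data(), state[k], x, y, dir);
        if (R_finite(lp_new) && lp_new - lp_cur > std::log(unif_rand())) {
          lp_cur = lp_new;
          ++acc[j]; ++acc_batch[j];
        } else {
          state[j] = old;
        }
        ++tot[j];
      }
      if (it < warmup && ((it + 1) % batch_size == 0)) {
        for (int j = 0; j < npar; ++j) {
          const double rate = (double)acc_batch[j] / batch_size;
          lstep[j] += 0.6 * (rate - 0.44);
          if (lstep[j] < -12.0) lstep[j] = -12.0;
          if (lstep[j] > 6.0) lstep[j] = 6.0;
          acc_batch[j] = 0;
        }
      }
    }

    // accumulate chain moments (after a short settling period)
    if (it >= phase1_end / 2) {
      ++n_mom;
      for (int i = 0; i < npar; ++i) {
        const double d = state[i] - mean[i];
        mean[i] += d / n_mom;
        for (int j = 0; j <= i; ++j)
          m2[i * npar + j] += d * (state[j] - mean[j]);
      }
    }
    // (re)build the proposal Cholesky during warmup
    if (it < warmup && it >= phase1_end - 1 && n_mom >= 10 * npar &&
        ((it + 1) % 100 == 0 || !have_chol)) {
      std::vector<double> cov(npar * npar, 0.0);
      for (int i = 0; i < npar; ++i)
        for (int j = 0; j <= i; ++j) {
          double cij = m2[i * npar + j] / (n_mom - 1);
          if (i == j) cij += 1e-10 + 1e-6 * cij;
          cov[i * npar + j] = cov[j * npar + i] = cij;
        }
      std::vector<double> L = cov;
      if (chol_lower(L, npar)) {
        chol = L;
        have_chol = true;
      }
    }

    if (it >= warmup) {
      const int r = it - warmup;
      for (int j = 0; j < npar; ++j) draws(r, j) = state[j];
      lp_out[r] = lp_cur;
    }
  }
  PutRNGstate();

  NumericVector acc_rate(npar);
  for (int j = 0; j < npar; ++j)
    acc_rate[j] = tot[j] > 0 ? (double)acc[j] / tot[j] : NA_REAL;
  return List::create(_["draws"] = draws, _["lp"] = lp_out,
                      _["accept_rate"] = acc_rate);
}

// Weighted pool-adjacent-violators for a monotone increasing fit.
static void pava_inc(const double *xbar, const double *w, const int K,
                     double *out) {
  std::vector<double> v(xbar, xbar + K), ww(w, w + K);
  std::vector<int> len(K, 1);
  int m = 0; // blocks 0..m
  for (int i = 1; i < K; ++i) {
    ++m;
    v[m] = xbar[i]; ww[m] = w[i]; len[m] = 1;
    while (m > 0 && v[m - 1] > v[m]) {
      v[m - 1] = (ww[m - 1] * v[m - 1] + ww[m] * v[m]) / (ww[m - 1] + ww[m]);
      ww[m - 1] += ww[m];
      len[m - 1] += len[m];
      --m;
    }
  }
  int pos = 0;
  for (int b = 0; b <= m; ++b)
    for (int l = 0; l < len[b]; ++l) out[pos++] = v[b];
}

// [[Rcpp::export]]
NumericVector cpp_isotonic_means(const NumericVector xbar,
                                 const NumericVector n,
                                 const bool increasing) {
  const int K = xbar.size();
  NumericVector out(K);
  if (increasing) {
    pava_inc(xbar.begin(), n.begin(), K, out.begin());
  } else {
    std::vector<double> neg(K), fit(K);
    for (int i = 0; i < K; ++i) neg[i] = -xbar[i];
    pava_inc(neg.data(), n.begin(), K, fit.data());
    for (int i = 0; i < K; ++i) out[i] = -fit[i];
  }
  return out;
}

// Williams-type trend statistic. grp: 0..K-1 in ascending dose order,
// group 0 = control. direction: 0 auto (absmax over both), +1, -1.
// Returns c(T, direction); T = NA if pooled within-group SD is zero.
static void group_stats(const NumericVector &y, const IntegerVector &grp,
                        const int K, double *xbar, double *n, double *s) {
  const int N = y.size();
  for (int j = 0; j < K; ++j) { xbar[j] = 0.0; n[j] = 0.0; }
  for (int i = 0; i < N; ++i) { xbar[grp[i]] += y[i]; n[grp[i]] += 1.0; }
  for (int j = 0; j < K; ++j) xbar[j] /= n[j];
  double sse = 0.0;
  for (int i = 0; i < N; ++i) {
    const double d = y[i] - xbar[grp[i]];
    sse += d * d;
  }
  *s = std::sqrt(sse / (N - K));
}

static double williams_T_dir(const double *xbar, const double *n, const int K,
                             const double s, const bool increasing) {
  std::vector<double> mu(K);
  if (increasing) {
    pava_inc(xbar, n, K, mu.data());
  } else {
    std::vector<double> neg(K), fit(K);
    for (int i = 0; i < K; ++i) neg[i] = -xbar[i];
    pava_inc(neg.data(), n, K, fit.data());
    for (int i = 0; i < K; ++i) mu[i] = -fit[i];
  }
  double T = 0.0;
  for (int i = 1; i < K; ++i) {
    const double se = s * std::sqrt(1.0 / n[i] + 1.0 / n[0]);
    const double t = std::fabs(mu[i] - xbar[0]) / se;
    if (t > T) T = t;
  }
  return T;
}

// [[Rcpp::export]]
NumericVector cpp_williams(const NumericVector y, const IntegerVector grp,
                           const int K, const int direction) {
  std::vector<double> xbar(K), n(K);
  double s;
  group_stats(y, grp, K, xbar.data(), n.data(), &s);
  if (s <= 0.0)
    return NumericVector::create(NA_REAL, 0.0);
  if (direction == 1 || direction == -1) {
    const double T = williams_T_dir(xbar.data(), n.data(), K, s,
                                    direction == 1);
    return NumericVector::create(T, (double)direction);
  }
  const double Ti = williams_T_dir(xbar.data(), n.data(), K, s, true);
  const double Td = williams_T_dir(xbar.data(), n.data(), K, s, false);
  return (Ti >= Td) ? NumericVector::create(Ti, 1.0)
                    : NumericVector::create(Td, -1.0);
}

// Null distribution of the trend statistic by permuting dose labels
// (permutation) or resampling from the pooled sample (bootstrap).
// Direction is re-chosen per replicate (absmax). Uses R's RNG.
// [[Rcpp::export]]
NumericVector cpp_trend_null(const NumericVector y, const IntegerVector grp,
                             const int K, const int B, const bool bootstrap) {
  const int N = y.size();
  NumericVector Tb(B);
  std::vector<double> yb(N), xbar(K), n(K);
  GetRNGstate();
  for (int b = 0; b < B; ++b) {
    if (bootstrap) {
      for (int i = 0; i < N; ++i)
        yb[i] = y[(int)(unif_rand() * N) % N];
    } else {
      std::copy(y.begin(), y.end(), yb.begin());
      for (int i = N - 1; i > 0; --i) {
        const int j = (int)(unif_rand() * (i + 1)) % (i + 1);
        std::swap(yb[i], yb[j]);
      }
    }
    double s;
    NumericVector ybv(yb.begin(), yb.end());
    group_stats(ybv, grp, K, xbar.data(), n.data(), &s);
    if (s <= 0.0) { Tb[b] = 0.0; continue; }
    const double Ti = williams_T_dir(xbar.data(), n.data(), K, s, true);
    const double Td = williams_T_dir(xbar.data(), n.data(), K, s, false);
    Tb[b] = (Ti >= Td) ? Ti : Td;
  }
  PutRNGstate();
  return Tb;
}

// Unnormalized log posterior for a batch of parameter vectors (rows of
// theta, last column sigma); -Inf outside the prior support. Used by the
// bridge-sampling marginal-likelihood estimator.
// [[Rcpp::export]]
NumericVector cpp_log_post_mat(const int model, const NumericMatrix theta,
                               const NumericVector x, const NumericVector y,
                               const int dir, const NumericVector hyper) {
  const int n = theta.nrow();
  const int k = n_theta(model);
  NumericVector out(n);
  std::vector<double> th(k + 1);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j <= k; ++j) th[j] = theta(i, j);
    double lp = log_prior(model, th.data(), th[k], hyper);
    if (R_finite(lp)) lp += log_lik(model, th.data(), th[k], x, y, dir);
    out[i] = lp;
  }
  return out;
}
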