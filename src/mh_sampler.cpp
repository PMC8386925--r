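// Component-wise random-walk Metropolis-Hastings for the concentration-
// dependent mixing model, on additive-logratio coordinates of the diet
// fraction simplex.
//
// Given diet fractions f (K sources), each signal s has concentration-
// dependent weights w_sk = f_k q_sk / sum_j f_j q_sj, a predicted mean
// mu_s = sum_k w_sk vbar_sk + omean_s, and -- with the Gaussian source
// values and offsets marginalised analytically -- a predictive variance
// var_s = s2_s + sum_k w_sk^2 tau2_sk + ovar_s. The prior on f is flat
// Dirichlet(1,...,1); sampling runs on z in R^{K-1} with f = softmax(z, 0)
// and the log-Jacobian sum(log f).

#include <Rcpp.h>
using namespace Rcpp;

static double log_posterior(const NumericVector& z,
                            const NumericVector& m,
                            const NumericVector& s2,
                            const NumericMatrix& vbar,
                            const NumericMatrix& tau2,
                            const NumericMatrix& q,
                            const NumericVector& omean,
                            const NumericVector& ovar,
                            std::vector<double>& f,
                            double* loglik_out) {
  const int K = vbar.ncol(), S = vbar.nrow();
  // softmax with an appended reference coordinate 0
  double zmax = 0.0;
  for (int k = 0; k < K - 1; ++k) if (z[k] > zmax) zmax = z[k];
  double denom = std::exp(-zmax);
  for (int k = 0; k < K - 1; ++k) denom += std::exp(z[k] - zmax);
  for (int k = 0; k < K - 1; ++k) f[k] = std::exp(z[k] - zmax) / denom;
  f[K - 1] = std::exp(-zmax) / denom;

  double ll = 0.0;
  for (int s = 0; s < S; ++s) {
    double wsum = 0.0;
    for (int k = 0; k < K; ++k) wsum += f[k] * q(s, k);
    if (wsum <= 0.0) { *loglik_out = R_NegInf; return R_NegInf; }
    double mu = omean[s], var = s2[s] + ovar[s];
    for (int k = 0; k < K; ++k) {
      double w = f[k] * q(s, k) / wsum;
      mu += w * vbar(s, k);
      var += w * w * tau2(s, k);
    }
    ll += R::dnorm(m[s], mu, std::sqrt(var), 1);
  }
  *loglik_out = ll;
  double logjac = 0.0;
  for (int k = 0; k < K; ++k) logjac += std::log(f[k]);
  return ll + logjac;
}

// [[Rcpp::export(name = ".mh_sample_cpp")]]
List mh_sample_cpp(NumericVector m, NumericVector s2,
                   NumericMatrix vbar, NumericMatrix tau2, NumericMatrix q,
                   NumericVector omean, NumericVector ovar,
                   int n_burn, int n_iter,
                   NumericVector init_z, double init_step,
                   int adapt_every, double target_acc) {
  const int K = vbar.ncol();
  const int D = K - 1;
  NumericVector z = clone(init_z);
  std::vector<double> f(K), f_prop(K);
  std::vector<double> step(D, init_step);
  std::vector<int> win_acc(D, 0), win_try(D, 0);

  double loglik = 0.0, loglik_prop = 0.0;
  double lp = log_posterior(z, m, s2, vbar, tau2, q, omean, ovar, f, &loglik);

  NumericMatrix chains(n_iter, K);
  NumericVector ll_out(n_iter);
  long acc_post = 0, try_post = 0;

  RNGScope scope;
  for (int it = 0; it < n_burn + n_iter; ++it) {
    for (int j = 0; j < D; ++j) {
      double zj_old = z[j];
      z[j] = zj_old + step[j] * norm_rand();
      double lp_prop = log_posterior(z, m, s2, vbar, tau2, q, omean, ovar,
                                     f_prop, &loglik_prop);
      bool accept = std::log(unif_rand()) < lp_prop - lp;
      if (accept) {
        lp = lp_prop; loglik = loglik_prop; f = f_prop;
        if (it < n_burn) ++win_acc[j]; else ++acc_post;
      } else {
        z[j] = zj_old;
      }
      if (it < n_burn) ++win_try[j]; else ++try_post;
    }
    if (it < n_burn && (it + 1) % adapt_every == 0) {
      for (int j = 0; j < D; ++j) {
        double rate = win_try[j] > 0 ? (double)win_acc[j] / win_try[j] : 0.0;
        step[j] *= std::exp(rate - target_acc);
        if (step[j] < 1e-4) step[j] = 1e-4;
        if (step[j] > 25.0) step[j] = 25.0;
        win_acc[j] = 0; win_try[j] = 0;
      }
    }
    if (it >= n_burn) {
      int r = it - n_burn;
      for (int k = 0; k < K; ++k) chains(r, k) = f[k];
      ll_out[r] = loglik;
    }
  }

  return List::create(
    _["chains"] = chains,
    _["loglik"] = ll_out,
    _["acceptance_rate"] = try_post > 0 ? (double)acc_post / try_post : NA_REAL,
    _["steps"] = NumericVector(step.begin(), step.end()));
}
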