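// Gibbs sampler kernel for the three-level random-slope linear mixed model:
//   y = X beta + v[practice] + u0[farm] + u1[farm] * age + e
// with conjugate full-conditional updates throughout. All randomness comes
// from R's RNG so runs are reproducible via set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Wishart(df, S) via Bartlett decomposition
static arma::mat rwish_bartlett(double df, const arma::mat& S) {
  const arma::uword p = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// exposed for testing the sampling convention (df, scale S => E[W] = df * S)
// [[Rcpp::export(name = ".rwishart")]]
arma::mat rwishart(double df, const arma::mat& S) {
  return rwish_bartlett(df, S);
}

// [[Rcpp::export(name = ".gibbs_kernel")]]
List gibbs_kernel(const arma::vec& y, const arma::mat& X,
                  const arma::vec& age,
                  const arma::uvec& farm,        // 0-based, per record
                  const arma::uvec& farm_prac,   // 0-based, per farm
                  int n_prac,
                  double a_v, double b_v, double a_e, double b_e,
                  double w_df, const arma::mat& w_R0,  // prior scale-inverse
                  arma::vec beta, arma::vec v, arma::mat U,
                  double var_v, arma::mat Omega, double var_e,
                  int burn_in, int n_iter, int thin,
                  bool use_prac, bool use_farm, bool store_ranef) {
  const arma::uword n = y.n_elem;
  const arma::uword p = X.n_cols;
  const arma::uword J = U.n_rows;
  const arma::uword K = (arma::uword)n_prac;
  const int n_store = n_iter / thin;

  // practice index per record
  arma::uvec prac(n);
  for (arma::uword i = 0; i < n; ++i) prac[i] = farm_prac[farm[i]];

  // fixed-design precomputations
  arma::mat XtX = X.t() * X;
  arma::mat XtX_inv = arma::inv_sympd(XtX);
  arma::mat XtX_inv_chol = arma::chol(XtX_inv, "lower");

  // per-cluster record counts and farm Z'Z blocks
  arma::vec n_k(K, arma::fill::zeros);
  arma::vec zz11(J, arma::fill::zeros), zz12(J, arma::fill::zeros),
            zz22(J, arma::fill::zeros);
  for (arma::uword i = 0; i < n; ++i) {
    n_k[prac[i]] += 1.0;
    zz11[farm[i]] += 1.0;
    zz12[farm[i]] += age[i];
    zz22[farm[i]] += age[i] * age[i];
  }

  arma::mat out(n_store, p + 6, arma::fill::zeros);
  arma::vec v_mean(K, arma::fill::zeros);
  arma::mat U_mean(J, 2, arma::fill::zeros);
  arma::mat v_draws, U_draws;
  if (store_ranef) {
    v_draws.set_size(n_store, K);
    U_draws.set_size(n_store, 2 * J);
  }

  arma::vec re(n), r(n), r2(n);
  arma::vec sum_k(K);
  arma::vec s1(J), s2(J);
  const double LOG2PI = std::log(2.0 * M_PI);

  int stored = 0;
  for (int it = 0; it < burn_in + n_iter; ++it) {
    // (1) fixed effects | rest
    for (arma::uword i = 0; i < n; ++i)
      re[i] = (use_prac ? v[prac[i]] : 0.0) +
              (use_farm ? U(farm[i], 0) + U(farm[i], 1) * age[i] : 0.0);
    arma::vec bmean = XtX_inv * (X.t() * (y - re));
    arma::vec z(p);
    for (arma::uword d = 0; d < p; ++d) z[d] = norm_rand();
    beta = bmean + std::sqrt(var_e) * (XtX_inv_chol * z);

    arma::vec fit = X * beta;
    r = y - fit;

    // (2) practice intercepts | rest
    if (use_prac) {
      sum_k.zeros();
      for (arma::uword i = 0; i < n; ++i) {
        double ru = r[i] - (use_farm ?
          U(farm[i], 0) + U(farm[i], 1) * age[i] : 0.0);
        sum_k[prac[i]] += ru;
      }
      for (arma::uword k = 0; k < K; ++k) {
        double prec = n_k[k] / var_e + 1.0 / var_v;
        double mean = (sum_k[k] / var_e) / prec;
        v[k] = mean + norm_rand() / std::sqrt(prec);
      }
    }

    // (3) farm (intercept, slope) pairs | rest
    if (use_farm) {
      arma::mat Omega_inv = arma::inv_sympd(Omega);
      s1.zeros(); s2.zeros();
      for (arma::uword i = 0; i < n; ++i) {
        double rv = r[i] - (use_prac ? v[prac[i]] : 0.0);
        s1[farm[i]] += rv;
        s2[farm[i]] += rv * age[i];
      }
      for (arma::uword j = 0; j < J; ++j) {
        arma::mat P(2, 2);
        P(0, 0) = zz11[j] / var_e + Omega_inv(0, 0);
        P(0, 1) = zz12[j] / var_e + Omega_inv(0, 1);
        P(1, 0) = P(0, 1);
        P(1, 1) = zz22[j] / var_e + Omega_inv(1, 1);
        arma::mat Pinv = arma::inv_sympd(P);
        arma::vec m = Pinv * arma::vec({s1[j] / var_e, s2[j] / var_e});
        arma::mat Lc = arma::chol(Pinv, "lower");
        arma::vec z2 = {norm_rand(), norm_rand()};
        arma::vec u = m + Lc * z2;
        U(j, 0) = u[0];
        U(j, 1) = u[1];
      }
    }

    // (4) practice precision | v
    if (use_prac) {
      double shape = a_v + 0.5 * (double)K;
      double rate = b_v + 0.5 * arma::dot(v, v);
      var_v = 1.0 / R::rgamma(shape, 1.0 / rate);
    }

    // (5) residual precision | all effects
    double sse = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      double e = r[i] - (use_prac ? v[prac[i]] : 0.0) -
        (use_farm ? U(farm[i], 0) + U(farm[i], 1) * age[i] : 0.0);
      sse += e * e;
    }
    var_e = 1.0 / R::rgamma(a_e + 0.5 * (double)n, 1.0 / (b_e + 0.5 * sse));

    // (6) farm precision matrix | U (Wishart with df = prior df + J)
    if (use_farm) {
      arma::mat Sm = w_R0 + U.t() * U;
      arma::mat prec = rwish_bartlett(w_df + (double)J,
                                      arma::inv_sympd(Sm));
      Omega = arma::inv_sympd(prec);
    }

    if (it >= burn_in && ((it - burn_in + 1) % thin == 0)) {
      double dev = (double)n * (LOG2PI + std::log(var_e)) + sse / var_e;
      for (arma::uword d = 0; d < p; ++d) out(stored, d) = beta[d];
      out(stored, p + 0) = var_v;
      out(stored, p + 1) = Omega(0, 0);
      out(stored, p + 2) = Omega(0, 1);
      out(stored, p + 3) = Omega(1, 1);
      out(stored, p + 4) = var_e;
      out(stored, p + 5) = dev;
      v_mean += v;
      U_mean += U;
      if (store_ranef) {
        v_draws.row(stored) = v.t();
        U_draws.row(stored) = arma::join_rows(U.col(0).t(), U.col(1).t());
      }
      ++stored;
    }
  }
  if (stored > 0) {
    v_mean /= (double)stored;
    U_mean /= (double)stored;
  }

  List res = List::create(
    Named("draws") = out,
    Named("v_mean") = v_mean,
    Named("U_mean") = U_mean,
    Named("final") = List::create(
      Named("beta") = beta, Named("v") = v, Named("U") = U,
      Named("var_practice") = var_v, Named("cov_farm") = Omega,
      Named("var_residual") = var_e));
  if (store_ranef) {
    res["v_draws"] = v_draws;
    res["U_draws"] = U_draws;
  }
  return res;
}
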