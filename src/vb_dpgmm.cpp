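// Truncated stick-breaking variational inference for the DP Gaussian
// mixture. Priors: sticks Beta(1, alpha), means N(0, (1/beta0) Lambda^-1)
// (small beta0 emulates the independent N(0, I) mean prior while keeping
// conjugacy), precisions Wishart(nu0 = D, W0 = I). The returned ELBO is
// sum_n log-normalizer of the responsibilities minus the KL divergences of
// the stick and Normal-Wishart posteriors from their priors, which is the
// exact variational lower bound immediately after an E-step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double lmvgamma(double a, int D) {
  double out = 0.25 * D * (D - 1) * std::log(M_PI);
  for (int i = 1; i <= D; ++i) out += std::lgamma(a + 0.5 * (1 - i));
  return out;
}

// [[Rcpp::export]]
Rcpp::List vb_dpgmm_cpp(const arma::mat& X, const arma::mat& resp_init,
                        double alpha, double beta0, int max_iter,
                        double tol) {
  const int n = X.n_rows, D = X.n_cols, K = resp_init.n_cols;
  const double nu0 = (double) D;
  mat resp = resp_init;

  vec Nk(K), a(K), b(K), beta_k(K), nu_k(K), elogpi(K), eloglam(K),
      logdetWinv(K);
  mat m_k(K, D);
  cube Winv(D, D, K), Lchol(D, D, K);
  double elbo = -datum::inf, prev = -datum::inf;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // ---- M-step
    Nk = sum(resp, 0).t() + 1e-10;
    mat xbar = (resp.t() * X);
    xbar.each_col() /= Nk;
    double tail = 0.0;
    for (int k = K - 1; k >= 0; --k) { b(k) = alpha + tail; tail += Nk(k); }
    a = 1.0 + Nk;
    beta_k = beta0 + Nk;
    nu_k = nu0 + Nk;
    for (int k = 0; k < K; ++k) {
      m_k.row(k) = xbar.row(k) * (Nk(k) / beta_k(k));
      mat xc = X.each_row() - xbar.row(k);
      xc.each_col() %= sqrt(resp.col(k));
      mat S = xc.t() * xc;
      Winv.slice(k) = eye(D, D) + S +
        (beta0 * Nk(k) / beta_k(k)) * (xbar.row(k).t() * xbar.row(k));
      Lchol.slice(k) = chol(Winv.slice(k), "lower");
      logdetWinv(k) = 2.0 * sum(log(Lchol.slice(k).diag()));
    }

    // ---- E-step
    vec diga = vec(K), digb = vec(K), digab = vec(K);
    for (int k = 0; k < K; ++k) {
      diga(k) = R::digamma(a(k));
      digb(k) = R::digamma(b(k));
      digab(k) = R::digamma(a(k) + b(k));
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      elogpi(k) = diga(k) - digab(k) + acc;
      acc += digb(k) - digab(k);
    }
    mat logrho(n, K);
    for (int k = 0; k < K; ++k) {
      double el = D * std::log(2.0) - logdetWinv(k);
      for (int i = 1; i <= D; ++i)
        el += R::digamma(0.5 * (nu_k(k) + 1 - i));
      eloglam(k) = el;
      mat xc = (X.each_row() - m_k.row(k)).t();     // D x n
      mat sol = solve(trimatl(Lchol.slice(k)), xc); // L^{-1} (x-m)
      rowvec q = sum(square(sol), 0);
      logrho.col(k) = elogpi(k) + 0.5 * el - 0.5 * D / beta_k(k) -
        0.5 * nu_k(k) * q.t() - 0.5 * D * std::log(2.0 * M_PI);
    }
    vec mx = max(logrho, 1);
    vec lse = mx + log(sum(exp(logrho.each_col() - mx), 1));
    resp = exp(logrho.each_col() - lse);

    // ---- ELBO = sum lse - KL(sticks) - KL(Normal-Wishart)
    double kl = 0.0;
    for (int k = 0; k < K; ++k) {
      // Beta(a,b) vs Beta(1, alpha)
      double logB_ab = std::lgamma(a(k)) + std::lgamma(b(k)) -
        std::lgamma(a(k) + b(k));
      double logB_0 = std::lgamma(1.0) + std::lgamma(alpha) -
        std::lgamma(1.0 + alpha);
      kl += logB_0 - logB_ab + (a(k) - 1.0) * diga(k) +
        (b(k) - alpha) * digb(k) + (1.0 - a(k) + alpha - b(k)) * digab(k);
      // Normal part (expected over Lambda)
      vec sol = solve(trimatl(Lchol.slice(k)), m_k.row(k).t());
      double mWm = nu_k(k) * dot(sol, sol); // nu m^T W m via W = Winv^{-1}
      // note: m^T W m computed with W = Winv^{-1}: solve gives L^{-1} m and
      // W = L^{-T} L^{-1} only if Winv = L L^T -> m^T W m = ||L^{-1} m||^2
      kl += 0.5 * (D * beta0 / beta_k(k) + beta0 * mWm - D +
                   D * std::log(beta_k(k) / beta0));
      // Wishart part, W0 = I
      double logdetW = -logdetWinv(k);
      double trW = trace(inv_sympd(Winv.slice(k)));
      kl += 0.5 * (nu_k(k) - nu0) * eloglam(k) +
        0.5 * nu_k(k) * (trW - D) -
        0.5 * nu_k(k) * D * std::log(2.0) - 0.5 * nu_k(k) * logdetW -
        lmvgamma(0.5 * nu_k(k), D) +
        0.5 * nu0 * D * std::log(2.0) + lmvgamma(0.5 * nu0, D);
    }
    elbo = accu(lse) - kl;
    if (std::isfinite(prev) && std::abs(elbo - prev) < tol) break;
    prev = elbo;
  }

  Nk = sum(resp, 0).t();
  cube covs(D, D, K);
  for (int k = 0; k < K; ++k) covs.slice(k) = Winv.slice(k) / nu_k(k);
  return Rcpp::List::create(
    Rcpp::Named("weights") = Nk / (double) n,
    Rcpp::Named("means") = m_k,
    Rcpp::Named("covariances") = covs,
    Rcpp::Named("Nk") = Nk,
    Rcpp::Named("elbo") = elbo,
    Rcpp::Named("iterations") = iter);
}
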