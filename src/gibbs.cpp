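// Blocked Gibbs sampler for the multilevel AR model with dummy-separated
// within-day / overnight lag terms.
//
// Model (likelihood-eligible rows r = 1..N):
//   y_r = x_r' gamma + z_r' u_{pid(r)} + xi_{wid(r)} + zeta_{did(r)} + eps_r
//   eps_r ~ N(0, sig2e)
//   u_i ~ N_q(0, Sigma);  xi_w ~ N(0, sig2xi);  zeta_d ~ N(0, sig2zeta)
// Priors (Huang & Wand 2013 scale-mixture family, all conjugate):
//   gamma_j ~ N(0, 1/gamma_prior_prec)   (improper flat when prec = 0)
//   sig2* ~ InvGamma(sd_df/2, sd_df/a_*),  a_* ~ InvGamma(1/2, 1/sd_scale^2)
//     => sigma_* marginally half-t(sd_df, sd_scale)
//   Sigma ~ InvWishart(re_df + q - 1, 2 re_df diag(1/a_1..1/a_q)),
//     a_j ~ InvGamma(1/2, 1/re_scale^2)
//     => RE SDs marginally half-t(re_df, re_scale); with re_df = 2 the
//        marginal prior on each correlation is uniform on (-1, 1)
//
// All full conditionals are conjugate. Randomness goes through R's RNG so
// set.seed() in R gives fully reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Sample from InvWishart(df, S) using the Bartlett decomposition of the
// corresponding Wishart(df, S^{-1}) draw, with R's RNG.
static arma::mat rinvwishart(double df, const arma::mat& S) {
  const int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) A(i, i) = std::sqrt(R::rchisq(df - i));
  for (int i = 1; i < d; ++i)
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(arma::symmatu(W));
}

// MVN draw given precision matrix A and linear term b: N(A^{-1} b, A^{-1})
static arma::vec rmvn_prec(const arma::mat& A, const arma::vec& b) {
  arma::mat U = arma::chol(arma::symmatu(A), "upper");
  arma::vec mu = arma::solve(arma::trimatu(U),
                             arma::solve(arma::trimatl(U.t()), b));
  arma::vec z(b.n_elem);
  for (arma::uword j = 0; j < z.n_elem; ++j) z(j) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(U), z);
}

static double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate) => 1/X ~ InvGamma(shape, rate)
  return 1.0 / R::rgamma(shape, 1.0 / rate);
}

// [[Rcpp::export]]
List gibbs_lmm(const arma::vec& y, const arma::mat& X, const arma::mat& Z,
               const arma::ivec& pid, const arma::ivec& wid,
               const arma::ivec& did,
               int n_person, int n_wavegrp, int n_daygrp,
               bool use_person, bool use_wave, bool use_day,
               double gamma_prior_prec, double sd_df, double sd_scale,
               double re_df, double re_scale,
               int iter, int warmup) {
  const int N = y.n_elem;
  const int P = X.n_cols;
  const int q = use_person ? Z.n_cols : 0;
  const int n_keep = iter - warmup;
  if (n_keep <= 0) stop("iter must exceed warmup");
  if (gamma_prior_prec <= 0.0 && P > N)
    stop("flat prior requires at least as many rows as fixed effects");

  arma::uvec pu = N > 0 ? arma::conv_to<arma::uvec>::from(pid) : arma::uvec();
  arma::uvec wu = N > 0 ? arma::conv_to<arma::uvec>::from(wid) : arma::uvec();
  arma::uvec du = N > 0 ? arma::conv_to<arma::uvec>::from(did) : arma::uvec();

  // Precomputed cross-products (X and Z never change across iterations).
  arma::mat XtX = X.t() * X;
  arma::cube ZtZ(q, q, std::max(n_person, 1), arma::fill::zeros);
  if (use_person) {
    for (int r = 0; r < N; ++r) {
      const arma::rowvec zr = Z.row(r);
      ZtZ.slice(pid(r)) += zr.t() * zr;
    }
  }
  arma::vec n_w(std::max(n_wavegrp, 1), arma::fill::zeros);
  arma::vec n_d(std::max(n_daygrp, 1), arma::fill::zeros);
  for (int r = 0; r < N; ++r) {
    if (use_wave) n_w(wid(r)) += 1.0;
    if (use_day)  n_d(did(r)) += 1.0;
  }

  // State
  arma::vec gamma(P, arma::fill::zeros);
  arma::mat u(std::max(n_person, 1), std::max(q, 1), arma::fill::zeros);
  arma::vec xi(std::max(n_wavegrp, 1), arma::fill::zeros);
  arma::vec zeta(std::max(n_daygrp, 1), arma::fill::zeros);
  arma::mat Sigma = arma::eye(std::max(q, 1), std::max(q, 1)) * 0.1;
  double sig2e = N > 1 ? arma::var(y) : 1.0;
  if (!(sig2e > 0)) sig2e = 1.0;
  double sig2xi = 0.1, sig2zeta = 0.1;
  // latent scales of the half-t mixture priors
  double a_e = 1.0, a_xi = 1.0, a_zeta = 1.0;
  arma::vec a_re(std::max(q, 1), arma::fill::ones);
  const double inv_A2 = 1.0 / (sd_scale * sd_scale);
  const double inv_A2_re = 1.0 / (re_scale * re_scale);

  // Storage
  arma::mat gamma_draws(n_keep, P, arma::fill::zeros);
  arma::mat sigma_draws(n_keep, use_person ? q * (q + 1) / 2 : 0);
  arma::vec sig2xi_draws(use_wave ? n_keep : 0);
  arma::vec sig2zeta_draws(use_day ? n_keep : 0);
  arma::vec sig2e_draws(n_keep);
  arma::cube u_draws(use_person ? n_keep : 0,
                     use_person ? n_person : 0,
                     use_person ? q : 0);

  arma::vec zu(N, arma::fill::zeros);
  arma::vec rnd(N, arma::fill::zeros);   // xi + zeta contribution per row

  auto update_zu = [&]() {
    if (!use_person || N == 0) return;
    arma::vec uc = u.col(0);
    zu = Z.col(0) % uc.elem(pu);
    for (int j = 1; j < q; ++j) {
      uc = u.col(j);
      zu += Z.col(j) % uc.elem(pu);
    }
  };
  auto update_rnd = [&]() {
    if (N == 0) return;
    rnd.zeros();
    if (use_wave) rnd += xi.elem(wu);
    if (use_day)  rnd += zeta.elem(du);
  };

  for (int it = 0; it < iter; ++it) {
    update_zu();
    update_rnd();

    // --- gamma ---
    {
      arma::mat A = XtX / sig2e;
      A.diag() += gamma_prior_prec;
      arma::vec b = N > 0 ? arma::vec(X.t() * (y - zu - rnd) / sig2e)
                          : arma::vec(P, arma::fill::zeros);
      gamma = rmvn_prec(A, b);
    }
    arma::vec fx = N > 0 ? arma::vec(X * gamma) : arma::vec();

    // --- person effects u_i, then Sigma ---
    if (use_person) {
      arma::mat bmat(q, n_person, arma::fill::zeros);
      if (N > 0) {
        arma::vec e = y - fx - rnd;
        const double* zp[8];
        for (int j = 0; j < q; ++j) zp[j] = Z.colptr(j);
        for (int r = 0; r < N; ++r) {
          double* bc = bmat.colptr(pid(r));
          const double er = e(r);
          for (int j = 0; j < q; ++j) bc[j] += zp[j][r] * er;
        }
      }
      arma::mat Sigmainv = arma::inv_sympd(arma::symmatu(Sigma));
      for (int i = 0; i < n_person; ++i) {
        arma::mat A = ZtZ.slice(i) / sig2e + Sigmainv;
        u.row(i) = rmvn_prec(A, bmat.col(i) / sig2e).t();
      }
      update_zu();
      arma::mat S = u.rows(0, n_person - 1).t() * u.rows(0, n_person - 1);
      S.diag() += 2.0 * re_df / a_re;
      Sigma = rinvwishart(re_df + q - 1.0 + n_person, S);
      arma::mat Sigmainv2 = arma::inv_sympd(arma::symmatu(Sigma));
      for (int j = 0; j < q; ++j)
        a_re(j) = rinvgamma((re_df + q) / 2.0,
                            re_df * Sigmainv2(j, j) + inv_A2_re);
    }

    // --- wave intercepts xi ---
    if (use_wave) {
      arma::vec s(n_wavegrp, arma::fill::zeros);
      if (N > 0) {
        arma::vec e = y - fx - zu;
        if (use_day) e -= zeta.elem(du);
        for (int r = 0; r < N; ++r) s(wid(r)) += e(r);
      }
      for (int w = 0; w < n_wavegrp; ++w) {
        double prec = n_w(w) / sig2e + 1.0 / sig2xi;
        xi(w) = (s(w) / sig2e) / prec + R::norm_rand() / std::sqrt(prec);
      }
      sig2xi = rinvgamma((sd_df + n_wavegrp) / 2.0,
                         sd_df / a_xi + arma::dot(xi.head(n_wavegrp),
                                                  xi.head(n_wavegrp)) / 2.0);
      a_xi = rinvgamma((sd_df + 1.0) / 2.0, sd_df / sig2xi + inv_A2);
    }

    // --- day intercepts zeta ---
    if (use_day) {
      arma::vec s(n_daygrp, arma::fill::zeros);
      if (N > 0) {
        arma::vec e = y - fx - zu;
        if (use_wave) e -= xi.elem(wu);
        for (int r = 0; r < N; ++r) s(did(r)) += e(r);
      }
      for (int d = 0; d < n_daygrp; ++d) {
        double prec = n_d(d) / sig2e + 1.0 / sig2zeta;
        zeta(d) = (s(d) / sig2e) / prec + R::norm_rand() / std::sqrt(prec);
      }
      sig2zeta = rinvgamma((sd_df + n_daygrp) / 2.0,
                           sd_df / a_zeta +
                             arma::dot(zeta.head(n_daygrp),
                                       zeta.head(n_daygrp)) / 2.0);
      a_zeta = rinvgamma((sd_df + 1.0) / 2.0, sd_df / sig2zeta + inv_A2);
    }

    // --- translation (interweaving) moves ---
    // Sample an exact shift between each fixed effect and the mean of its
    // random-effect column (likelihood-invariant because the fixed and
    // random designs share these columns); this decorrelates gamma from
    // the group means and removes the sampler's slowest direction.
    if (use_person) {
      arma::mat Sigmainv = arma::inv_sympd(arma::symmatu(Sigma));
      for (int j = 0; j < q && j < P; ++j) {
        arma::vec colsum = arma::sum(u.rows(0, n_person - 1), 0).t();
        arma::vec Su = Sigmainv * colsum;
        double prec = n_person * Sigmainv(j, j) + gamma_prior_prec;
        double mean = (Su(j) - gamma(j) * gamma_prior_prec) / prec;
        double c = mean + R::norm_rand() / std::sqrt(prec);
        u.col(j) -= c;
        gamma(j) += c;
      }
    }
    if (use_wave && P > 0) {
      double prec = n_wavegrp / sig2xi + gamma_prior_prec;
      double mean = (arma::accu(xi.head(n_wavegrp)) / sig2xi -
                     gamma(0) * gamma_prior_prec) / prec;
      double c = mean + R::norm_rand() / std::sqrt(prec);
      xi.head(n_wavegrp) -= c;
      gamma(0) += c;
    }
    if (use_day && P > 0) {
      double prec = n_daygrp / sig2zeta + gamma_prior_prec;
      double mean = (arma::accu(zeta.head(n_daygrp)) / sig2zeta -
                     gamma(0) * gamma_prior_prec) / prec;
      double c = mean + R::norm_rand() / std::sqrt(prec);
      zeta.head(n_daygrp) -= c;
      gamma(0) += c;
    }

    // --- residual variance ---
    double ssr = 0.0;
    if (N > 0) {
      fx = X * gamma;   // refresh after the translation moves
      update_zu();
      update_rnd();
      arma::vec e = y - fx - zu - rnd;
      ssr = arma::dot(e, e);
    }
    sig2e = rinvgamma((sd_df + N) / 2.0, sd_df / a_e + ssr / 2.0);
    a_e = rinvgamma((sd_df + 1.0) / 2.0, sd_df / sig2e + inv_A2);

    // --- store ---
    if (it >= warmup) {
      const int k = it - warmup;
      gamma_draws.row(k) = gamma.t();
      if (use_person) {
        int c = 0;
        for (int i = 0; i < q; ++i)
          for (int j = i; j < q; ++j) sigma_draws(k, c++) = Sigma(i, j);
        for (int i = 0; i < n_person; ++i)
          for (int j = 0; j < q; ++j) u_draws(k, i, j) = u(i, j);
      }
      if (use_wave) sig2xi_draws(k) = sig2xi;
      if (use_day)  sig2zeta_draws(k) = sig2zeta;
      sig2e_draws(k) = sig2e;
    }
  }

  return List::create(_["gamma"] = gamma_draws,
                      _["sigma_tri"] = sigma_draws,
                      _["sig2_wave"] = sig2xi_draws,
                      _["sig2_day"] = sig2zeta_draws,
                      _["sig2_eps"] = sig2e_draws,
                      _["u"] = u_draws);
}
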