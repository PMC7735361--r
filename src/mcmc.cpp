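// Metropolis-within-Gibbs sampler for the Poisson log-link phylogenetic
// GLMM:  y_i ~ Pois(exp(l_i)),  l_i = x_i'beta + o_i + u_i + e_i,
//        u ~ N(0, sig2_a * A),  e ~ N(0, sig2_e * I).
//
// The latent field l is updated by adaptive single-site random-walk
// Metropolis (step sizes tuned to 0.44 acceptance during burn-in only);
// given l, the decomposition (beta, u, e) is resampled by exact Gaussian
// conditionals; variances are inverse-Gamma Gibbs draws, with the
// parameter-expansion working scalar alpha (u = alpha * eta,
// sig2_a = alpha^2 * sig2_eta) giving the phylogenetic variance its
// scaled-F prior.  A is passed pre-eigendecomposed (A = Q diag(lam) Q')
// so the eta update is diagonal in the rotated basis: O(n^2) per sweep.
//
// All randomness comes from R's RNG, so set.seed() on the R side governs
// the whole chain.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rinvgamma(double shape, double scale) {
  // X ~ Gamma(shape, rate = scale)  =>  1/X ~ InvGamma(shape, scale)
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// [[Rcpp::export(name = ".mcmc_core")]]
List mcmc_core(const arma::vec& y, const arma::mat& X, const arma::vec& o,
               const arma::mat& Q, const arma::vec& lam,
               List priors, int nitt, int thin, int burnin,
               double fix_a, double fix_e, bool use_lik,
               const arma::vec& beta_init) {
  const int n = y.n_elem, p = X.n_cols;
  const double Vb     = as<double>(priors["V_beta"]);
  const double nu_a   = as<double>(priors["nu_a"]);
  const double Va     = as<double>(priors["V_a"]);
  const double alphaV = as<double>(priors["alpha_V"]);
  const double nu_e   = as<double>(priors["nu_e"]);
  const double Ve     = as<double>(priors["V_e"]);
  const bool px = fix_a < 0;          // parameter-expanded sig2_a update?
  const bool free_e = fix_e < 0;

  arma::vec beta = beta_init;
  arma::vec zeta(n, arma::fill::zeros);          // eta in the eigenbasis
  arma::vec eta(n, arma::fill::zeros);
  double alpha = 1.0;
  double sig2_eta = px ? Va : fix_a;
  double sig2_e = free_e ? Ve : fix_e;
  if (sig2_e <= 0) stop("sig2_e must be fixed at a positive value");
  if (!px && sig2_eta < 0) stop("sig2_a must be fixed at a non-negative value");

  arma::vec ell = X * beta + o;
  arma::vec step(n, arma::fill::value(0.5));     // RW proposal sds
  arma::vec n_acc(n, arma::fill::zeros);

  const int n_keep = (nitt - burnin) / thin;
  arma::mat beta_chain(n_keep, p), latent_chain(n_keep, n);
  arma::vec s2a_chain(n_keep), s2e_chain(n_keep);
  int keep = 0;

  for (int it = 1; it <= nitt; ++it) {
    // --- single-site Metropolis on the latents -------------------------
    arma::vec m = X * beta + o + alpha * eta;
    const double inv2s2e = 0.5 / sig2_e;
    for (int i = 0; i < n; ++i) {
      double cur = ell[i];
      double prop = cur + step[i] * norm_rand();
      double d = 0.0;
      if (use_lik)
        d += y[i] * (prop - cur) - (std::exp(prop) - std::exp(cur));
      double rc = cur - m[i], rp = prop - m[i];
      d += inv2s2e * (rc * rc - rp * rp);
      bool acc = std::log(unif_rand()) < d;
      if (acc) { ell[i] = prop; n_acc[i] += 1.0; }
      if (it <= burnin) {
        double gam = std::pow((double)it, -0.6);
        step[i] *= std::exp(gam * ((acc ? 1.0 : 0.0) - 0.44));
        if (step[i] < 1e-4) step[i] = 1e-4;
        if (step[i] > 50.0) step[i] = 50.0;
      }
    }
    if (!ell.is_finite())
      stop("divergent chain: non-finite latent predictor at iteration %d", it);

    // --- (beta, alpha) Gaussian conditional given l, eta ---------------
    {
      int q = px ? p + 1 : p;
      arma::mat W(n, q);
      W.cols(0, p - 1) = X;
      if (px) W.col(p) = eta;
      arma::mat M = W.t() * W / sig2_e;
      for (int j = 0; j < p; ++j) M(j, j) += 1.0 / Vb;
      if (px) M(p, p) += 1.0 / alphaV;
      arma::vec b = W.t() * (ell - o) / sig2_e;
      arma::mat R = arma::chol(M);               // M = R'R, R upper
      arma::vec mu = arma::solve(M, b);
      arma::vec z(q); for (int j = 0; j < q; ++j) z[j] = norm_rand();
      arma::vec theta = mu + arma::solve(arma::trimatu(R), z);
      beta = theta.head(p);
      if (px) alpha = theta[p];
    }

    // --- eta (rotated: diagonal precision) -----------------------------
    if (sig2_eta > 0) {
      arma::vec r = ell - o - X * beta;
      arma::vec rq = Q.t() * r;
      for (int j = 0; j < n; ++j) {
        double prec = alpha * alpha / sig2_e + 1.0 / (sig2_eta * lam[j]);
        double mean = (alpha / sig2_e) * rq[j] / prec;
        zeta[j] = mean + norm_rand() / std::sqrt(prec);
      }
      eta = Q * zeta;
    } else {
      zeta.zeros(); eta.zeros();
    }

    // --- variances -----------------------------------------------------
    arma::vec e = ell - o - X * beta - alpha * eta;
    if (free_e)
      sig2_e = rinvgamma(0.5 * (nu_e + n),
                         0.5 * (nu_e * Ve + arma::dot(e, e)));
    if (px) {
      double ss = 0.0;
      for (int j = 0; j < n; ++j) ss += zeta[j] * zeta[j] / lam[j];
      sig2_eta = rinvgamma(0.5 * (nu_a + n), 0.5 * (nu_a * Va + ss));
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      beta_chain.row(keep) = beta.t();
      s2a_chain[keep] = px ? alpha * alpha * sig2_eta : sig2_eta;
      s2e_chain[keep] = sig2_e;
      latent_chain.row(keep) = ell.t();
      ++keep;
    }
  }

  return List::create(
    _["beta"] = beta_chain, _["sig2_a"] = s2a_chain,
    _["sig2_e"] = s2e_chain, _["latent"] = latent_chain,
    _["acc_rate"] = n_acc / nitt, _["step"] = step);
}
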