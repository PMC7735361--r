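#' Model specification for the node-count GLMM
#'
#' The three candidate forms of the time effect on the latent (log) scale:
#' `"null"` is linear in time elapsed (`1, t`), `"asymptote"` uses the
#' square root (`1, sqrt(t)`), and `"downturn"` adds a quadratic term
#' (`1, t, t^2`).  The intercept can be estimated, or fixed on the latent
#' scale at 0 (`E[y] = 1` when no time has elapsed) or at 1
#' (`E[y] = e` at the root); fixing replaces the intercept column by a
#' constant offset.
#'
#' @param form `"null"`, `"asymptote"` or `"downturn"`.
#' @param intercept `"estimated"`, `"fixed_zero"` or `"fixed_one"`.
#' @return list of class `"model_spec"`.
#' @export
model_spec <- function(form = c("null", "asymptote", "downturn"),
                       intercept = c("estimated", "fixed_zero", "fixed_one")) {
  structure(list(form = match.arg(form), intercept = match.arg(intercept)),
            class = "model_spec")
}

#' Prior specification
#'
#' Defaults follow the standard weakly-informative setup for Poisson
#' phylogenetic mixed models: diffuse independent normals for fixed
#' effects (`mu = 0`, `V = 1e10`); a parameter-expanded prior for the
#' phylogenetic variance (`V = 1`, `nu = 1`, working scalar
#' `alpha ~ N(0, 25^2)`, giving a heavy-tailed scaled-F marginal); and an
#' inverse-Gamma `V = 1`, `nu = 0.002` prior for the residual variance.
#'
#' @param V_beta fixed-effect prior variance per coefficient.
#' @param nu_a,V_a phylogenetic-variance inverse-Gamma parameters.
#' @param alpha_mu,alpha_V mean and variance of the parameter-expansion
#'   working scalar (the mean must be 0 in this implementation).
#' @param nu_e,V_e residual-variance inverse-Gamma parameters.
#' @return list of class `"prior_spec"`.
#' @export
prior_spec <- function(V_beta = 1e10, nu_a = 1, V_a = 1,
                       alpha_mu = 0, alpha_V = 25^2,
                       nu_e = 0.002, V_e = 1) {
  stopifnot(V_beta > 0, V_a > 0, alpha_V > 0, V_e > 0, nu_a > 0, nu_e > 0,
            alpha_mu == 0)
  structure(list(V_beta = V_beta, nu_a = nu_a, V_a = V_a,
                 alpha_mu = alpha_mu, alpha_V = alpha_V,
                 nu_e = nu_e, V_e = V_e),
            class = "prior_spec")
}

#' MCMC settings
#'
#' Defaults: `5e5` iterations, thinning every `1e3`, the first `5e4`
#' discarded as burn-in, retaining `(nitt - burnin) / thin = 450` samples.
#'
#' @param nitt total iterations.
#' @param thin thinning interval.
#' @param burnin burn-in iterations (adaptation happens only here).
#' @param seed integer seed for the whole chain.
#' @return list of class `"mcmc_settings"` with an `n_keep` element.
#' @export
mcmc_settings <- function(nitt = 5e5, thin = 1e3, burnin = 5e4, seed = 1L) {
  stopifnot(burnin < nitt, thin >= 1)
  structure(list(nitt = as.integer(nitt), thin = as.integer(thin),
                 burnin = as.integer(burnin), seed = as.integer(seed),
                 n_keep = as.integer((nitt - burnin) %/% thin)),
            class = "mcmc_settings")
}

#' Build the fixed-effect design for a model specification
#'
#' @param stats data.frame with a `time_elapsed` column (see
#'   [extract_table()]), or a numeric vector of times.
#' @param spec a [model_spec()].
#' @return list with `X` (design matrix) and `offset` (latent-scale
#'   constant offset vector: 0 under `estimated`/`fixed_zero`, 1 under
#'   `fixed_one`).
#' @export
build_design <- function(stats, spec) {
  stopifnot(inherits(spec, "model_spec"))
  tt <- if (is.data.frame(stats)) stats$time_elapsed else as.numeric(stats)
  if (spec$form == "asymptote" && any(tt < 0))
    stop("negative time elapsed under the asymptote (square-root) form")
  Xt <- switch(spec$form,
               null = cbind(t = tt),
               asymptote = cbind(sqrt_t = sqrt(tt)),
               downturn = cbind(t = tt, t2 = tt^2))
  if (spec$intercept == "estimated") {
    X <- cbind(`(Intercept)` = rep(1, length(tt)), Xt)
    offset <- rep(0, length(tt))
  } else {
    X <- Xt
    offset <- rep(if (spec$intercept == "fixed_one") 1 else 0, length(tt))
  }
  list(X = X, offset = offset)
}

#' Log-likelihood and log-prior of the Poisson phylogenetic GLMM
#'
#' Evaluates the two parts of the (unnormalized) log posterior at a given
#' state.  The log-likelihood is
#' `sum_i [ y_i l_i - exp(l_i) - log(y_i!) ]` with
#' `l_i = x_i'beta + o_i + u_i + e_i`; the log-prior combines
#' `u ~ N(0, sig2_a A)`, `e ~ N(0, sig2_e I)`, normal priors on `beta`
#' and inverse-Gamma priors on the variances.
#'
#' @param y counts; `X` design; `o` offset; `A` phylogenetic covariance.
#' @param X,o,A see above.
#' @param beta,u,e state vectors; `sig2_a`, `sig2_e` variances (`> 0`).
#' @param sig2_a,sig2_e variance components.
#' @param priors a [prior_spec()].
#' @return named numeric `c(loglik, logprior)`.
#' @export
log_posterior_parts <- function(y, X, o, A, beta, u, e, sig2_a, sig2_e,
                                priors = prior_spec()) {
  stopifnot(sig2_a > 0, sig2_e > 0)
  if (any(!is.finite(c(beta, u, e)))) stop("non-finite state")
  ell <- as.vector(X %*% beta) + o + u + e
  loglik <- sum(y * ell - exp(ell) - lgamma(y + 1))
  eg <- eigen(A, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-12)
  uq <- as.vector(crossprod(eg$vectors, u))
  lp_u <- -0.5 * sum(log(2 * pi * sig2_a * lam)) -
    0.5 * sum(uq^2 / (sig2_a * lam))
  lp_e <- sum(stats::dnorm(e, 0, sqrt(sig2_e), log = TRUE))
  lp_b <- sum(stats::dnorm(beta, 0, sqrt(priors$V_beta), log = TRUE))
  ig <- function(x, nu, V) {
    a <- nu / 2; b <- nu * V / 2
    a * log(b) - lgamma(a) - (a + 1) * log(x) - b / x
  }
  lp_v <- ig(sig2_a, priors$nu_a, priors$V_a) +
    ig(sig2_e, priors$nu_e, priors$V_e)
  c(loglik = loglik, logprior = lp_u + lp_e + lp_b + lp_v)
}

#' Fit the Poisson phylogenetic GLMM by MCMC
#'
#' Runs the built-in Metropolis-within-Gibbs sampler (see the package
#' vignette for the algorithm) and returns posterior chains, DIC and ESS
#' diagnostics.  `A` is eigendecomposed once; eigenvalues below `1e-8`
#' are raised to `1e-8` (trees with zero shared branch lengths can be
#' numerically borderline), and an eigenvalue below `-1e-8` is an error.
#'
#' @param y integer counts (length n).
#' @param X design matrix (n x p), from [build_design()].
#' @param o latent-scale offset vector (length n).
#' @param A phylogenetic covariance matrix (n x n), from [phylo_vcv()].
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param fix_sig2_a,fix_sig2_e optionally hold a variance component fixed
#'   at a given positive value (`fix_sig2_a = 0` is allowed and removes
#'   the phylogenetic effect entirely); `NULL` (default) samples it.
#' @param likelihood set `FALSE` to sample from the prior only
#'   (diagnostic).
#' @return object of class `"ncdiv_fit"`: list with `chains` (matrix of
#'   retained samples for the fixed effects and variances), `latent`
#'   (retained latent-predictor samples), `DIC`, `pD`, `ess`
#'   (per-parameter), `mean_ess`, `acc_rate`, `spec`/`priors`/`settings`
#'   echoes.
#' @export
fit_mcmc <- function(y, X, o, A, priors = prior_spec(),
                     settings = mcmc_settings(),
                     fix_sig2_a = NULL, fix_sig2_e = NULL,
                     likelihood = TRUE) {
  stopifnot(inherits(priors, "prior_spec"), inherits(settings, "mcmc_settings"))
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(o) == n, nrow(A) == n, ncol(A) == n)
  if (any(y < 0) || any(y != round(y))) stop("y must be non-negative counts")
  eg <- eigen(A, symmetric = TRUE)
  if (min(eg$values) < -1e-8)
    stop("A is not positive semi-definite: eigenvalue ",
         format(min(eg$values)))
  lam <- pmax(eg$values, 1e-8)
  beta_init <- tryCatch(
    qr.solve(crossprod(X) + diag(1e-8, p),
             crossprod(X, log(pmax(y, 0.5)) - o)),
    error = function(e) rep(0, p))
  set.seed(settings$seed)
  out <- .mcmc_core(as.numeric(y), X, as.numeric(o), eg$vectors, lam,
                    unclass(priors), settings$nitt, settings$thin,
                    settings$burnin,
                    if (is.null(fix_sig2_a)) -1 else fix_sig2_a,
                    if (is.null(fix_sig2_e)) -1 else fix_sig2_e,
                    isTRUE(likelihood), as.numeric(beta_init))
  xnames <- colnames(X)
  if (is.null(xnames)) xnames <- paste0("beta", seq_len(p) - 1L)
  chains <- cbind(out$beta, sig2_a = out$sig2_a, sig2_e = out$sig2_e)
  colnames(chains) <- c(xnames, "sig2_a", "sig2_e")
  dic <- compute_dic(out$latent, y)
  ess <- apply(chains, 2L, function(ch)
    suppressWarnings(compute_ess(ch)))
  fit <- structure(list(
    chains = chains, latent = out$latent,
    DIC = dic[["DIC"]], pD = dic[["pD"]],
    ess = ess, mean_ess = mean(ess),
    acc_rate = as.vector(out$acc_rate),
    priors = priors, settings = settings,
    y = y, X = X, offset = o), class = "ncdiv_fit")
  if (fit$mean_ess < 200 && likelihood)
    message("note: mean ESS ", round(fit$mean_ess, 1),
            " is below the quality bar of 200")
  fit
}

#' @export
print.ncdiv_fit <- function(x, ...) {
  cat("Poisson phylogenetic GLMM fit (", nrow(x$chains),
      " retained samples)\n", sep = "")
  cat("  DIC = ", format(x$DIC, digits = 6), ", pD = ",
      format(x$pD, digits = 4), ", mean ESS = ",
      format(x$mean_ess, digits = 4), "\n", sep = "")
  pm <- colMeans(x$chains)
  ci <- apply(x$chains, 2L, quantile, c(0.025, 0.975))
  tab <- data.frame(mean = pm, lower95 = ci[1L, ], upper95 = ci[2L, ],
                    ESS = x$ess)
  print(round(tab, 4))
  invisible(x)
}

#' Effective sample size of an MCMC chain
#'
#' `N / (1 + 2 * sum rho_k)` with the autocorrelation sum truncated by
#' Geyer's initial positive sequence (summing consecutive lag pairs while
#' their sum stays positive).  The result is clipped to `[0, N]`.  A
#' constant chain has no information and returns 0 with a warning.
#'
#' @param chain numeric vector, length >= 10.
#' @return effective sample size (numeric scalar).
#' @export
compute_ess <- function(chain) {
  N <- length(chain)
  if (N < 10) stop("chain too short (need >= 10)")
  if (stats::var(chain) == 0) {
    warning("constant chain: ESS is 0")
    return(0)
  }
  rho <- as.vector(acf(chain, lag.max = N - 1, plot = FALSE,
                       demean = TRUE)$acf)
  # rho[1] = lag 0; pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  tau <- 0
  m <- 0
  repeat {
    i1 <- 2 * m + 1; i2 <- 2 * m + 2  # 1-based indices of lags 2m, 2m+1
    if (i1 > length(rho)) break
    g <- rho[i1] + if (i2 <= length(rho)) rho[i2] else 0
    if (g <= 0) break
    tau <- tau + 2 * g
    m <- m + 1
  }
  tau <- tau - 1  # lag 0 counted twice in the pair sums
  ess <- N / max(tau, .Machine$double.eps)
  min(max(ess, 0), N)
}

#' DIC from retained latent-predictor samples
#'
#' Uses the deviance conditional on the latent predictors:
#' `D(l) = -2 sum_i log Pois(y_i | exp(l_i))`.  `Dbar` is the posterior
#' mean deviance, `Dhat` the deviance at the posterior-mean latents,
#' `pD = Dbar - Dhat` and `DIC = Dbar + pD`.  (DIC variants differ for
#' hierarchical models; the conditional focus is the standard choice when
#' the marginal likelihood is intractable, so absolute DIC values are
#' comparable only within this package while DIC differences between
#' models on the same data are the meaningful quantity.)
#'
#' @param latent matrix of retained latent samples (samples x n).
#' @param y observed counts (length n).
#' @return named numeric `c(DIC, pD)`.
#' @export
compute_dic <- function(latent, y) {
  latent <- as.matrix(latent)
  if (nrow(latent) == 0L) stop("empty chain")
  dev_of <- function(l) -2 * sum(stats::dpois(y, exp(l), log = TRUE))
  D <- apply(latent, 1L, dev_of)
  Dbar <- mean(D)
  Dhat <- dev_of(colMeans(latent))
  c(DIC = Dbar + (Dbar - Dhat), pD = Dbar - Dhat)
}

#' Fit one model form to a dated tree
#'
#' Convenience wrapper: extracts the node-count table and phylogenetic
#' covariance from a dated tree, builds the design for `spec`, and calls
#' [fit_mcmc()].
#'
#' @param tree a dated `"phylo"`.
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @param scale_vcv passed to [phylo_vcv()] as `scale`.
#' @return an `"ncdiv_fit"` (see [fit_mcmc()]), with the spec attached.
#' @export
fit_nodecount_model <- function(tree, spec, priors = prior_spec(),
                                settings = mcmc_settings(),
                                scale_vcv = FALSE) {
  tab <- extract_table(tree)
  d <- build_design(tab, spec)
  A <- phylo_vcv(tree, scale = scale_vcv)
  fit <- fit_mcmc(tab$node_count, d$X, d$offset, A, priors, settings)
  fit$spec <- spec
  fit
}
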