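test_that("build_design encodes form and intercept treatment", {
  d <- build_design(4, model_spec("downturn", "estimated"))
  expect_equal(unname(d$X[1, ]), c(1, 4, 16))
  expect_equal(d$offset, 0)

  d2 <- build_design(4, model_spec("asymptote", "fixed_one"))
  expect_equal(unname(d2$X[1, ]), 2)
  expect_equal(d2$offset, 1)

  d3 <- build_design(4, model_spec("null", "fixed_zero"))
  expect_equal(unname(d3$X[1, ]), 4)
  expect_equal(d3$offset, 0)

  # at the root (t = 0) the estimated-intercept row is (1, 0[, 0]) so the
  # expected count is exp(beta0)
  for (f in c("null", "asymptote", "downturn")) {
    d0 <- build_design(0, model_spec(f, "estimated"))
    expect_equal(unname(d0$X[1, -1]), rep(0, ncol(d0$X) - 1L))
    expect_equal(unname(d0$X[1, 1]), 1)
  }
  expect_error(build_design(-1, model_spec("asymptote")), "negative time")
})

test_that("log-likelihood part matches the Poisson pmf oracle", {
  # single-observation anchors: y=1, l=0 and y=0, l=0 both give -1
  A1 <- diag(1)
  lp <- log_posterior_parts(1, matrix(0), 0, A1, beta = 0, u = 0, e = 0,
                            sig2_a = 1, sig2_e = 1)
  expect_equal(unname(lp["loglik"]), -1)
  lp0 <- log_posterior_parts(0, matrix(0), 0, A1, beta = 0, u = 0, e = 0,
                             sig2_a = 1, sig2_e = 1)
  expect_equal(unname(lp0["loglik"]), -1)

  # random small instances against dpois()
  set.seed(21)
  for (rep in 1:20) {
    n <- 7
    tr <- random_tree(n)
    A <- phylo_vcv(tr)
    X <- cbind(1, runif(n, 0, 10))
    beta <- rnorm(2, 0, 0.3); u <- rnorm(n, 0, 0.5); e <- rnorm(n, 0, 0.2)
    o <- rep(0.5, n)
    y <- rpois(n, 3)
    ell <- as.vector(X %*% beta) + o + u + e
    want <- sum(dpois(y, exp(ell), log = TRUE))
    got <- log_posterior_parts(y, X, o, A, beta, u, e, 0.3, 0.2)
    expect_equal(unname(got["loglik"]), want, tolerance = 1e-10)
    expect_true(is.finite(got["logprior"]))
  }
  expect_error(log_posterior_parts(1, matrix(1), 0, A1, NaN, 0, 0, 1, 1),
               "non-finite")
})

test_that("retained-sample bookkeeping matches the settings arithmetic", {
  # default chain settings retain (5e5 - 5e4) / 1e3 = 450 samples
  expect_identical(mcmc_settings()$n_keep, 450L)
  st <- mcmc_settings(nitt = 3000, thin = 10, burnin = 500, seed = 4)
  tr <- bd_fixture(lo = 20, hi = 100, seed_from = 9L)
  fit <- fit_nodecount_model(tr, model_spec("null"), settings = st)
  expect_identical(nrow(fit$chains), (3000L - 500L) %/% 10L)
  expect_identical(nrow(fit$latent), nrow(fit$chains))
  expect_true(all(fit$chains[, "sig2_a"] > 0))
  expect_true(all(fit$chains[, "sig2_e"] > 0))
  expect_true(is.finite(fit$DIC))
})

test_that("same seed gives identical chains", {
  tr <- bd_fixture(lo = 20, hi = 100, seed_from = 9L)
  st <- mcmc_settings(nitt = 2000, thin = 10, burnin = 200, seed = 99)
  f1 <- fit_nodecount_model(tr, model_spec("asymptote"), settings = st)
  f2 <- fit_nodecount_model(tr, model_spec("asymptote"), settings = st)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$DIC, f2$DIC)
})

test_that("ESS estimator behaves on iid, constant and AR(1) chains", {
  expect_warning(ess0 <- compute_ess(rep(3, 100)), "constant")
  expect_equal(ess0, 0)
  expect_error(compute_ess(1:5), "too short")

  set.seed(31)
  ess_iid <- replicate(100, compute_ess(rnorm(450)))
  expect_lt(abs(median(ess_iid) - 450) / 450, 0.2)
  expect_true(all(ess_iid <= 450))

  # AR(1) with rho = 0.9: ESS ~= N (1 - rho) / (1 + rho)
  rho <- 0.9; N <- 2000
  ess_ar <- replicate(100, {
    x <- as.vector(stats::arima.sim(list(ar = rho), N))
    compute_ess(x)
  })
  want <- N * (1 - rho) / (1 + rho)
  expect_lt(abs(median(ess_ar) - want) / want, 0.3)
})

test_that("DIC matches hand arithmetic and degenerates correctly", {
  y <- c(2, 0, 5)
  # all retained samples identical -> pD = 0, DIC = Dhat
  lat <- rbind(c(0.5, -1, 1.2), c(0.5, -1, 1.2))
  d <- compute_dic(lat, y)
  expect_equal(unname(d["pD"]), 0)
  expect_equal(unname(d["DIC"]),
               -2 * sum(dpois(y, exp(c(0.5, -1, 1.2)), log = TRUE)))

  # two distinct samples: hand-computed Dbar, Dhat
  l1 <- c(0.2, 0.1, 1.5); l2 <- c(0.8, -0.4, 1.0)
  dev <- function(l) -2 * sum(y * l - exp(l) - lgamma(y + 1))
  Dbar <- (dev(l1) + dev(l2)) / 2
  Dhat <- dev((l1 + l2) / 2)
  got <- compute_dic(rbind(l1, l2), y)
  expect_equal(unname(got["pD"]), Dbar - Dhat, tolerance = 1e-12)
  expect_equal(unname(got["DIC"]), 2 * Dbar - Dhat, tolerance = 1e-12)
  expect_error(compute_dic(matrix(0, 0, 3), y), "empty")
})

test_that("prior-only sampling recovers the fixed-effect prior moments", {
  # a shallow tree keeps the slope's lever arm O(1), so the chain can
  # traverse the prior within a cheap Monte-Carlo budget
  set.seed(2)
  n <- 15
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  A <- phylo_vcv(tr)
  X <- cbind(1, time_elapsed(tr))
  pr <- prior_spec(V_beta = 4, nu_a = 4, V_a = 0.5, alpha_V = 1,
                   nu_e = 4, V_e = 0.5)  # sd-2 coefficients, tame variances
  st <- mcmc_settings(nitt = 80000, thin = 20, burnin = 5000, seed = 17)
  fit <- fit_mcmc(rpois(n, 2), X, rep(0, n), A, priors = pr,
                  settings = st, likelihood = FALSE)
  b <- fit$chains[, 1:2]
  # mean 0, sd 2 within Monte-Carlo error of the (autocorrelated) chain
  for (j in 1:2) {
    ess <- max(compute_ess(b[, j]), 10)
    expect_lt(abs(mean(b[, j])), 4 * 2 / sqrt(ess))
    expect_lt(abs(sd(b[, j]) - 2), 0.5)
  }
})

test_that("with variances pinned near zero the fit approaches the GLM MLE", {
  tr <- bd_fixture(lo = 80, hi = 200, seed_from = 9L)
  sim <- simulate_glmm_counts(tr, beta = c(1, 0.03), sig2_a = 0, sig2_e = 0,
                              form = "null", seed = 12)
  d <- build_design(sim$time_elapsed, model_spec("null"))
  A <- phylo_vcv(tr)
  st <- mcmc_settings(nitt = 60000, thin = 100, burnin = 10000, seed = 13)
  fit <- fit_mcmc(sim$count, d$X, d$offset, A, settings = st,
                  fix_sig2_a = 1e-4, fix_sig2_e = 1e-4)
  mle <- glm(sim$count ~ sim$time_elapsed, family = poisson)
  pm <- colMeans(fit$chains[, 1:2])
  psd <- apply(fit$chains[, 1:2], 2, sd)
  expect_lt(abs(pm[1] - coef(mle)[1]), 2 * max(psd[1], summary(mle)$coef[1, 2]))
  expect_lt(abs(pm[2] - coef(mle)[2]), 2 * max(psd[2], summary(mle)$coef[2, 2]))
  # fixed variances really are fixed
  expect_equal(unique(fit$chains[, "sig2_a"]), 1e-4)
  expect_equal(unique(fit$chains[, "sig2_e"]), 1e-4)
})

test_that("jointly permuting taxa leaves DIC statistically unchanged", {
  tr <- bd_fixture(lo = 50, hi = 120, seed_from = 9L)
  sim <- simulate_glmm_counts(tr, beta = c(0.8, 0.03), sig2_a = 0.05,
                              sig2_e = 0.05, form = "null", seed = 3)
  d <- build_design(sim$time_elapsed, model_spec("null"))
  A <- phylo_vcv(tr)
  st <- function(seed) mcmc_settings(nitt = 40000, thin = 80,
                                     burnin = 8000, seed = seed)
  base1 <- fit_mcmc(sim$count, d$X, d$offset, A, settings = st(1))$DIC
  base2 <- fit_mcmc(sim$count, d$X, d$offset, A, settings = st(2))$DIC
  set.seed(4)
  pp <- sample(nrow(A))
  perm <- fit_mcmc(sim$count[pp], d$X[pp, , drop = FALSE], d$offset[pp],
                   A[pp, pp], settings = st(3))$DIC
  mc_spread <- max(abs(base1 - base2), 1)
  expect_lt(abs(perm - (base1 + base2) / 2), 5 * mc_spread)
})

test_that("A must be positive semi-definite", {
  y <- c(1, 2, 3)
  X <- cbind(1, 1:3)
  Abad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)  # eigenvalue -1
  expect_error(fit_mcmc(y, X, rep(0, 3), Abad), "eigenvalue")
})
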