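# Shared fixtures and independent oracles for the test suite.

# random valid parameter sets in moderate, well-conditioned ranges
rand_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    mu = runif(n, -2, 2),
    sigma = runif(n, 0.3, 2.5),
    k = runif(n, 0.3, 4),
    lambda = runif(n, 0.5, 5))
}

# independent textbook logit-normal formulas (the k = 1, lambda = 1 special
# case), written directly from the change of variables x = plogis(t)
ref_logitnorm_pdf <- function(x, mu, sigma) {
  stats::dnorm(stats::qlogis(x), mu, sigma) / (x * (1 - x))
}
ref_logitnorm_cdf <- function(x, mu, sigma) {
  stats::pnorm((stats::qlogis(x) - mu) / sigma)
}
ref_logitnorm_q <- function(p, mu, sigma) {
  stats::plogis(mu + sigma * stats::qnorm(p))
}

# log-likelihood written independently from the density formula (plain
# arithmetic, no shared code with the package internals); test data stay away
# from the support boundary so naive evaluation is accurate
oracle_loglik <- function(x, mu, sigma, k, lambda) {
  w <- log(x^k / (lambda^k - x^k))
  sum(log(k) + k * log(lambda) - log(x) - log(lambda^k - x^k) -
        0.5 * log(2 * pi * sigma^2) - (w - mu)^2 / (2 * sigma^2))
}

# brute-force maximum-likelihood oracle: coarse 3-d grid over
# (mu, log sigma, log k), then Nelder-Mead polish of the best grid point
oracle_mle_loglik <- function(x, lambda) {
  grid <- expand.grid(mu = seq(-3, 3, length.out = 7),
                      lsig = log(seq(0.3, 3, length.out = 7)),
                      lk = log(exp(seq(log(0.1), log(10), length.out = 9))))
  vals <- apply(grid, 1, function(g)
    oracle_loglik(x, g[1], exp(g[2]), exp(g[3]), lambda))
  start <- as.numeric(grid[which.max(vals), ])
  opt <- stats::optim(start, function(th)
    -oracle_loglik(x, th[1], exp(th[2]), exp(th[3]), lambda),
    method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 20000))
  -opt$value
}

# identity-link Gaussian regression fitted by least squares, reported in the
# same goodness-of-fit format as the NPLD regression model
gaussian_glm_report <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  mu <- fit$fitted.values
  sigma <- sqrt(mean(fit$residuals^2))
  ll <- sum(stats::dnorm(y, mu, sigma, log = TRUE))
  u <- stats::pnorm((y - mu) / sigma)
  npld_gof_report(y, mu, u, neg_loglik = -ll, n_params = ncol(X) + 1)
}

# bimodal bounded-response regression fixture used by the model-comparison
# checks: one covariate, large transformed-scale noise pushes mass toward both
# support boundaries
bimodal_fixture <- function(n = 300, seed = 101) {
  synth_npld_regression(n = n, coefficients = c(-1.5, 3), sigma = 2,
                        k = 1, lambda = 2,
                        covariate_law = list(c(0, 1)), seed = seed)
}
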