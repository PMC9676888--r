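#' Log-likelihood of an NPLD sample
#'
#' Sum of the log-density over the sample. Every observation must lie strictly
#' inside `(0, lambda)`; the first offending index is named in the error.
#'
#' @param x Numeric sample.
#' @param params An [npld_params()] object.
#' @return A single numeric value.
#' @examples
#' npld_loglik(0.5, npld_params(0, 1, 1, 1))  # log(4 / sqrt(2 * pi))
#' @export
npld_loglik <- function(x, params) {
  p <- as_npld_params(params)
  check_support(x, p$lambda)
  sum(dnpld(x, p$mu, p$sigma, p$k, p$lambda, log = TRUE))
}

check_support <- function(x, lambda) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  bad <- which(is.na(x) | x <= 0 | x >= lambda)
  if (length(bad))
    stop(sprintf(
      "support violation: observation %d (value %s) is not inside (0, %g)",
      bad[1], format(x[bad[1]]), lambda), call. = FALSE)
  invisible(TRUE)
}

#' Plug-in estimate of the upper bound lambda
#'
#' The upper bound cannot be estimated by maximum likelihood (the likelihood
#' is unbounded in `lambda` at the sample maximum), so it is fixed from the
#' data as `max(x) + epsilon` for a small user-chosen offset
#' `0 < epsilon < 1`.
#'
#' @param x Numeric sample (non-empty, positive).
#' @param epsilon Offset, in `(0, 1)`; default `1e-3`.
#' @return Numeric scalar strictly greater than every observation.
#' @examples
#' npld_lambda_hat(c(0.2, 0.9, 1.4))  # 1.401
#' @export
npld_lambda_hat <- function(x, epsilon = 1e-3) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (!is.numeric(epsilon) || length(epsilon) != 1L || is.na(epsilon) ||
      epsilon <= 0 || epsilon >= 1)
    stop("'epsilon' must lie in (0, 1)", call. = FALSE)
  max(x) + epsilon
}

#' Moment-based starting value for the shape exponent k
#'
#' Treats the sample as if it came from the power-function baseline with cdf
#' `(x / lambda)^k`, whose moment estimator is `k0 = xbar / (lambda - xbar)`.
#' Used to start the one-dimensional profile-likelihood search.
#'
#' @param x Numeric sample with mean strictly below `lambda`.
#' @param lambda Upper bound.
#' @return Positive numeric scalar.
#' @examples
#' npld_initial_k(c(0.5, 1, 1.5), lambda = 2)  # 1
#' @export
npld_initial_k <- function(x, lambda) {
  xbar <- mean(x)
  if (!is.finite(xbar) || xbar >= lambda)
    stop("sample mean must be strictly below 'lambda'", call. = FALSE)
  if (xbar <= 0) stop("sample mean must be positive", call. = FALSE)
  xbar / (lambda - xbar)
}

#' Profile maximizers of mu and sigma for fixed k and lambda
#'
#' For fixed `(k, lambda)` the transformed values `w_i` are Gaussian, so the
#' likelihood is maximized in closed form by `mu = mean(w)` and
#' `sigma = sqrt(mean((w - mu)^2))` (the divide-by-n maximum-likelihood scale).
#'
#' @param x Numeric sample, all values in `(0, lambda)`, length at least 2.
#' @param k Shape exponent, `> 0`.
#' @param lambda Upper bound.
#' @return Named numeric vector `c(mu, sigma)`.
#' @examples
#' npld_profile_musigma(plogis(c(-1, 0, 1)), k = 1, lambda = 1)
#' @export
npld_profile_musigma <- function(x, k, lambda) {
  if (length(x) < 2)
    stop("at least two observations are required to estimate sigma",
         call. = FALSE)
  check_npld_params(0, 1, k, lambda)
  check_support(x, lambda)
  w <- npld_w(x, k, lambda)
  mu <- mean(w)
  c(mu = mu, sigma = sqrt(mean((w - mu)^2)))
}

#' Score (gradient) of the NPLD log-likelihood in (mu, sigma, k)
#'
#' Analytic partial derivatives of the log-likelihood with `lambda` held
#' fixed. At the profile estimates the `mu` and `sigma` components vanish
#' exactly; the `k` component vanishes at an interior maximum of the profile
#' likelihood.
#'
#' @inheritParams npld_loglik
#' @return Named numeric vector `c(mu, sigma, k)`.
#' @export
npld_score <- function(x, params) {
  p <- as_npld_params(params)
  check_support(x, p$lambda)
  n <- length(x)
  u <- p$k * (log(x) - log(p$lambda))
  w <- u - log(-expm1(u))
  # d w / d k = (log x - log lambda) * lambda^k / (lambda^k - x^k)
  dw <- (log(x) - log(p$lambda)) / (-expm1(u))
  # (lambda^k log lambda - x^k log x) / (lambda^k - x^k)
  tail_term <- log(p$lambda) / (-expm1(u)) - log(x) * exp(w)
  c(mu = sum(w - p$mu) / p$sigma^2,
    sigma = -n / p$sigma + sum((w - p$mu)^2) / p$sigma^3,
    k = n / p$k + n * log(p$lambda) - sum((w - p$mu) * dw) / p$sigma^2 -
      sum(tail_term))
}

#' Maximum-likelihood fit of the NPLD
#'
#' Fits `(mu, sigma, k)` by profile likelihood: `lambda` is fixed first
#' (plug-in `max(x) + epsilon`, or a user-supplied value); for each `k` the
#' closed-form maximizers of `mu` and `sigma` are substituted, and the
#' resulting one-dimensional profile log-likelihood is maximized over `k` by a
#' derivative-free bracketing search (expanding bracket on the log scale
#' started at the power-function moment estimate, refined by Brent's method).
#'
#' Standard errors for a single-sample fit are not computed (`NA`); interval
#' estimates based on the error-bound construction are produced by
#' [npld_simstudy()], where the dispersion of the estimator across replicates
#' is observable.
#'
#' @param x Numeric sample of positive values.
#' @param epsilon Offset used by the `lambda` plug-in; see [npld_lambda_hat()].
#' @param lambda Optional fixed value for `lambda`; when supplied, the plug-in
#'   is skipped (all observations must lie strictly below it).
#' @param k_bounds Positive search interval for `k`; default `c(1e-4, 1e4)`.
#' @param tol Relative convergence tolerance of the `k` search; default `1e-8`.
#' @return An object of class `"npld_fit"`: a list with components `params`
#'   (an [npld_params()] object holding the estimates), `loglik`, `converged`,
#'   `n`, `se` and `ci` (both `NA` for single-sample fits), `lambda_fixed`.
#' @examples
#' x <- rnpld(500, mu = 1, sigma = 1, k = 2, lambda = 2, seed = 42)
#' fit <- npld_mle(x, lambda = 2)
#' fit
#' @export
npld_mle <- function(x, epsilon = 1e-3, lambda = NULL,
                     k_bounds = c(1e-4, 1e4), tol = 1e-8) {
  if (!length(x)) stop("empty sample", call. = FALSE)
  if (length(x) < 2)
    stop("at least two observations are required", call. = FALSE)
  if (any(is.na(x) | x <= 0))
    stop("all observations must be positive", call. = FALSE)
  if (!is.numeric(k_bounds) || length(k_bounds) != 2L || k_bounds[1] <= 0 ||
      k_bounds[2] <= k_bounds[1])
    stop("'k_bounds' must be an increasing positive interval", call. = FALSE)
  lambda_fixed <- !is.null(lambda)
  lam <- if (lambda_fixed) lambda else npld_lambda_hat(x, epsilon)
  check_support(x, lam)

  prof <- function(log_k) {
    k <- exp(log_k)
    ms <- npld_profile_musigma(x, k, lam)
    if (ms[["sigma"]] <= 0) return(-Inf)
    npld_loglik(x, list(mu = ms[["mu"]], sigma = ms[["sigma"]],
                        k = k, lambda = lam))
  }

  # degenerate sample: all transformed values identical => sigma-hat = 0
  k0 <- min(max(npld_initial_k(x, lam), k_bounds[1]), k_bounds[2])
  w0 <- npld_w(x, k0, lam)
  if (stats::sd(w0) < .Machine$double.eps^0.5 * max(1, abs(mean(w0))))
    stop("degenerate sample: transformed values have zero dispersion, ",
         "sigma cannot be estimated", call. = FALSE)

  lo_bound <- log(k_bounds[1]); hi_bound <- log(k_bounds[2])
  # expand a bracket around log(k0) until the profile decreases on both sides
  ctr <- min(max(log(k0), lo_bound), hi_bound)
  step <- 1
  lo <- max(ctr - step, lo_bound); hi <- min(ctr + step, hi_bound)
  f_ctr <- prof(ctr)
  for (i in 1:60) {
    at_lo <- lo <= lo_bound; at_hi <- hi >= hi_bound
    f_lo <- prof(lo); f_hi <- prof(hi)
    if ((f_lo < f_ctr || at_lo) && (f_hi < f_ctr || at_hi)) break
    if (f_lo >= f_ctr) { ctr <- lo; f_ctr <- f_lo }
    if (f_hi >= f_ctr) { ctr <- hi; f_ctr <- f_hi }
    step <- step * 2
    lo <- max(ctr - step, lo_bound); hi <- min(ctr + step, hi_bound)
  }
  opt <- stats::optimize(prof, interval = c(lo, hi), maximum = TRUE,
                         tol = tol)
  k_hat <- exp(opt$maximum)
  ms <- npld_profile_musigma(x, k_hat, lam)
  est <- npld_params(ms[["mu"]], ms[["sigma"]], k_hat, lam)
  at_bound <- (opt$maximum - lo_bound) < 1e-6 || (hi_bound - opt$maximum) < 1e-6
  if (at_bound)
    warning("k search terminated at a bound of 'k_bounds'; ",
            "estimate may not be a stationary point", call. = FALSE)
  structure(list(
    params = est,
    loglik = npld_loglik(x, est),
    converged = !at_bound,
    n = length(x),
    se = c(mu = NA_real_, sigma = NA_real_, k = NA_real_),
    ci = NULL,
    lambda_fixed = lambda_fixed,
    epsilon = if (lambda_fixed) NA_real_ else epsilon
  ), class = "npld_fit")
}

#' @export
print.npld_fit <- function(x, ...) {
  cat("Maximum-likelihood fit of the Normal-Power{Logistic} distribution\n")
  cat(sprintf("  n = %d, log-likelihood = %.6g, converged = %s\n",
              x$n, x$loglik, x$converged))
  cat(sprintf("  mu = %.6g, sigma = %.6g, k = %.6g\n",
              x$params$mu, x$params$sigma, x$params$k))
  cat(sprintf("  lambda = %.6g (%s)\n", x$params$lambda,
              if (x$lambda_fixed) "fixed" else
                sprintf("plug-in max(x) + %g", x$epsilon)))
  invisible(x)
}

#' @export
coef.npld_fit <- function(object, ...) {
  unlist(object$params[c("mu", "sigma", "k", "lambda")])
}

#' @export
logLik.npld_fit <- function(object, ...) {
  structure(object$loglik, df = 3L, nobs = object$n, class = "logLik")
}

#' Standard quantile function used in the error-bound construction
#'
#' The `k = sigma = 1`, `mu = 0` specialization of the NPLD quantile function,
#' `Q*(p) = lambda * e^{z_p} / (1 + e^{z_p})` with `z_p` the standard-normal
#' quantile. `lambda` acts here as a regulator chosen by the analyst (1, 2 or
#' 3 in practice) that scales how wide the error bound is.
#'
#' @param p Probability strictly inside `(0, 1)`.
#' @param lambda Positive regulator; default 2.
#' @return Numeric vector, strictly inside `(0, lambda)`.
#' @examples
#' npld_standard_quantile(0.5, 2)   # 1
#' npld_standard_quantile(0.95, 2)  # ~1.676, the 95% interval multiplier
#' @export
npld_standard_quantile <- function(p, lambda = 2) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.numeric(lambda) || any(lambda <= 0))
    stop("'lambda' must be positive", call. = FALSE)
  lambda * stats::plogis(stats::qnorm(p))
}

#' Error-bound confidence interval for a generic parameter
#'
#' Interval `theta_hat +/- B` with error bound
#' `B = Q*(1 - alpha) * se`, where `Q*` is [npld_standard_quantile()] with
#' regulator `lambda`. With `alpha = 0.05` and `lambda = 2` the multiplier is
#' about 1.676 (slightly tighter than the Gaussian 1.96).
#'
#' @param theta_hat Point estimate.
#' @param se Standard error, `>= 0`.
#' @param alpha Significance level in `(0, 1)`; default 0.05.
#' @param lambda Regulator passed to [npld_standard_quantile()]; default 2.
#' @return Numeric vector `c(lower, upper)`.
#' @examples
#' npld_confint(0.5, se = 0.01)
#' @export
npld_confint <- function(theta_hat, se, alpha = 0.05, lambda = 2) {
  if (!is.numeric(se) || any(is.na(se)) || any(se < 0))
    stop("'se' must be non-negative", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  b <- npld_standard_quantile(1 - alpha, lambda) * se
  c(lower = theta_hat - b, upper = theta_hat + b)
}
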