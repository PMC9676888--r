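#' Plug-in estimates of the response bounds for the NPLD regression model
#'
#' Fixes the upper bound and shape exponent from the response alone:
#' `lambda = max(y) + sd(y)/sqrt(n)` (the sample maximum pushed up by the
#' standard error of the mean, so every observation stays strictly interior)
#' and `k = ybar / (lambda - ybar)`, the power-function moment estimate.
#'
#' @param y Positive numeric response, length at least 2, not constant.
#' @return Named numeric vector `c(k, lambda)`.
#' @examples
#' npld_response_bounds(c(1, 2, 3))  # lambda = 3 + 1/sqrt(3), k ~ 1.268
#' @export
npld_response_bounds <- function(y) {
  if (length(y) < 2) stop("at least two observations required", call. = FALSE)
  if (any(is.na(y) | y <= 0))
    stop("all response values must be positive", call. = FALSE)
  se_y <- stats::sd(y) / sqrt(length(y))
  if (se_y == 0)
    stop("degenerate response: constant y gives a zero offset and a closed ",
         "support bound", call. = FALSE)
  lam <- max(y) + se_y
  c(k = mean(y) / (lam - mean(y)), lambda = lam)
}

#' Inverse link of the NPLD regression model
#'
#' Maps linear-predictor values back to the response scale:
#' `y = lambda * (e^eta / (1 + e^eta))^(1/k)`. Strictly increasing, with range
#' `(0, lambda)`; identical to [npld_inverse_transform()].
#'
#' @param eta Numeric vector of linear-predictor values.
#' @param k Shape exponent, `> 0`.
#' @param lambda Upper bound, `> 0`.
#' @return Numeric vector in `(0, lambda)`.
#' @examples
#' npld_inverse_link(0, k = 1, lambda = 2)  # 1
#' @export
npld_inverse_link <- function(eta, k, lambda) {
  npld_inverse_transform(eta, k = k, lambda = lambda)
}

#' Joint sufficient statistics for (mu, sigma) on the transformed scale
#'
#' On the Gaussian scale the NPLD is an exponential-family model whose joint
#' sufficient statistics for the location and scale are `sum(w)` and
#' `sum(w^2)`; two samples sharing these (and `n`) yield identical profile
#' estimates of `mu` and `sigma`.
#'
#' @param y Response values strictly inside `(0, lambda)`.
#' @inheritParams npld_inverse_link
#' @return Named numeric vector `c(sum_w, sum_w_sq)`.
#' @export
npld_sufficient_stats <- function(y, k, lambda) {
  w <- npld_transform(y, k = k, lambda = lambda)
  c(sum_w = sum(w), sum_w_sq = sum(w^2))
}

#' Gaussian log-likelihood of the NPLD regression model on the w scale
#'
#' With `w_i = log(y_i^k / (lambda^k - y_i^k))` and linear predictor
#' `mu_i = x_i' B`, the conditional model is `w_i ~ Normal(mu_i, sigma)`, so
#' the log-likelihood is the Gaussian log-density sum
#' `sum(dnorm(w, X B, sigma, log = TRUE))`. Maximizing it over `B` is ordinary
#' least squares of `w` on `X`, which is why the coefficient estimator has the
#' closed form `(X'X)^{-1} X' w`.
#'
#' @param X Design matrix (including the intercept column).
#' @param y Response vector, strictly inside `(0, lambda)`.
#' @param B Coefficient vector of length `ncol(X)`.
#' @param sigma Residual scale on the w scale, `> 0`.
#' @inheritParams npld_inverse_link
#' @return A single numeric value.
#' @export
npld_glm_loglik <- function(X, y, B, sigma, k, lambda) {
  X <- as.matrix(X)
  if (length(B) != ncol(X))
    stop("length of 'B' must match ncol(X)", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be positive", call. = FALSE)
  w <- npld_transform(y, k = k, lambda = lambda)
  sum(stats::dnorm(w, drop(X %*% B), sigma, log = TRUE))
}

# y-scale log-density sum: the full NPLD density with per-observation location,
# used for goodness-of-fit comparison across models fitted to the same data
npld_glm_loglik_response <- function(X, y, B, sigma, k, lambda) {
  eta <- drop(as.matrix(X) %*% B)
  sum(dnpld(y, mu = eta, sigma = sigma, k = k, lambda = lambda, log = TRUE))
}

npld_glm_fit_core <- function(X, y, k, lambda, w_clip = 700) {
  X <- as.matrix(X)
  n <- nrow(X); pp <- ncol(X)
  if (length(y) != n) stop("length of 'y' must match nrow(X)", call. = FALSE)
  if (n <= pp)
    stop("too few observations: need n > ncol(X)", call. = FALSE)
  if (qr(X)$rank < pp)
    stop("singular design: X is rank deficient", call. = FALSE)
  check_support(y, lambda)
  w <- npld_transform(y, k = k, lambda = lambda)
  if (any(abs(w) > w_clip)) {
    warning("transformed responses beyond +/-", w_clip,
            " clipped before the linear algebra", call. = FALSE)
    w <- pmin(pmax(w, -w_clip), w_clip)
  }
  # closed-form estimator B = (X'X)^{-1} X' w
  B <- drop(solve(crossprod(X), crossprod(X, w)))
  eta <- drop(X %*% B)
  resid <- w - eta
  sigma <- sqrt(mean(resid^2))  # maximum-likelihood (divide-by-n) scale
  list(B = B, eta = eta, w = w, sigma = sigma)
}

#' Fit the NPLD generalized linear model
#'
#' Regression for a bounded response assumed NPLD. The response is mapped to
#' the Gaussian scale by the normalizing transform with plug-in `(k, lambda)`
#' (estimated from the response by [npld_response_bounds()] unless fixed), and
#' the coefficients are the closed-form estimator
#' `B = (X'X)^{-1} X' w` — ordinary least squares of the transformed response
#' on the design. Fitted values on the response scale come back through
#' [npld_inverse_link()]. Coefficient standard errors and p-values use
#' Gaussian theory on the w scale with the maximum-likelihood residual scale.
#'
#' @param formula Model formula; the intercept is included unless removed in
#'   the formula.
#' @param data Data frame holding the response and covariates.
#' @param k,lambda Optional fixed plug-in values; estimated from the response
#'   when `NULL` (default).
#' @param w_clip Clipping bound for extreme transformed responses
#'   (default 700); prevents infinite leverage when an observation sits
#'   numerically at the support boundary.
#' @param x Object for printing.
#' @param object Fitted model.
#' @param newdata Data frame (or design matrix with the fitted columns) for
#'   prediction.
#' @param ... Unused.
#' @return An object of class `"npld_glm"`: list with `coefficients`, `se`,
#'   `p_value`, `k`, `lambda`, `sigma`, `eta` (linear predictor),
#'   `fitted_response`, `loglik` (w-scale Gaussian value),
#'   `loglik_response` (full NPLD density on the y scale, used by the GoF
#'   block), `gof` (a [npld_gof_report()]), plus bookkeeping (`terms`,
#'   `X`, `y`, `n`).
#' @examples
#' dat <- synth_npld_regression(n = 200, coefficients = c(0.5, 1),
#'                              sigma = 1, k = 1.5, lambda = 2, seed = 7)
#' fit <- npld_glm(y ~ x1, data = dat$data)
#' coef(fit)
#' @export
npld_glm <- function(formula, data, k = NULL, lambda = NULL, w_clip = 700) {
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)
  fit <- npld_glm_fit(X, y, k = k, lambda = lambda, w_clip = w_clip)
  fit$terms <- attr(mf, "terms")
  fit$call <- match.call()
  fit
}

#' @rdname npld_glm
#' @param X Design matrix including an explicit intercept column of ones
#'   (for the matrix interface).
#' @param y Positive bounded response vector.
#' @export
npld_glm_fit <- function(X, y, k = NULL, lambda = NULL, w_clip = 700) {
  X <- as.matrix(X)
  if ((is.null(k) || is.null(lambda))) {
    kl <- npld_response_bounds(y)
    if (is.null(k)) k <- kl[["k"]]
    if (is.null(lambda)) lambda <- kl[["lambda"]]
  }
  check_npld_params(0, 1, k, lambda)
  core <- npld_glm_fit_core(X, y, k, lambda, w_clip = w_clip)
  n <- nrow(X)
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(diag(xtx_inv)) * core$sigma
  zval <- core$B / se
  fitted_y <- npld_inverse_link(core$eta, k, lambda)
  sig_eff <- max(core$sigma, 1e-300)  # keep the likelihood defined at sigma = 0
  ll_w <- sum(stats::dnorm(core$w, core$eta, sig_eff, log = TRUE))
  ll_y <- npld_glm_loglik_response(X, y, core$B, sig_eff, k, lambda)
  n_par <- ncol(X) + 1L  # coefficients + sigma; k, lambda are plug-ins
  # the GoF block needs a positive residual scale; a (near-)interpolating fit
  # has no residual distribution to test against
  gof <- if (core$sigma > 1e-10) {
    u <- stats::pnorm((core$w - core$eta) / core$sigma)
    npld_gof_report(y, fitted_y, u, neg_loglik = -ll_y, n_params = n_par)
  } else NULL
  structure(list(
    coefficients = core$B, se = se, p_value = 2 * stats::pnorm(-abs(zval)),
    k = k, lambda = lambda, sigma = core$sigma,
    eta = core$eta, fitted_response = fitted_y,
    loglik = ll_w, loglik_response = ll_y, n_params = n_par,
    gof = gof, X = X, y = y, n = n
  ), class = "npld_glm")
}

#' @rdname npld_glm
#' @export
print.npld_glm <- function(x, ...) {
  cat("NPLD generalized linear model\n")
  cat(sprintf("  n = %d, plug-ins: k = %.4g, lambda = %.4g; sigma = %.4g\n",
              x$n, x$k, x$lambda, x$sigma))
  tab <- cbind(Estimate = x$coefficients, `Std. Error` = x$se,
               `p value` = x$p_value)
  print(tab, digits = 5)
  cat(sprintf("  log-likelihood (w scale) = %.6g, (response scale) = %.6g\n",
              x$loglik, x$loglik_response))
  invisible(x)
}

#' @export
coef.npld_glm <- function(object, ...) object$coefficients

#' @export
fitted.npld_glm <- function(object, ...) object$fitted_response

#' @export
logLik.npld_glm <- function(object, ...) {
  structure(object$loglik_response, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @rdname npld_glm
#' @export
predict.npld_glm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_response)
  if (is.matrix(newdata)) {
    X_new <- newdata
  } else if (!is.null(object$terms)) {
    tt <- stats::delete.response(object$terms)
    X_new <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  } else {
    X_new <- as.matrix(newdata)
  }
  if (ncol(X_new) != length(object$coefficients))
    stop(sprintf("newdata has %d columns; the model was fitted with %d",
                 ncol(X_new), length(object$coefficients)), call. = FALSE)
  npld_inverse_link(drop(X_new %*% object$coefficients),
                    object$k, object$lambda)
}
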