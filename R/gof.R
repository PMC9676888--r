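#' One-sample empirical-distribution goodness-of-fit statistics
#'
#' Standard one-sample statistics computed from the model cdf evaluated at the
#' (sorted) observations, `u_i = F(x_(i))`:
#' * Kolmogorov-Smirnov: `D = max_i max(i/n - u_i, u_i - (i-1)/n)`;
#' * Anderson-Darling:
#'   `A2 = -n - (1/n) sum (2i - 1) (log u_i + log(1 - u_(n+1-i)))`;
#' * Cramer-von Mises: `W2 = 1/(12n) + sum (u_i - (2i-1)/(2n))^2`;
#' * chi-square: `sum (O_j - E_j)^2 / E_j` over equiprobable bins defined by
#'   model quantiles (equivalently, equal-width bins of the `u_i`).
#'
#' `cdf_eval` may be a function mapping observations to model cdf values, or a
#' numeric vector of the same length as `sample` containing those values
#' directly (useful for regression models, where the conditional cdf differs
#' per observation).
#'
#' @param sample Non-empty numeric sample.
#' @param cdf_eval Model cdf: function of the observations, or a numeric
#'   vector of cdf values in `[0, 1]`.
#' @param n_bins Number of equiprobable bins for the chi-square statistic
#'   (at least 2); default `max(4, floor(n / 15))`.
#' @return A single numeric value.
#' @examples
#' x <- rnorm(50)
#' gof_ks(x, pnorm)
#' gof_ad(x, pnorm)
#' gof_cvm(x, pnorm)
#' gof_chisq(x, pnorm)
#' @name gof-statistics
NULL

gof_u <- function(sample, cdf_eval, open = FALSE) {
  if (!length(sample)) stop("empty sample", call. = FALSE)
  u <- if (is.function(cdf_eval)) cdf_eval(sample) else cdf_eval
  if (length(u) != length(sample))
    stop("'cdf_eval' values must match the sample length", call. = FALSE)
  if (anyNA(u) || any(u < 0) || any(u > 1))
    stop("'cdf_eval' must produce values in [0, 1]", call. = FALSE)
  u <- sort(u)
  if (open && any(u == 0 | u == 1))
    stop("cdf values of exactly 0 or 1 make the statistic diverge ",
         "(log of zero)", call. = FALSE)
  u
}

#' @rdname gof-statistics
#' @export
gof_ks <- function(sample, cdf_eval) {
  u <- gof_u(sample, cdf_eval)
  n <- length(u)
  i <- seq_len(n)
  max(pmax(i / n - u, u - (i - 1) / n))
}

#' @rdname gof-statistics
#' @export
gof_ad <- function(sample, cdf_eval) {
  u <- gof_u(sample, cdf_eval, open = TRUE)
  n <- length(u)
  i <- seq_len(n)
  -n - mean((2 * i - 1) * (log(u) + log(1 - rev(u))))
}

#' @rdname gof-statistics
#' @export
gof_cvm <- function(sample, cdf_eval) {
  u <- gof_u(sample, cdf_eval)
  n <- length(u)
  i <- seq_len(n)
  1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
}

#' @rdname gof-statistics
#' @export
gof_chisq <- function(sample, cdf_eval, n_bins = NULL) {
  u <- gof_u(sample, cdf_eval)
  n <- length(u)
  if (is.null(n_bins)) n_bins <- max(2, min(max(4, floor(n / 15)), n))
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 2)
    stop("'n_bins' must be an integer of at least 2", call. = FALSE)
  expected <- n / n_bins
  if (expected < 1)
    stop("expected count per bin below 1; use fewer bins", call. = FALSE)
  observed <- tabulate(pmin(floor(u * n_bins) + 1L, n_bins), nbins = n_bins)
  sum((observed - expected)^2 / expected)
}

#' Akaike information criterion from a negative log-likelihood
#'
#' `AIC = 2 * n_params + 2 * neg_loglik`.
#'
#' @param neg_loglik Negative maximized log-likelihood.
#' @param n_params Number of free parameters (at least 1).
#' @return A single numeric value.
#' @examples
#' gof_aic(0, 3)  # 6
#' @export
gof_aic <- function(neg_loglik, n_params) {
  if (!is.numeric(n_params) || length(n_params) != 1L || n_params < 1)
    stop("'n_params' must be at least 1", call. = FALSE)
  2 * n_params + 2 * neg_loglik
}

#' Assemble the goodness-of-fit report for a fitted model
#'
#' Bundles the criteria used to rank competing fits of the same data: negative
#' log-likelihood, AIC, the one-sample statistics D, A2, W2 and chi-square
#' (computed from the model cdf values of the observations), and the Pearson
#' correlation between the observed and predicted responses. Lower is better
#' on every criterion except the correlation, where higher is better.
#'
#' @param y Observed response.
#' @param y_hat Predicted response, same length as `y`.
#' @param cdf_eval Model cdf values of the observations (vector), or a
#'   function of `y`; see [gof_ks()].
#' @param neg_loglik Negative maximized log-likelihood of the fit.
#' @param n_params Number of free parameters used for the AIC.
#' @param n_bins Optional chi-square bin count; see [gof_chisq()].
#' @return An object of class `"npld_gof"`: list with fields `neg_loglik`,
#'   `aic`, `ks_D`, `ad_A`, `cvm_omega`, `chi_square`, `correlation`.
#' @export
npld_gof_report <- function(y, y_hat, cdf_eval, neg_loglik, n_params,
                            n_bins = NULL) {
  if (length(y) != length(y_hat))
    stop("'y' and 'y_hat' must have the same length", call. = FALSE)
  if (stats::sd(y_hat) == 0)
    stop("correlation undefined: predictions have zero variance",
         call. = FALSE)
  structure(list(
    neg_loglik = neg_loglik,
    aic = gof_aic(neg_loglik, n_params),
    ks_D = gof_ks(y, cdf_eval),
    ad_A = gof_ad(y, cdf_eval),
    cvm_omega = gof_cvm(y, cdf_eval),
    chi_square = gof_chisq(y, cdf_eval, n_bins = n_bins),
    correlation = stats::cor(y, y_hat)
  ), class = "npld_gof")
}

#' @export
print.npld_gof <- function(x, ...) {
  cat("Goodness-of-fit report\n")
  cat(sprintf("  -logL = %.6g, AIC = %.6g\n", x$neg_loglik, x$aic))
  cat(sprintf("  KS D = %.4g, AD A2 = %.4g, CvM W2 = %.4g, chi2 = %.4g\n",
              x$ks_D, x$ad_A, x$cvm_omega, x$chi_square))
  cat(sprintf("  cor(y, y_hat) = %.4g\n", x$correlation))
  invisible(x)
}
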