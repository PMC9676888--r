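#' Parameter set of the Normal-Power{Logistic} distribution
#'
#' Bundles and validates the four NPLD parameters. The distribution lives on
#' the open interval `(0, lambda)`; its log-odds-of-power transform
#' `w = log(x^k / (lambda^k - x^k))` is Gaussian with mean `mu` and standard
#' deviation `sigma`.
#'
#' @param mu Location on the transformed scale; any finite real.
#' @param sigma Scale on the transformed scale; finite real `> 0`.
#' @param k Shape exponent; finite real `> 0`.
#' @param lambda Upper support bound; finite real `> 0`.
#'
#' @return An object of class `"npld_params"`: a named list with components
#'   `mu`, `sigma`, `k`, `lambda`.
#'
#' @examples
#' p <- npld_params(mu = 0.5, sigma = 1, k = 2, lambda = 2)
#' p
#' @export
npld_params <- function(mu, sigma, k, lambda) {
  check_npld_params(mu, sigma, k, lambda)
  structure(list(mu = mu, sigma = sigma, k = k, lambda = lambda),
            class = "npld_params")
}

#' @export
print.npld_params <- function(x, ...) {
  cat(sprintf(
    "NPLD parameters: mu = %g, sigma = %g, k = %g, lambda = %g\n",
    x$mu, x$sigma, x$k, x$lambda))
  cat(sprintf("  support: (0, %g)\n", x$lambda))
  invisible(x)
}

#' @export
as.list.npld_params <- function(x, ...) unclass(x)

# scalar-or-vector parameter validation shared by all distribution functions
check_npld_params <- function(mu, sigma, k, lambda) {
  if (!is.numeric(mu) || anyNA(mu) || any(!is.finite(mu)))
    stop("invalid parameters: 'mu' must be finite numeric", call. = FALSE)
  if (!is.numeric(sigma) || anyNA(sigma) || any(!is.finite(sigma)) || any(sigma <= 0))
    stop("invalid parameters: 'sigma' must be finite and > 0", call. = FALSE)
  if (!is.numeric(k) || anyNA(k) || any(!is.finite(k)) || any(k <= 0))
    stop("invalid parameters: 'k' must be finite and > 0", call. = FALSE)
  if (!is.numeric(lambda) || anyNA(lambda) || any(!is.finite(lambda)) || any(lambda <= 0))
    stop("invalid parameters: 'lambda' must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

# coerce an npld_params object or 4 scalars into a plain list
as_npld_params <- function(params) {
  if (inherits(params, "npld_params")) return(unclass(params))
  if (is.list(params) &&
      all(c("mu", "sigma", "k", "lambda") %in% names(params))) {
    check_npld_params(params$mu, params$sigma, params$k, params$lambda)
    return(params[c("mu", "sigma", "k", "lambda")])
  }
  stop("'params' must be an npld_params object or a named list with ",
       "mu, sigma, k, lambda", call. = FALSE)
}
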