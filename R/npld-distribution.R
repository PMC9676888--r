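#' The Normal-Power{Logistic} Distribution
#'
#' Density, distribution function, quantile function and random generation for
#' the Normal-Power{Logistic} distribution (NPLD) with location `mu`, scale
#' `sigma`, shape `k` and upper bound `lambda`.
#'
#' The NPLD is supported on the open interval `(0, lambda)`. Writing
#' `w(x) = log(x^k / (lambda^k - x^k))`, the density is
#' \deqn{f(x) = \frac{k \lambda^k}{x (\lambda^k - x^k)}
#'   \phi\!\left(\frac{w(x) - \mu}{\sigma}\right) / \sigma,}
#' the distribution function is \eqn{F(x) = \Phi((w(x) - \mu)/\sigma)}, and the
#' quantile function is
#' \deqn{Q(p) = \lambda \left\{ \frac{e^{\mu + \sigma \Phi^{-1}(p)}}
#'   {1 + e^{\mu + \sigma \Phi^{-1}(p)}} \right\}^{1/k}.}
#' For `k = 1`, `lambda = 1` the family reduces to the logit-normal
#' distribution. Depending on `sigma` and `k` the density can be unimodal,
#' U-shaped or bimodal, which makes the family useful for bounded, possibly
#' two-humped data (proportions, bounded scores, spill volumes).
#'
#' All density work is carried out in the log domain; the transform uses
#' `expm1`/`log1p`-style guards so that values of `x` very close to `0` or
#' `lambda` do not overflow.
#'
#' @param x,q Vector of quantiles.
#' @param p Vector of probabilities, strictly inside `(0, 1)` for `qnpld`
#'   (the support is open, so the quantile function is only defined there).
#' @param n Number of draws.
#' @param mu Location parameter on the transformed scale.
#' @param sigma Scale parameter on the transformed scale, `> 0`.
#' @param k Shape exponent, `> 0`.
#' @param lambda Upper support bound, `> 0`.
#' @param log,log.p Logical; if `TRUE`, probabilities/densities are given as
#'   `log(p)`.
#' @param lower.tail Logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed Optional integer. When supplied, `rnpld` draws a reproducible
#'   stream seeded from it and restores the caller's RNG state afterwards.
#'
#' @return `dnpld` gives the density (0 outside the open support), `pnpld` the
#'   distribution function (clamped to `[0, 1]`), `qnpld` the quantile
#'   function, `rnpld` generates random deviates by inverse-transform sampling.
#'
#' @examples
#' dnpld(0.5, mu = 0, sigma = 1, k = 1, lambda = 1)   # 4 / sqrt(2 * pi)
#' pnpld(0.5, mu = 0, sigma = 1, k = 1, lambda = 1)   # 0.5
#' qnpld(0.5, mu = 0.5, sigma = 1, k = 1, lambda = 2) # 2 * plogis(0.5)
#' x <- rnpld(5, mu = 1, sigma = 1, k = 2, lambda = 2, seed = 1)
#' range(x)                                           # inside (0, 2)
#' @name npld-distribution
NULL

# u = k * log(x / lambda) <= 0 for x in (0, lambda);
# w = log(x^k / (lambda^k - x^k)) = u - log(1 - e^u) = u - log(-expm1(u))
npld_w <- function(x, k, lambda) {
  u <- k * (log(x) - log(lambda))
  u - log(-expm1(u))
}

#' @rdname npld-distribution
#' @export
dnpld <- function(x, mu = 0, sigma = 1, k = 1, lambda = 1, log = FALSE) {
  check_npld_params(mu, sigma, k, lambda)
  n <- max(length(x), length(mu), length(sigma), length(k), length(lambda))
  x <- rep_len(x, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  k <- rep_len(k, n); lambda <- rep_len(lambda, n)
  out <- rep(-Inf, n)
  inside <- !is.na(x) & x > 0 & x < lambda
  if (any(inside)) {
    xi <- x[inside]; ki <- k[inside]; li <- lambda[inside]
    u <- ki * (log(xi) - log(li))
    w <- u - log(-expm1(u))
    # log f = log k - log x - log(1 - (x/lambda)^k) + log phi((w - mu)/sigma)/sigma
    out[inside] <- log(ki) - log(xi) - log(-expm1(u)) +
      stats::dnorm(w, mu[inside], sigma[inside], log = TRUE)
  }
  out[is.na(x)] <- NA_real_
  if (log) out else exp(out)
}

#' @rdname npld-distribution
#' @export
pnpld <- function(q, mu = 0, sigma = 1, k = 1, lambda = 1,
                  lower.tail = TRUE, log.p = FALSE) {
  check_npld_params(mu, sigma, k, lambda)
  n <- max(length(q), length(mu), length(sigma), length(k), length(lambda))
  q <- rep_len(q, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  k <- rep_len(k, n); lambda <- rep_len(lambda, n)
  z <- rep(NA_real_, n)
  lo <- !is.na(q) & q <= 0
  hi <- !is.na(q) & q >= lambda
  inside <- !is.na(q) & !lo & !hi
  z[lo] <- -Inf
  z[hi] <- Inf
  if (any(inside)) {
    z[inside] <- (npld_w(q[inside], k[inside], lambda[inside]) - mu[inside]) /
      sigma[inside]
  }
  stats::pnorm(z, lower.tail = lower.tail, log.p = log.p)
}

#' @rdname npld-distribution
#' @export
qnpld <- function(p, mu = 0, sigma = 1, k = 1, lambda = 1) {
  check_npld_params(mu, sigma, k, lambda)
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly inside (0, 1)", call. = FALSE)
  # lambda * plogis(mu + sigma * z)^(1/k), computed on the log scale
  eta <- mu + sigma * stats::qnorm(p)
  lambda * exp(stats::plogis(eta, log.p = TRUE) / k)
}

#' @rdname npld-distribution
#' @export
rnpld <- function(n, mu = 0, sigma = 1, k = 1, lambda = 1, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a positive integer", call. = FALSE)
  check_npld_params(mu, sigma, k, lambda)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  qnpld(stats::runif(n), mu = mu, sigma = sigma, k = k, lambda = lambda)
}

#' Survival, hazard and related functions of the NPLD
#'
#' `npld_survival` returns `1 - F(x)`, `npld_hazard` the hazard rate
#' `f(x) / (1 - F(x))`, `npld_cum_hazard` the cumulative hazard
#' `-log(1 - F(x))`, and `npld_reverse_hazard` the reverse hazard
#' `f(x) / F(x)`.
#'
#' The hazard-type ratios are only defined strictly inside the support: at a
#' boundary where both numerator and denominator vanish the ratio is `0/0` and
#' an error is signalled.
#'
#' @inheritParams npld-distribution
#' @return Numeric vector.
#' @examples
#' npld_survival(0.7, mu = 0.2, sigma = 1, k = 2, lambda = 1.5)
#' npld_hazard(0.7, mu = 0.2, sigma = 1, k = 2, lambda = 1.5)
#' @export
npld_survival <- function(x, mu = 0, sigma = 1, k = 1, lambda = 1) {
  pnpld(x, mu, sigma, k, lambda, lower.tail = FALSE)
}

check_interior <- function(x, lambda, what) {
  if (any(!is.na(x) & (x <= 0 | x >= lambda)))
    stop(what, " is only defined strictly inside the support (0, lambda): ",
         "ratio is degenerate (0/0) at or beyond the boundary", call. = FALSE)
}

#' @rdname npld_survival
#' @export
npld_hazard <- function(x, mu = 0, sigma = 1, k = 1, lambda = 1) {
  check_npld_params(mu, sigma, k, lambda)
  check_interior(x, lambda, "the hazard")
  exp(dnpld(x, mu, sigma, k, lambda, log = TRUE) -
        pnpld(x, mu, sigma, k, lambda, lower.tail = FALSE, log.p = TRUE))
}

#' @rdname npld_survival
#' @export
npld_cum_hazard <- function(x, mu = 0, sigma = 1, k = 1, lambda = 1) {
  -pnpld(x, mu, sigma, k, lambda, lower.tail = FALSE, log.p = TRUE)
}

#' @rdname npld_survival
#' @export
npld_reverse_hazard <- function(x, mu = 0, sigma = 1, k = 1, lambda = 1) {
  check_npld_params(mu, sigma, k, lambda)
  check_interior(x, lambda, "the reverse hazard")
  exp(dnpld(x, mu, sigma, k, lambda, log = TRUE) -
        pnpld(x, mu, sigma, k, lambda, log.p = TRUE))
}

#' Normalizing transformation between the data and Gaussian scales
#'
#' `npld_transform` maps observations in `(0, lambda)` to the unbounded
#' transformed scale, `w = log(x^k / (lambda^k - x^k))`; if `x` is NPLD
#' distributed, `w` is Gaussian with mean `mu` and standard deviation `sigma`.
#' `npld_inverse_transform` is the exact inverse,
#' `x = lambda * (e^w / (1 + e^w))^(1/k)`.
#'
#' @param x Values strictly inside `(0, lambda)`.
#' @param w Finite values on the transformed scale.
#' @inheritParams npld-distribution
#' @return Numeric vector.
#' @examples
#' w <- npld_transform(0.5, k = 2, lambda = 2)
#' npld_inverse_transform(w, k = 2, lambda = 2)  # 0.5
#' @export
npld_transform <- function(x, k = 1, lambda = 1) {
  check_npld_params(0, 1, k, lambda)
  if (any(!is.na(x) & (x <= 0 | x >= lambda)))
    stop("the transform is infinite at or beyond the support boundary: ",
         "all values must lie strictly inside (0, lambda)", call. = FALSE)
  npld_w(x, k, lambda)
}

#' @rdname npld_transform
#' @export
npld_inverse_transform <- function(w, k = 1, lambda = 1) {
  check_npld_params(0, 1, k, lambda)
  lambda * exp(stats::plogis(w, log.p = TRUE) / k)
}
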