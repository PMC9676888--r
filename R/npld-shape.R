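#' Quartiles and octiles of the NPLD
#'
#' Evaluates the quantile function at the quartile and octile probabilities.
#' Exact standard-normal quantiles are used throughout (e.g.
#' `qnorm(0.75) = 0.6745`, often quoted rounded as 0.68; `qnorm(0.625) =
#' 0.3186`, quoted as 0.32; `qnorm(0.875) = 1.1503`, quoted as 1.15). By
#' construction `E2 = Q1` and `E6 = Q3`.
#'
#' @param params An [npld_params()] object.
#' @return Named numeric vector with elements `Q1`, `Q2`, `Q3`, `E1`...`E7`.
#' @examples
#' npld_partition(npld_params(0, 1, 1, 1))
#' @export
npld_partition <- function(params) {
  p <- as_npld_params(params)
  q <- function(pr) qnpld(pr, p$mu, p$sigma, p$k, p$lambda)
  e <- q((1:7) / 8)
  c(Q1 = e[[2]], Q2 = q(0.5), Q3 = e[[6]],
    E1 = e[[1]], E2 = e[[2]], E3 = e[[3]], E4 = e[[4]],
    E5 = e[[5]], E6 = e[[6]], E7 = e[[7]])
}

#' Robust quantile-based shape measures of the NPLD
#'
#' `npld_skewness` returns the Bowley coefficient
#' `(Q3 + Q1 - 2 Q2) / (Q3 - Q1)`, bounded in `(-1, 1)`;
#' `npld_kurtosis` returns the Moors coefficient
#' `((E7 - E5) + (E3 - E1)) / (E6 - E2)`, always positive. Both are free of
#' `lambda`, which acts as a pure scale on every quantile.
#'
#' @param params An [npld_params()] object.
#' @return A single numeric value.
#' @examples
#' npld_skewness(npld_params(0, 1, 1, 1))    # 0 by symmetry
#' npld_kurtosis(npld_params(0.5, 1, 1, 1))
#' @export
npld_skewness <- function(params) {
  q <- npld_partition(params)
  denom <- q[["Q3"]] - q[["Q1"]]
  if (denom <= 0 || !is.finite(denom))
    stop("degenerate scale: interquartile range is not positive", call. = FALSE)
  (q[["Q3"]] + q[["Q1"]] - 2 * q[["Q2"]]) / denom
}

#' @rdname npld_skewness
#' @export
npld_kurtosis <- function(params) {
  q <- npld_partition(params)
  denom <- q[["E6"]] - q[["E2"]]
  if (denom <= 0 || !is.finite(denom))
    stop("degenerate scale: interquartile range is not positive", call. = FALSE)
  ((q[["E7"]] - q[["E5"]]) + (q[["E3"]] - q[["E1"]])) / denom
}

# stationary-point condition of the log-density, derived by differentiating
# log f(x) = log k - log x - log(lambda^k - x^k) + log phi((w - mu)/sigma):
#   g(x) = (k+1) x^k - lambda^k - (k lambda^k / sigma^2) (w(x) - mu) = 0
# scaled by x (lambda^k - x^k) > 0, so roots coincide with d f / dx = 0.
npld_mode_eq <- function(x, p) {
  w <- npld_w(x, p$k, p$lambda)
  (p$k + 1) * x^p$k - p$lambda^p$k -
    (p$k * p$lambda^p$k / p$sigma^2) * (w - p$mu)
}

#' Stationary points (modes and antimodes) of the NPLD density
#'
#' Finds all interior stationary points of the density by sign-scanning the
#' analytic stationarity condition on a dense grid and refining each bracketed
#' sign change with root finding, then classifies each root as a local maximum
#' or minimum by the sign of a second difference of the log-density. The
#' density can be unimodal, or — for large `sigma` or `k > 1` — multimodal;
#' an empty result is legal and means the density is monotone or
#' boundary-dominated (no interior stationary point).
#'
#' @param params An [npld_params()] object.
#' @param grid_n Number of grid points used for the sign scan (default 2001).
#' @return A data frame with columns `x` (root location) and `type`
#'   (`"maximum"` or `"minimum"`), possibly with zero rows.
#' @examples
#' npld_mode(npld_params(0, 1, 1, 1))   # single mode at 0.5
#' npld_mode(npld_params(0, 3, 1, 1))   # bimodal: two maxima, one antimode
#' @export
npld_mode <- function(params, grid_n = 2001) {
  p <- as_npld_params(params)
  eps <- 1e-9 * p$lambda
  xs <- seq(eps, p$lambda - eps, length.out = grid_n)
  g <- npld_mode_eq(xs, p)
  roots <- numeric(0)
  sgn <- sign(g)
  flip <- which(sgn[-1] * sgn[-grid_n] < 0)
  for (i in flip) {
    r <- stats::uniroot(npld_mode_eq, interval = c(xs[i], xs[i + 1]), p = p,
                        tol = 1e-12 * p$lambda)
    roots <- c(roots, r$root)
  }
  roots <- c(roots, xs[sgn == 0])
  if (!length(roots))
    return(data.frame(x = numeric(0), type = character(0)))
  roots <- sort(roots)
  h <- 1e-6 * p$lambda
  curv <- vapply(roots, function(r) {
    lf <- dnpld(c(r - h, r, r + h), p$mu, p$sigma, p$k, p$lambda, log = TRUE)
    lf[1] - 2 * lf[2] + lf[3]
  }, numeric(1))
  data.frame(x = roots, type = ifelse(curv < 0, "maximum", "minimum"))
}

#' Raw moments of the NPLD by quadrature
#'
#' Computes `E(X^r)` by adaptive quadrature on the Gaussian scale:
#' with `W ~ Normal(mu, sigma)`,
#' `E(X^r) = lambda^r E[plogis(W)^{r/k}]`, an integral over the real line with
#' a bounded, smooth integrand — better behaved than integrating `x^r f(x)`
#' across the support boundaries. The bounded support implies
#' `0 < E(X^r) <= lambda^r`.
#'
#' @param params An [npld_params()] object.
#' @param r Positive integer moment order.
#' @return A single numeric value.
#' @examples
#' npld_moment(npld_params(0, 1, 1, 1), 1)  # 0.5 by symmetry
#' @export
npld_moment <- function(params, r) {
  p <- as_npld_params(params)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 1 || r != round(r))
    stop("'r' must be a positive integer", call. = FALSE)
  integrand <- function(w)
    exp(r / p$k * stats::plogis(w, log.p = TRUE)) *
      stats::dnorm(w, p$mu, p$sigma)
  val <- tryCatch(
    stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-10)$value,
    error = function(e)
      stop("numerical integration of the moment failed: ",
           conditionMessage(e), call. = FALSE))
  p$lambda^r * val
}
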