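test_that("density matches closed form, vanishes outside the support, integrates to 1", {
  expect_equal(dnpld(0.5, 0, 1, 1, 1), 4 / sqrt(2 * pi), tolerance = 1e-14)
  expect_identical(dnpld(1.5, 0, 1, 1, 1), 0)
  expect_identical(dnpld(c(-1, 0, 1), 0, 1, 1, 1), c(0, 0, 0))
  expect_equal(
    stats::integrate(function(x) dnpld(x, 0.7, 1.3, 2, 3), 0, 3,
                     rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
  expect_error(dnpld(0.5, 0, -1, 1, 1), "sigma")
  expect_error(dnpld(0.5, 0, 1, 0, 1), "'k'")
})

test_that("log density is stable at the support boundaries", {
  expect_equal(exp(dnpld(0.5, 0, 1, 1, 1, log = TRUE)), dnpld(0.5, 0, 1, 1, 1))
  lf <- dnpld(1e-12, 0, 1, 1, 1, log = TRUE)
  expect_true(is.finite(lf))
  lf2 <- dnpld(1 - 1e-13, 0, 1, 1, 1, log = TRUE)
  expect_true(is.finite(lf2))
  expect_identical(dnpld(c(0, 1), 0, 1, 1, 1, log = TRUE), c(-Inf, -Inf))
})

test_that("cdf has correct boundaries, is non-decreasing, and matches density quadrature", {
  expect_equal(pnpld(0.5, 0, 1, 1, 1), 0.5, tolerance = 1e-14)
  expect_identical(pnpld(0, 1, 2, 3, 1.5), 0)
  expect_identical(pnpld(1.5, 1, 2, 3, 1.5), 1)
  expect_identical(pnpld(-3, 1, 2, 3, 1.5), 0)
  for (x0 in c(0.5, 1.0, 1.5)) {
    expect_equal(
      pnpld(x0, 1, 0.5, 3, 2),
      stats::integrate(function(t) dnpld(t, 1, 0.5, 3, 2), 0, x0,
                       rel.tol = 1e-11)$value,
      tolerance = 1e-8)
  }
  grid <- seq(0.01, 1.99, length.out = 200)
  expect_true(all(diff(pnpld(grid, 1, 0.5, 3, 2)) >= 0))
})

test_that("survival, hazard, cumulative and reverse hazard satisfy their identities", {
  pars <- rand_params(20, seed = 4)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    xs <- seq(0.05, 0.95, length.out = 20) * p$lambda
    s <- npld_survival(xs, p$mu, p$sigma, p$k, p$lambda)
    expect_equal(s + pnpld(xs, p$mu, p$sigma, p$k, p$lambda),
                 rep(1, 20), tolerance = 1e-12)
    expect_equal(npld_hazard(xs, p$mu, p$sigma, p$k, p$lambda) * s,
                 dnpld(xs, p$mu, p$sigma, p$k, p$lambda), tolerance = 1e-10)
    expect_equal(npld_reverse_hazard(xs, p$mu, p$sigma, p$k, p$lambda) *
                   pnpld(xs, p$mu, p$sigma, p$k, p$lambda),
                 dnpld(xs, p$mu, p$sigma, p$k, p$lambda), tolerance = 1e-10)
  }
  expect_equal(npld_cum_hazard(0.7, 0.2, 1, 2, 1.5),
               -log(npld_survival(0.7, 0.2, 1, 2, 1.5)), tolerance = 1e-12)
  expect_error(npld_hazard(1.5, 0, 1, 1, 1.5), "strictly inside")
  expect_error(npld_reverse_hazard(0, 0, 1, 1, 1.5), "strictly inside")
})

test_that("quantile function: closed forms, cdf roundtrip, root-finding oracle", {
  # median lambda * (e^mu / (1 + e^mu))^(1/k); at mu = 0, k = 1 it is lambda/2
  expect_equal(qnpld(0.5, 0, 1, 1, 1), 0.5, tolerance = 1e-14)
  expect_equal(qnpld(0.5, 0, 7, 1, 3), 1.5, tolerance = 1e-14)
  expect_equal(qnpld(0.5, 0.5, 1, 1, 2), 2 * exp(0.5) / (1 + exp(0.5)),
               tolerance = 1e-14)
  pars <- rand_params(15, seed = 9)
  ps <- c(0.01, 0.25, 0.5, 0.9, 0.999)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    q <- qnpld(ps, p$mu, p$sigma, p$k, p$lambda)
    expect_true(all(q > 0 & q < p$lambda))
    expect_true(all(diff(q) > 0))
    expect_equal(pnpld(q, p$mu, p$sigma, p$k, p$lambda), ps,
                 tolerance = 1e-10)
  }
  # independent oracle: bisection root of cdf(x) = 0.75
  root <- stats::uniroot(function(x) pnpld(x, 0.4, 1.2, 2, 3) - 0.75,
                         c(1e-9, 3 - 1e-9), tol = 1e-13)$root
  expect_equal(qnpld(0.75, 0.4, 1.2, 2, 3), root, tolerance = 1e-9)
  expect_error(qnpld(0), "strictly inside")
  expect_error(qnpld(1), "strictly inside")
})

test_that("lambda acts as a pure scale on quantiles", {
  ps <- c(0.05, 0.3, 0.5, 0.8, 0.99)
  for (lam in c(0.5, 2, 10, 1000)) {
    expect_equal(qnpld(ps, 0.7, 1.1, 2.3, lam),
                 lam * qnpld(ps, 0.7, 1.1, 2.3, 1), tolerance = 1e-13)
  }
})

test_that("random generation is reproducible, supported, and distributed per the cdf", {
  x <- rnpld(1e4, 1, 1, 2, 2, seed = 11)
  expect_length(x, 1e4)
  expect_true(all(x > 0 & x < 2))
  expect_identical(x, rnpld(1e4, 1, 1, 2, 2, seed = 11))
  # one-sample distributional check against the model cdf at the 1% level
  ks <- suppressWarnings(
    stats::ks.test(x, function(q) pnpld(q, 1, 1, 2, 2)))
  expect_gt(ks$p.value, 0.01)
  # empirical median against the closed form 2 e^0.5 / (1 + e^0.5)
  m <- stats::median(rnpld(1e5, 0.5, 1, 1, 2, seed = 12))
  expect_equal(m, 2 * exp(0.5) / (1 + exp(0.5)), tolerance = 0.02)
  expect_error(rnpld(0, 0, 1, 1, 1), "positive integer")
})

test_that("normalizing transform and its inverse roundtrip and gaussianize", {
  for (x0 in c(0.1, 0.5, 0.9) * 2.5) {
    expect_equal(
      npld_inverse_transform(npld_transform(x0, k = 1.7, lambda = 2.5),
                             k = 1.7, lambda = 2.5),
      x0, tolerance = 1e-12)
  }
  pars <- rand_params(10, seed = 21)
  for (i in seq_len(nrow(pars))) {
    p <- pars[i, ]
    expect_equal(
      npld_transform(qnpld(0.5, p$mu, p$sigma, p$k, p$lambda),
                     k = p$k, lambda = p$lambda),
      p$mu, tolerance = 1e-9)
  }
  w <- npld_transform(rnpld(1e4, 2, 0.5, 1.5, 4, seed = 31),
                      k = 1.5, lambda = 4)
  ks <- suppressWarnings(stats::ks.test(w, "pnorm", 2, 0.5))
  expect_gt(ks$p.value, 0.01)
  expect_error(npld_transform(0, k = 1, lambda = 1), "boundary")
  expect_error(npld_transform(2, k = 1, lambda = 2), "boundary")
})

test_that("k = 1, lambda = 1 reduces to the logit-normal distribution", {
  xs <- c(0.02, 0.2, 0.5, 0.77, 0.98)
  ps <- c(0.03, 0.25, 0.5, 0.8, 0.97)
  for (th in list(c(0, 1), c(0.8, 0.4), c(-1.2, 2.2))) {
    expect_equal(dnpld(xs, th[1], th[2], 1, 1),
                 ref_logitnorm_pdf(xs, th[1], th[2]), tolerance = 1e-12)
    expect_equal(pnpld(xs, th[1], th[2], 1, 1),
                 ref_logitnorm_cdf(xs, th[1], th[2]), tolerance = 1e-12)
    expect_equal(qnpld(ps, th[1], th[2], 1, 1),
                 ref_logitnorm_q(ps, th[1], th[2]), tolerance = 1e-12)
  }
})

test_that("parameter container validates and prints", {
  p <- npld_params(0.5, 1, 2, 3)
  expect_s3_class(p, "npld_params")
  expect_output(print(p), "lambda = 3")
  expect_error(npld_params(0, 0, 1, 1), "sigma")
  expect_error(npld_params(0, 1, -2, 1), "'k'")
  expect_error(npld_params(0, 1, 1, 0), "lambda")
  expect_error(npld_params(NA, 1, 1, 1), "mu")
})
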