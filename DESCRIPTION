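Package: npld
Title: The Normal-Power{Logistic} Distribution for Bounded Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution functions, quantile-based shape measures, maximum
    likelihood inference and regression for the Normal-Power{Logistic}
    distribution (NPLD), a four-parameter continuous distribution on a bounded
    interval (0, lambda) whose log-odds-of-power transform
    log(x^k / (lambda^k - x^k)) is Gaussian. Provides d/p/q/r functions,
    survival and hazard functions, robust (quantile-based) skewness and
    kurtosis, mode finding, moments by quadrature, profile-likelihood maximum
    likelihood estimation with error-bound confidence intervals, a Monte-Carlo
    simulation-study runner, the NPLD generalized linear model with its
    closed-form coefficient estimator, a goodness-of-fit battery
    (log-likelihood, AIC, Kolmogorov-Smirnov, Anderson-Darling,
    Cramer-von Mises, chi-square, observed-predicted correlation),
    synthetic-data generators, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
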