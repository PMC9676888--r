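test_that("sample fixtures are reproducible bit-for-bit with metadata sidecars", {
  p <- npld_params(1, 1, 2, 2)
  f1 <- file.path(tempdir(), "s1.csv")
  f2 <- file.path(tempdir(), "s2.csv")
  synth_npld_sample(p, n = 200, seed = 99, path = f1)
  synth_npld_sample(p, n = 200, seed = 99, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  meta <- jsonlite::read_json(paste0(f1, ".meta.json"), simplifyVector = TRUE)
  x <- npld_read_table(f1)$x
  expect_true(all(x > 0 & x < meta$lambda))
  # regeneration from the sidecar matches to the precision the CSV stores
  expect_equal(x, as.numeric(
    synth_npld_sample(npld_params(meta$mu, meta$sigma, meta$k, meta$lambda),
                      n = meta$n, seed = meta$seed)), tolerance = 1e-12)
})

test_that("refitting a large sample fixture recovers the recorded parameters", {
  x <- synth_npld_sample(npld_params(1, 1, 2, 2), n = 2000, seed = 55)
  fit <- npld_mle(as.numeric(x), lambda = 2)
  expect_lt(abs(fit$params$sigma - 1), 0.15)
  expect_lt(abs(fit$params$mu - 1), 0.45)
  expect_lt(abs(fit$params$k - 2), 0.8)
})

test_that("regression fixtures follow the generative model", {
  # noise-free limit: the transformed response is exactly linear
  fx0 <- synth_npld_regression(n = 50, coefficients = c(0.4, -1.1), sigma = 0,
                               k = 2, lambda = 3, seed = 61)
  w <- npld_transform(fx0$data$y, k = 2, lambda = 3)
  expect_equal(w, 0.4 - 1.1 * fx0$data$x1, tolerance = 1e-10)
  fx <- synth_npld_regression(n = 400, coefficients = c(0.5, 1), sigma = 1.5,
                              k = 1, lambda = 2, seed = 62)
  expect_true(all(fx$data$y > 0 & fx$data$y < 2))
  fx2 <- synth_npld_regression(n = 400, coefficients = c(0.5, 1), sigma = 1.5,
                               k = 1, lambda = 2, seed = 62)
  expect_identical(fx$data, fx2$data)
})

test_that("table IO roundtrips CSV and TSV and names malformed cells", {
  df <- data.frame(y = c(0.25, 0.5), x1 = c(1.5, -2))
  csv <- file.path(tempdir(), "t.csv")
  tsv <- file.path(tempdir(), "t.tsv")
  npld_write_table(df, csv)
  npld_write_table(df, tsv)
  expect_equal(npld_read_table(csv), df)
  expect_equal(npld_read_table(tsv), df)
  bad <- file.path(tempdir(), "bad.csv")
  writeLines(c("y,x1", "0.5,1.0", ",2.0"), bad)
  expect_error(npld_read_table(bad), "row 2, column 'y'")
  writeLines(c("y,x1", "0.5,abc"), bad)
  expect_error(npld_read_table(bad), "column 'x1'")
  expect_error(npld_read_table(file.path(tempdir(), "nope.csv")),
               "not found")
})

test_that("CLI: synthetic sample, distribution fit, and gof run end to end", {
  out <- file.path(tempdir(), "cli_sample.csv")
  st <- npld_cli(c("synth-sample", "--mu", "1", "--sigma", "1", "--k", "2",
                   "--lambda", "2", "--n", "300", "--seed", "7",
                   "--output", out, "--log-level", "quiet"))
  expect_identical(st, 0L)
  expect_true(file.exists(out) && file.exists(paste0(out, ".meta.json")))

  rep_json <- file.path(tempdir(), "fit.json")
  st <- npld_cli(c("fit-dist", "--input", out, "--lambda", "2",
                   "--output", rep_json, "--log-level", "quiet"))
  expect_identical(st, 0L)
  fit <- jsonlite::read_json(rep_json)
  expect_true(is.numeric(fit$loglik) && fit$n == 300)
  expect_lt(abs(fit$sigma - 1), 0.5)

  gof_json <- file.path(tempdir(), "gof.json")
  st <- npld_cli(c("gof", "--input", out, "--mu", "1", "--sigma", "1",
                   "--k", "2", "--lambda", "2", "--output", gof_json,
                   "--log-level", "quiet"))
  expect_identical(st, 0L)
  g <- jsonlite::read_json(gof_json)
  expect_true(all(c("neg_loglik", "aic", "ks_D", "ad_A", "cvm_omega",
                    "chi_square", "correlation") %in% names(g)))
})

test_that("CLI: regression fixture and glm fit exit cleanly and write reports", {
  cfg <- file.path(tempdir(), "reg.yaml")
  writeLines(c("n: 250", "coefficients: [0.5, 1.0]", "sigma: 1.0",
               "k: 1.5", "lambda: 2.0", "seed: 13"), cfg)
  dat <- file.path(tempdir(), "reg.csv")
  st <- npld_cli(c("synth-regression", "--config", cfg, "--output", dat,
                   "--log-level", "quiet"))
  expect_identical(st, 0L)
  glm_json <- file.path(tempdir(), "glm.json")
  fitted_csv <- file.path(tempdir(), "fitted.csv")
  st <- npld_cli(c("fit-glm", "--input", dat, "--response", "y",
                   "--output", glm_json, "--fitted-out", fitted_csv,
                   "--log-level", "quiet"))
  expect_identical(st, 0L)
  rep <- jsonlite::read_json(glm_json)
  expect_true(all(c("coefficients", "k", "lambda", "sigma", "gof") %in%
                    names(rep)))
  expect_equal(nrow(npld_read_table(fitted_csv)), 250)
})

test_that("CLI: simulate-tables writes the simulation table from a YAML spec", {
  cfg <- file.path(tempdir(), "sim.yaml")
  writeLines(c("mu: 2", "sigma: 2", "k: 2", "lambda: 2",
               "n_values: [50, 100]", "replicates: 30", "seed: 5"), cfg)
  out <- file.path(tempdir(), "sim.csv")
  st <- npld_cli(c("simulate-tables", "--config", cfg, "--output", out,
                   "--log-level", "quiet"))
  expect_identical(st, 0L)
  tab <- npld_read_table(out, columns = c("n", "actual", "mean", "se"))
  expect_equal(names(tab),
               c("n", "parameter", "actual", "mean", "se", "ci_low",
                 "ci_high"))
  expect_equal(nrow(tab), 6L)
  # seed override on the command line is honored and reproducible
  out2 <- file.path(tempdir(), "sim2.csv")
  npld_cli(c("simulate-tables", "--config", cfg, "--output", out2,
             "--seed", "5", "--log-level", "quiet"))
  expect_identical(readLines(out), readLines(out2))
})

test_that("CLI: usage and runtime failures map to distinct exit codes", {
  expect_identical(suppressMessages(npld_cli(c("fit-dist", "--bogus", "1"))),
                   2L)
  expect_identical(suppressMessages(npld_cli("not-a-command")), 2L)
  expect_identical(suppressMessages(npld_cli(character(0))), 2L)
  msg <- capture.output(
    st <- npld_cli(c("fit-dist", "--input", "/nope/missing.csv")),
    type = "message")
  expect_identical(st, 1L)
  expect_true(any(grepl("/nope/missing.csv", msg)))
  # strict config validation: unknown keys are fatal
  cfg <- file.path(tempdir(), "badcfg.yaml")
  writeLines(c("mu: 1", "sigma: 1", "k: 1", "lambda: 2", "n_values: [50]",
               "replicates: 10", "seed: 1", "typo_key: 3"), cfg)
  expect_identical(suppressMessages(
    npld_cli(c("simulate-tables", "--config", cfg, "--output",
               file.path(tempdir(), "x.csv")))), 1L)
})
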