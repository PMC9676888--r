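#' Generate a synthetic NPLD sample fixture
#'
#' Draws a reproducible sample by inverse-transform sampling and (optionally)
#' writes it as a one-column CSV together with a JSON sidecar recording the
#' generating parameters and seed, so any fixture can be regenerated
#' bit-for-bit from its metadata.
#'
#' @param params True parameter set, an [npld_params()] object.
#' @param n Sample size.
#' @param seed Integer seed.
#' @param path Optional output CSV path; a sidecar `<path>.meta.json` is
#'   written next to it.
#' @return The sample (invisibly when `path` is given), with the generating
#'   parameters and seed attached as attribute `"meta"`.
#' @examples
#' x <- synth_npld_sample(npld_params(1, 1, 2, 2), n = 100, seed = 3)
#' range(x)
#' @export
synth_npld_sample <- function(params, n, seed, path = NULL) {
  p <- as_npld_params(params)
  x <- rnpld(n, p$mu, p$sigma, p$k, p$lambda, seed = seed)
  meta <- list(mu = p$mu, sigma = p$sigma, k = p$k, lambda = p$lambda,
               n = n, seed = seed)
  attr(x, "meta") <- meta
  if (!is.null(path)) {
    npld_write_table(data.frame(x = as.numeric(x)), path)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
    return(invisible(x))
  }
  x
}

#' Generate a synthetic bounded-response regression fixture
#'
#' Emulates the structure of bounded, skewed or bimodal application data with
#' linear covariate structure on the transformed scale: covariates are drawn
#' uniformly on per-column ranges, the linear predictor `eta = X B` receives
#' Gaussian noise of standard deviation `sigma` on the w scale, and the
#' response comes back through the inverse link, so every `y` lies in
#' `(0, lambda)`. Large `sigma` pushes mass toward both support boundaries and
#' produces a bimodal marginal response.
#'
#' @param n Sample size.
#' @param coefficients True coefficient vector, intercept first.
#' @param sigma Transformed-scale noise standard deviation (`>= 0`; 0 gives a
#'   noise-free fixture).
#' @param k,lambda NPLD plug-ins of the generative model.
#' @param covariate_law List of `length(coefficients) - 1` numeric ranges
#'   `c(lo, hi)`, one per covariate; default unit ranges.
#' @param seed Integer seed.
#' @param path Optional output CSV path (`y` plus covariate columns); a JSON
#'   truth sidecar `<path>.meta.json` is written next to it.
#' @return List with `data` (data frame: `y`, `x1`, `x2`, ...) and `truth`
#'   (list of generating values).
#' @examples
#' fx <- synth_npld_regression(n = 100, coefficients = c(0.5, 1), sigma = 1,
#'                             k = 1.5, lambda = 2, seed = 11)
#' head(fx$data)
#' @export
synth_npld_regression <- function(n, coefficients, sigma, k, lambda,
                                  covariate_law = NULL, seed,
                                  path = NULL) {
  if (length(coefficients) < 2)
    stop("'coefficients' must hold an intercept and at least one slope",
         call. = FALSE)
  if (!is.numeric(sigma) || sigma < 0)
    stop("'sigma' must be non-negative", call. = FALSE)
  check_npld_params(0, 1, k, lambda)
  n_cov <- length(coefficients) - 1L
  if (is.null(covariate_law))
    covariate_law <- rep(list(c(0, 1)), n_cov)
  if (length(covariate_law) != n_cov)
    stop("'covariate_law' must give one range per covariate", call. = FALSE)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  X <- cbind(1, vapply(covariate_law, function(rg)
    stats::runif(n, rg[1], rg[2]), numeric(n)))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(n_cov)))
  eta <- drop(X %*% coefficients)
  w <- eta + if (sigma > 0) stats::rnorm(n, 0, sigma) else 0
  y <- npld_inverse_transform(w, k = k, lambda = lambda)
  dat <- data.frame(y = y, X[, -1, drop = FALSE], check.names = FALSE)
  truth <- list(coefficients = as.numeric(coefficients), sigma = sigma,
                k = k, lambda = lambda, n = n, seed = seed,
                covariate_law = covariate_law)
  if (!is.null(path)) {
    npld_write_table(dat, path)
    jsonlite::write_json(truth, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  list(data = dat, truth = truth)
}

#' Read and write delimited data tables
#'
#' Thin CSV/TSV readers and writers for the package's data files. The dialect
#' is picked from the file extension (`.tsv`/`.tab` means tab, anything else
#' comma). A header row is required; for the columns named in `columns`
#' (default: all) every cell must parse as a non-missing number, and a
#' violation is reported with its row and column.
#'
#' @param path File path.
#' @param columns Character vector of column names that must be complete and
#'   numeric; defaults to all columns.
#' @return `npld_read_table` returns a data frame; `npld_write_table` returns
#'   the path invisibly.
#' @export
npld_read_table <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(columns)) columns <- names(df)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stop("column not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cn in columns) {
    col <- df[[cn]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("parse error in %s: row %d, column '%s' is not a number",
                   path, bad[1], cn), call. = FALSE)
    df[[cn]] <- num
  }
  df
}

#' @rdname npld_read_table
#' @param df Data frame to write.
#' @export
npld_write_table <- function(df, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
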