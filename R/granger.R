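#' Ordinary least squares fit returning coefficients and residual sum of
#' squares
#'
#' Thin QR-based backend for the nested model fits. Rank-deficient designs are
#' solved by the minimum-norm (pseudoinverse) solution with a warning.
#'
#' @param design numeric matrix (rows >= columns).
#' @param response numeric vector.
#' @return List with `coefficients` and `rss`.
#' @export
ols_fit <- function(design, response) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  if (nrow(design) != length(response)) {
    arg_error("design rows and response length differ")
  }
  if (nrow(design) < ncol(design)) {
    abort_tn("fewer rows than columns: insufficient data for OLS",
             "temponet_insufficient_data")
  }
  if (anyNA(design) || anyNA(response) ||
      !all(is.finite(design)) || !all(is.finite(response))) {
    arg_error("non-finite values in OLS inputs")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("rank-deficient design: using minimum-norm solution")
    sv <- svd(design)
    pos <- sv$d > max(sv$d) * 1e-12
    coefs <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], response)) / sv$d[pos])
    coefs <- drop(coefs)
  } else {
    coefs <- qr.coef(qrd, response)
  }
  fitted <- drop(design %*% coefs)
  list(coefficients = coefs, rss = sum((response - fitted)^2))
}

#' Pooled Granger causality F-test on stacked lagged rows
#'
#' Fits the reduced autoregressive model `y_t ~ 1 + y_{t-1}` and the full
#' bivariate model `y_t ~ 1 + y_{t-1} + x_{t-1}` on the pooled rows and
#' compares them with the nested F statistic
#' \deqn{F = \frac{(RSS_r - RSS_f) / 1}{RSS_f / (n - k)},}
#' where n is the number of pooled rows and k the number of full-model
#' coefficients (3 with intercept). A single coefficient set is shared across
#' all pooled individuals: the pooling assumes response slopes are similar
#' across individuals once baselines are removed.
#'
#' @param design a `lagged_design` from [stack_lagged_rows()], or any data
#'   frame with columns `y`, `y_lag`, `x_lag`.
#' @param intercept include an intercept in both models (default TRUE).
#' @return A `granger_result`: `f_stat`, `p_value`, `rss_full`,
#'   `rss_reduced`, `df1 = 1`, `df2 = n - k`, both coefficient vectors,
#'   `n_rows`, and flags `degenerate` (exact full fit, p reported as 0) and
#'   `collinear` (constant x_lag, test skipped with p = 1).
#' @export
#' @examples
#' s <- simulate_bvar_pair(bvar_params(), 240, seed = 7)
#' d <- data.frame(y = s$y[-1], y_lag = s$y[-240], x_lag = s$x[-240])
#' granger_test(d)$p_value
granger_test <- function(design, intercept = TRUE) {
  d <- as.data.frame(design)
  if (!all(c("y", "y_lag", "x_lag") %in% names(d))) {
    arg_error("design needs columns y, y_lag, x_lag")
  }
  n <- nrow(d)
  k_full <- if (intercept) 3L else 2L
  if (n < k_full + 1L) {
    abort_tn(sprintf("need at least %d rows for the F test, got %d",
                     k_full + 1L, n),
             "temponet_insufficient_data")
  }
  df2 <- n - k_full

  base_cols <- if (intercept) cbind(`(Intercept)` = 1, y_lag = d$y_lag)
               else cbind(y_lag = d$y_lag)

  res <- list(n_rows = n, df1 = 1L, df2 = df2,
              degenerate = FALSE, collinear = FALSE)

  if (stats::var(d$x_lag) < .Machine$double.eps) {
    # a constant predictor carries no past information; skip rather than fail
    red <- ols_fit(base_cols, d$y)
    res$rss_reduced <- red$rss
    res$rss_full <- red$rss
    res$coef_reduced <- red$coefficients
    res$coef_full <- c(red$coefficients, x_lag = 0)
    res$f_stat <- 0
    res$p_value <- 1
    res$collinear <- TRUE
    return(structure(res, class = "granger_result"))
  }

  red <- ols_fit(base_cols, d$y)
  full <- ols_fit(cbind(base_cols, x_lag = d$x_lag), d$y)
  f <- (red$rss - full$rss) / (full$rss / df2)
  res$rss_reduced <- red$rss
  res$rss_full <- full$rss
  res$coef_reduced <- red$coefficients
  res$coef_full <- full$coefficients
  if (full$rss <= 1e-12 * red$rss || !is.finite(f)) {
    # exact deterministic fit: evidence is unbounded
    res$f_stat <- Inf
    res$p_value <- 0
    res$degenerate <- TRUE
  } else {
    res$f_stat <- max(f, 0)
    res$p_value <- stats::pf(res$f_stat, 1, df2, lower.tail = FALSE)
  }
  structure(res, class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("Granger causality F test: F(1, %d) = %.4g, p = %.4g (n = %d)\n",
              x$df2, x$f_stat, x$p_value, x$n_rows))
  if (x$collinear) cat("  [skipped: constant x_lag column]\n")
  if (x$degenerate) cat("  [degenerate: exact full-model fit]\n")
  invisible(x)
}

#' Granger test directly on one simulated pair series
#'
#' Convenience wrapper building the lagged rows of a single `pair_series`
#' and applying [granger_test()].
#'
#' @param series a `pair_series`.
#' @param intercept passed to [granger_test()].
#' @return A `granger_result`.
#' @export
granger_test_series <- function(series, intercept = TRUE) {
  stopifnot(inherits(series, "pair_series"))
  T <- length(series$y)
  granger_test(data.frame(y = series$y[-1L],
                          y_lag = series$y[-T],
                          x_lag = series$x[-T]),
               intercept = intercept)
}

#' Pool several pair series into one lagged design and test
#'
#' Stacks the lagged rows of every series (rows never cross series
#' boundaries) and runs the pooled test with shared coefficients: the
#' virtual-long-series construction.
#'
#' @param population list of `pair_series`.
#' @param intercept passed to [granger_test()].
#' @return A `granger_result` with `n_rows = sum(T_i - 1)`.
#' @export
granger_test_pooled <- function(population, intercept = TRUE) {
  rows <- lapply(population, function(s) {
    T <- length(s$y)
    data.frame(y = s$y[-1L], y_lag = s$y[-T], x_lag = s$x[-T])
  })
  granger_test(do.call(rbind, rows), intercept = intercept)
}
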