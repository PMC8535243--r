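# OLS baseline and residual-normality diagnostics.
#
# The mean-regression comparison point: classical OLS inference is only
# trustworthy when residuals are close to iid normal; on right-skewed,
# leptokurtic billing-aggressiveness data the Lilliefors test and Q-Q
# pairs document how badly that assumption fails, motivating the
# quantile-regression analysis.

#' Ordinary least squares baseline
#'
#' Least-squares fit with classical homoscedastic standard errors and
#' two-sided t-test p-values (columns shaped like the usual
#' estimate / s.e. / p-value regression table). Heteroscedasticity-robust
#' (HC1) standard errors are available behind `robust = TRUE`.
#'
#' @param X covariate matrix or data.frame (no intercept column).
#' @param y response vector.
#' @param robust use HC1 sandwich standard errors instead of classical.
#' @return class `"ols_fit"`: `coefficients`, `se`, `t_stats`, `p_values`,
#'   `sigma2`, `residuals`, `fitted`, `r_squared`, `n`, `p`, `table`
#'   (a data.frame with variable/estimate/se/p_value).
#' @export
fit_ols <- function(X, y, robust = FALSE) {
  A <- .design_matrix(X)
  y <- as.numeric(y)
  if (nrow(A) <= ncol(A)) stop("need n > p + 1 observations", call. = FALSE)
  .check_full_rank(A)
  df <- as.data.frame(A[, -1L, drop = FALSE])
  fit <- if (ncol(df) == 0L) stats::lm(y ~ 1) else stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  beta <- stats::coef(fit)
  names(beta) <- colnames(A)
  res <- stats::residuals(fit)
  n <- nrow(A); k <- ncol(A)

  if (robust) {
    # HC1 sandwich
    Xi <- chol2inv(chol(crossprod(A)))
    meat <- crossprod(A * res)
    V <- Xi %*% meat %*% Xi * n / (n - k)
    se <- sqrt(diag(V))
    tstat <- beta / se
    pval <- 2 * stats::pt(-abs(tstat), df = n - k)
  } else {
    se <- stats::setNames(sm$coefficients[, "Std. Error"], colnames(A))
    tstat <- stats::setNames(sm$coefficients[, "t value"], colnames(A))
    pval <- stats::setNames(sm$coefficients[, "Pr(>|t|)"], colnames(A))
  }

  out <- list(coefficients = beta, se = se, t_stats = tstat, p_values = pval,
              sigma2 = sm$sigma^2, residuals = res,
              fitted = stats::fitted(fit), r_squared = sm$r.squared,
              n = n, p = k - 1L, robust = robust,
              table = data.frame(variable = colnames(A),
                                 estimate = unname(beta),
                                 se = unname(se),
                                 p_value = unname(pval),
                                 stringsAsFactors = FALSE))
  class(out) <- "ols_fit"
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d, p = %d, R^2 = %.4f, %s s.e.)\n",
              x$n, x$p, x$r_squared,
              if (x$robust) "HC1 robust" else "classical"))
  print(transform(x$table, estimate = signif(estimate, 5),
                  se = signif(se, 4), p_value = signif(p_value, 3)))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

# sup-norm distance between the ECDF of x and a normal with estimated
# mean/sd -- the Lilliefors statistic.
.lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  p <- stats::pnorm(z)
  max(pmax(seq_len(n) / n - p, p - (seq_len(n) - 1) / n))
}

#' Lilliefors test for residual normality (Monte-Carlo null)
#'
#' Kolmogorov-Smirnov distance between the residual ECDF and a normal
#' distribution with mean and standard deviation estimated from the same
#' sample. Because parameters are estimated, the classical KS null does
#' not apply; the p-value is computed by Monte Carlo: `mc_reps` samples of
#' `n` standard normals are pushed through the identical
#' estimate-then-measure step, and the p-value is
#' `(1 + #{D_null >= D_obs}) / (mc_reps + 1)`. Exact for any n, and
#' deterministic given `seed`.
#'
#' @param residuals numeric vector, length >= 5.
#' @param mc_reps Monte-Carlo null replicates.
#' @param seed integer seed.
#' @return list with `statistic`, `p_value`, `mc_reps`, `degenerate`
#'   (TRUE when the residuals have zero variance, in which case the test
#'   does not apply and `p_value` is reported as 0).
#' @export
lilliefors_test <- function(residuals, mc_reps = 10000L, seed = 1L) {
  x <- as.numeric(residuals)
  n <- length(x)
  if (n < 5) stop("Lilliefors test needs n >= 5", call. = FALSE)
  if (stats::sd(x) == 0) {
    return(list(statistic = NA_real_, p_value = 0, mc_reps = 0L,
                degenerate = TRUE))
  }
  d_obs <- .lilliefors_stat(x)
  exceed <- .with_seed(seed, {
    null_d <- vapply(seq_len(mc_reps),
                     function(i) .lilliefors_stat(stats::rnorm(n)),
                     numeric(1))
    sum(null_d >= d_obs)
  })
  list(statistic = d_obs, p_value = (1 + exceed) / (mc_reps + 1),
       mc_reps = as.integer(mc_reps), degenerate = FALSE)
}

#' Normal Q-Q pairs for residuals
#'
#' Standardized residual order statistics paired with standard-normal
#' quantiles at plotting positions \eqn{(i - 0.5)/n}; plot-ready (and
#' written as CSV by the pipeline).
#'
#' @param residuals numeric vector, length >= 2.
#' @return data.frame with `position`, `theoretical`, `sample` columns.
#' @export
qq_data <- function(residuals) {
  x <- as.numeric(residuals)
  n <- length(x)
  if (n < 2) stop("need at least 2 residuals", call. = FALSE)
  pos <- (seq_len(n) - 0.5) / n
  data.frame(position = pos,
             theoretical = stats::qnorm(pos),
             sample = sort((x - mean(x)) / stats::sd(x)))
}
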