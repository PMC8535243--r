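# L1-penalized quantile regression and modified-BIC penalty selection.
#
# The penalized problem
#     min  sum_i rho_tau(y_i - b0 - x_i'b) + lambda * n * sum_j |b_j|
# (factor-2 check loss, intercept unpenalized, covariates standardized)
# is solved exactly as an augmented quantile-regression LP: each penalty
# term lambda*n*|b_j| equals the factor-2 median check loss of a
# pseudo-observation (y = 0, design row = unit vector e_j, weight
# lambda*n), so one weighted per-row-tau LP engine serves both problems
# and the vertex solution carries exact zeros.

.standardize_design <- function(X) {
  X <- .design_matrix(X, intercept = FALSE)
  m <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  if (any(s == 0)) {
    stop("constant column(s) cannot be standardized: ",
         paste(colnames(X)[s == 0], collapse = ", "), call. = FALSE)
  }
  list(Xs = sweep(sweep(X, 2L, m), 2L, s, "/"), center = m, scale = s,
       names = colnames(X))
}

.unstandardize_beta <- function(beta_std, center, scale) {
  slopes <- beta_std[-1L] / scale
  b0 <- beta_std[1L] - sum(beta_std[-1L] * center / scale)
  c(beta_std[1L] * 0 + b0, slopes)
}

#' L1-penalized quantile regression
#'
#' Minimizes \eqn{\sum_i \rho_\tau(y_i - \beta_0 - x_i^T\beta) + \lambda n
#' \sum_j |\beta_j|} (factor-2 check loss) with an unpenalized intercept.
#' Covariates are centered and scaled to unit standard deviation before
#' penalization — the L1 penalty is scale-sensitive — and coefficients are
#' returned on both scales. Solved exactly as an augmented LP, so
#' non-selected coefficients are exactly zero at vertex solutions.
#'
#' @param X covariate matrix (no intercept).
#' @param y response vector.
#' @param tau quantile level in (0, 1).
#' @param lambda penalty level, >= 0; `lambda = 0` reproduces
#'   [fit_quantreg()].
#' @return list with `coefficients` (original scale, intercept first),
#'   `coefficients_std` (standardized scale: intercept plus slopes for
#'   unit-sd covariates), `objective` (penalized, factor-2 convention),
#'   `loss` (unpenalized factor-2 check loss at the solution),
#'   `lambda`, `tau`.
#' @export
fit_l1_quantreg <- function(X, y, tau, lambda) {
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  std <- .standardize_design(X)
  y <- as.numeric(y)
  n <- nrow(std$Xs); p <- ncol(std$Xs)
  if (n <= p + 1L) stop("need n > p + 1 observations", call. = FALSE)
  A <- cbind(`(Intercept)` = 1, std$Xs)
  .check_full_rank(A)

  if (lambda > 0) {
    P <- cbind(0, diag(p))
    colnames(P) <- colnames(A)
    Aaug <- rbind(A, P)
    yaug <- c(y, rep(0, p))
    taus <- c(rep(tau, n), rep(0.5, p))
    ws <- c(rep(1, n), rep(lambda * n, p))
    sol <- .qr_ip_engine(Aaug, yaug, tau = taus, w = ws)
  } else {
    sol <- .qr_ip_engine(A, y, tau = tau, w = rep(1, n))
  }
  beta_std <- stats::setNames(sol$coefficients, colnames(A))
  res <- y - drop(A %*% beta_std)
  loss <- sum(check_loss(res, tau))
  list(coefficients = stats::setNames(
         .unstandardize_beta(beta_std, std$center, std$scale), colnames(A)),
       coefficients_std = beta_std,
       objective = loss + lambda * n * sum(abs(beta_std[-1L])),
       loss = loss, lambda = lambda, tau = tau,
       center = std$center, scale = std$scale)
}

#' Zero-threshold rule for penalized coefficients
#'
#' Slope coefficients with absolute value strictly below `cut` (default
#' 0.001, applied on the standardized scale) are set to zero; the support
#' is the set of surviving slope indices. The intercept is never
#' thresholded and never counted in the support.
#'
#' @param beta_std coefficient vector on the standardized scale, intercept
#'   first.
#' @param cut threshold; values with `abs(beta) < cut` are zeroed (the
#'   boundary value `cut` itself is kept).
#' @return list with `beta` (thresholded, same scale and names) and
#'   `support` (integer indices into the slopes, 1..p).
#' @export
threshold_support <- function(beta_std, cut = 0.001) {
  stopifnot(length(beta_std) >= 1L, cut >= 0)
  slopes <- beta_std[-1L]
  drop_j <- abs(slopes) < cut
  slopes[drop_j] <- 0
  beta_std[-1L] <- slopes
  list(beta = beta_std, support = unname(which(!drop_j)))
}

#' Modified BIC for quantile regression
#'
#' \deqn{BIC(S) = \log \sum_i \rho_\tau(y_i - x_{iS}^T \hat\beta_S) +
#'   |S| \frac{\log n}{2n} C_n,}
#' where \eqn{C_n} is a positive sequence diverging with n. `|S|` counts
#' selected slopes only (never the intercept). The default
#' \eqn{C_n = \log\log n} is the standard choice in the modified-BIC
#' variable-selection literature; `log_p` and a user constant are
#' alternatives.
#'
#' @param loss summed factor-2 check loss at the candidate fit.
#' @param support_size number of selected slope coefficients, `|S|`.
#' @param n sample size (>= 3 under `loglog_n`).
#' @param Cn_spec one of `"loglog_n"`, `"log_p"`, or a positive number used
#'   as a constant.
#' @param p number of candidate covariates (needed for `"log_p"`).
#' @return the BIC value; `-Inf` with a warning when `loss == 0`
#'   (perfect interpolation).
#' @export
bic_quantile <- function(loss, support_size, n, Cn_spec = "loglog_n", p = NULL) {
  stopifnot(loss >= 0, support_size >= 0, n >= 2)
  Cn <- .resolve_cn(Cn_spec, n, p)
  if (loss == 0) {
    warning("zero check loss (perfect interpolation): BIC is -Inf")
    return(-Inf)
  }
  log(loss) + support_size * log(n) / (2 * n) * Cn
}

.resolve_cn <- function(Cn_spec, n, p = NULL) {
  if (is.numeric(Cn_spec)) {
    stopifnot(Cn_spec > 0)
    return(Cn_spec)
  }
  switch(match.arg(Cn_spec, c("loglog_n", "log_p")),
         loglog_n = {
           if (n < 3) stop("Cn = log(log n) requires n >= 3", call. = FALSE)
           log(log(n))
         },
         log_p = {
           if (is.null(p)) stop("Cn = log(p) requires `p`", call. = FALSE)
           log(p)
         })
}

#' Select the penalty level by modified BIC
#'
#' Fits the L1-penalized quantile regression over a grid of penalty
#' levels (default: 100 log-spaced points in \[0.01, 1\]), applies the
#' zero-threshold rule at each, and scores each candidate support with
#' the modified BIC evaluated at the unpenalized maximum-likelihood refit
#' on that support (the BIC is defined at the MLE of the candidate model;
#' using the shrunken penalized estimates instead would charge the
#' sparser grid points for their shrinkage bias and systematically favor
#' over-selection). Refits are cached per distinct support. Returns the
#' grid point with minimal BIC; ties are broken toward the largest
#' penalty (the sparser model).
#'
#' @param X covariate matrix.
#' @param y response vector.
#' @param tau quantile level.
#' @param lambda_grid increasing vector of penalties > 0; default
#'   `lambda_grid_default()`.
#' @param Cn_spec see [bic_quantile()].
#' @param cut zero threshold, see [threshold_support()].
#' @param refit if `TRUE`, the reported coefficients are an unpenalized
#'   refit on the selected support; default reports the penalized
#'   (thresholded) estimates.
#' @return class `"selection_result"`: `tau`, `path` (a data.frame with
#'   lambda, support size, L1 norm of standardized slopes, the MLE-refit
#'   check loss of the thresholded support, bic),
#'   `lambda_hat`, `support` (indices) and `support_names`, `coefficients`
#'   (original scale; non-selected slopes exactly 0), `coefficients_std`,
#'   `Cn` (resolved value) and `Cn_spec`, `refit`.
#' @export
select_lambda <- function(X, y, tau, lambda_grid = lambda_grid_default(),
                          Cn_spec = "loglog_n", cut = 0.001, refit = FALSE) {
  if (length(lambda_grid) == 0L) stop("empty lambda grid", call. = FALSE)
  stopifnot(all(lambda_grid > 0), !is.unsorted(lambda_grid))
  y <- as.numeric(y)
  n <- length(y)
  Xm <- .design_matrix(X, intercept = FALSE)
  p <- ncol(Xm)
  Cn <- .resolve_cn(Cn_spec, n, p)

  fits <- vector("list", length(lambda_grid))
  path <- data.frame(lambda = lambda_grid, support_size = NA_integer_,
                     l1_norm = NA_real_, loss = NA_real_, bic = NA_real_)
  refit_cache <- new.env(parent = emptyenv())
  for (i in seq_along(lambda_grid)) {
    f <- fit_l1_quantreg(Xm, y, tau, lambda_grid[i])
    th <- threshold_support(f$coefficients_std, cut = cut)
    key <- paste0("s", paste(th$support, collapse = "_"))
    if (is.null(refit_cache[[key]])) {
      refit_cache[[key]] <-
        fit_quantreg(Xm[, th$support, drop = FALSE], y, tau)$objective
    }
    loss_mle <- refit_cache[[key]]
    path$support_size[i] <- length(th$support)
    path$l1_norm[i] <- sum(abs(f$coefficients_std[-1L]))
    path$loss[i] <- loss_mle
    path$bic[i] <- if (loss_mle == 0) -Inf else
      log(loss_mle) + length(th$support) * log(n) / (2 * n) * Cn
    fits[[i]] <- list(fit = f, th = th)
  }

  best <- max(which(path$bic <= min(path$bic) + 1e-12))
  f <- fits[[best]]$fit
  th <- fits[[best]]$th
  beta_std <- th$beta
  beta <- stats::setNames(.unstandardize_beta(beta_std, f$center, f$scale),
                          names(f$coefficients))
  # back-transform can leave sub-cut dust on zeroed slopes: keep exact zeros
  beta[-1L][beta_std[-1L] == 0] <- 0

  if (refit) {
    rf <- fit_quantreg(Xm[, th$support, drop = FALSE], y, tau)
    beta[] <- 0
    beta[1L] <- rf$coefficients[1L]
    if (length(th$support)) beta[1L + th$support] <- rf$coefficients[-1L]
  }

  out <- list(tau = tau, path = path, lambda_hat = lambda_grid[best],
              support = th$support,
              support_names = colnames(Xm)[th$support],
              coefficients = beta, coefficients_std = beta_std,
              Cn = Cn, Cn_spec = Cn_spec, cut = cut, refit = refit,
              n = n, p = p)
  class(out) <- "selection_result"
  out
}

#' Default penalty grid
#'
#' 100 log-spaced points between 0.01 and 1, the published search range
#' for the penalty level under the \eqn{\lambda n \sum_j |\beta_j|}
#' parameterization used here.
#' @param lambda_min,lambda_max grid bounds.
#' @param length_out number of grid points.
#' @return increasing numeric vector.
#' @export
lambda_grid_default <- function(lambda_min = 0.01, lambda_max = 1,
                                length_out = 100L) {
  stopifnot(lambda_min > 0, lambda_max >= lambda_min, length_out >= 1L)
  exp(seq(log(lambda_min), log(lambda_max), length.out = length_out))
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Penalized quantile selection (tau = %g, n = %d, p = %d)\n",
              x$tau, x$n, x$p))
  cat(sprintf("  lambda_hat = %.5g (Cn = %.4g, threshold = %g)\n",
              x$lambda_hat, x$Cn, x$cut))
  cat(sprintf("  selected %d of %d: %s\n", length(x$support), x$p,
              if (length(x$support)) paste(x$support_names, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Selected-coefficient table across quantiles
#'
#' Combines per-quantile [select_lambda()] results into a variables-by-
#' quantiles coefficient matrix; variables outside a quantile's selected
#' support are reported as 0.
#'
#' @param results list of `selection_result` objects (one per tau).
#' @return data.frame with a `variable` column followed by one column per
#'   quantile (named `tau_<level>`).
#' @export
selection_table <- function(results) {
  stopifnot(length(results) >= 1L)
  stopifnot(all(vapply(results, inherits, TRUE, "selection_result")))
  vars <- names(results[[1L]]$coefficients)
  for (r in results) stopifnot(identical(names(r$coefficients), vars))
  out <- data.frame(variable = vars, stringsAsFactors = FALSE)
  for (r in results) out[[sprintf("tau_%g", r$tau)]] <- unname(r$coefficients)
  out
}
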