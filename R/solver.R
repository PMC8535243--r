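# Interior-point engine for weighted quantile regression.
#
# Solves  min_b  sum_i w_i * rho_tau_i(y_i - a_i' b)   (standard convention)
# via the bounded-variables dual LP
#     max  y'a   s.t.  A'a = A'(w*(1-tau)),  0 <= a <= w,
# with a Mehrotra predictor-corrector primal-dual method (the Frisch-Newton
# scheme used for quantile-regression LPs), followed by a vertex-polishing
# step that recovers an exact basic solution: the optimal b interpolates
# ncol(A) rows, so refitting through the rows with smallest |residual|
# (greedily completed to a full-rank basis) yields the exact LP vertex.
# Per-row tau and weights let one engine serve both the plain fit and the
# L1-penalized fit (penalty rows enter as extra observations at tau = 1/2).

.qr_ip_engine <- function(A, y, tau, w, tol = 1e-11, max_iter = 100L) {
  n <- nrow(A); k <- ncol(A)
  if (length(tau) == 1L) tau <- rep(tau, n)
  if (length(w) == 1L) w <- rep(w, n)
  stopifnot(length(y) == n, length(tau) == n, length(w) == n,
            all(tau > 0 & tau < 1), all(w > 0))

  a <- w * (1 - tau)                            # interior start with A'a = A'(w(1-tau)) exact
  s <- w - a
  b <- tryCatch(qr.coef(qr(A * sqrt(w)), y * sqrt(w)),
                error = function(e) rep(0, k))
  b[is.na(b)] <- 0
  r <- y - drop(A %*% b)
  delta <- 1e-4 * max(1, mean(abs(r)))
  z <- pmax(-r, 0) + delta
  q <- pmax(r, 0) + delta                       # maintains z - q = -r

  gap <- sum(a * z) + sum(s * q)
  it <- 0L
  scale0 <- 1 + sum(w * abs(y)) / n

  solve_step <- function(M, rhs) {
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) ch <- chol(M + diag(1e-10 * max(diag(M)), nrow(M)))
    backsolve(ch, forwardsolve(t(ch), rhs))
  }

  while (gap > tol * n * scale0 && it < max_iter) {
    it <- it + 1L
    theta <- z / a + q / s
    d <- 1 / theta
    AtDA <- crossprod(A, A * d)

    # affine (predictor) direction: target mu = 0, no corrector
    rz <- -a * z
    rq <- -s * q
    # Newton: da = d*(rz/a - rq/s - A db); A'da = 0 => (A'DA) db = A'[d*(rz/a - rq/s)]
    g <- d * (rz / a - rq / s)
    db <- solve_step(AtDA, crossprod(A, g))
    da <- d * (rz / a - rq / s - drop(A %*% db))
    ds <- -da
    dz <- (rz - z * da) / a
    dq <- (rq + q * da) / s

    step_len <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) 1 else min(1, 0.9995 * min(-v[neg] / dv[neg]))
    }
    ap <- min(step_len(a, da), step_len(s, ds))
    ad <- min(step_len(z, dz), step_len(q, dq))
    gap_aff <- sum((a + ap * da) * (z + ad * dz)) + sum((s + ap * ds) * (q + ad * dq))
    mu <- (gap_aff / gap)^3 * gap / (2 * n)

    # corrector direction, reusing the same scaling matrix
    rz <- mu - a * z - da * dz
    rq <- mu - s * q - ds * dq
    g <- d * (rz / a - rq / s)
    db <- solve_step(AtDA, crossprod(A, g))
    da <- d * (rz / a - rq / s - drop(A %*% db))
    ds <- -da
    dz <- (rz - z * da) / a
    dq <- (rq + q * da) / s

    ap <- min(step_len(a, da), step_len(s, ds))
    ad <- min(step_len(z, dz), step_len(q, dq))
    a <- a + ap * da; s <- s + ap * ds
    z <- z + ad * dz; q <- q + ad * dq
    b <- b + ad * db # b, z, q share the dual step so z - q = -(y - Ab) is kept
    gap <- sum(a * z) + sum(s * q)
  }

  # b is carried as the dual iterate; recover it from z - q = -(y - Ab)
  # at convergence via least squares on the interior rows is unnecessary:
  # we polish to an exact vertex instead.
  loss_fun <- function(beta) {
    res <- y - drop(A %*% beta)
    sum(w * res * (tau - (res < 0)))
  }
  b_ip <- b
  loss_ip <- loss_fun(b_ip)

  polished <- FALSE
  r_ip <- y - drop(A %*% b_ip)
  ord <- order(abs(r_ip))
  basis <- integer(0)
  Qr <- NULL
  for (i in ord) {
    cand <- c(basis, i)
    if (qr(t(A[cand, , drop = FALSE]))$rank == length(cand)) basis <- cand
    if (length(basis) == k) break
  }
  if (length(basis) == k) {
    b_v <- tryCatch(solve(A[basis, , drop = FALSE], y[basis]),
                    error = function(e) NULL)
    if (!is.null(b_v) && all(is.finite(b_v))) {
      loss_v <- loss_fun(b_v)
      if (loss_v <= loss_ip + 1e-9 * (1 + abs(loss_ip))) {
        b <- b_v; polished <- TRUE
      }
    }
  }
  if (!polished) b <- b_ip
  loss <- loss_fun(b)

  list(coefficients = drop(b), loss_standard = loss, iterations = it,
       gap = gap, polished = polished,
       converged = gap <= tol * n * scale0)
}

.design_matrix <- function(X, intercept = TRUE) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  storage.mode(X) <- "double"
  if (ncol(X) > 0L && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  X
}

.check_full_rank <- function(A) {
  qrA <- qr(A)
  if (qrA$rank < ncol(A)) {
    bad <- colnames(A)[qrA$pivot[(qrA$rank + 1L):ncol(A)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit a linear quantile regression by linear programming
#'
#' Minimizes the summed check loss \eqn{\sum_i \rho_\tau(y_i - [1, x_i]^T
#' \beta)} exactly, which is the maximum-likelihood fit when errors follow
#' an asymmetric Laplace distribution with asymmetry `tau`. The LP is
#' solved by an interior-point (Frisch-Newton) method and polished to an
#' exact basic solution, so the fitted hyperplane interpolates `p + 1`
#' observations and the optimality sign bounds
#' \eqn{\#\{r_i < 0\} \le n\tau} and \eqn{\#\{r_i > 0\} \le n(1-\tau)}
#' hold exactly.
#'
#' @param X covariate matrix or data.frame (`n x p`), without intercept.
#' @param y numeric response vector.
#' @param tau quantile level in (0, 1).
#' @param weights optional positive observation weights.
#' @return An object of class `"quantile_fit"`: `tau`, `coefficients`
#'   (length p+1, intercept first), `objective` (factor-2 summed
#'   check loss, i.e. twice the standard pinball loss), `objective_standard`,
#'   `residuals`, `fitted`, `n_below`/`n_above`/`n_zero` residual sign
#'   counts, and solver metadata.
#' @seealso [check_loss()], [bootstrap_ci()], [residual_sign_diagnostic()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 100, 2)
#' y <- 1 + X %*% c(2, -1) + rald(100, sigma = 0.2)
#' fit_quantreg(X, y, tau = 0.5)
#' @export
fit_quantreg <- function(X, y, tau, weights = NULL) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau < 1)
  A <- .design_matrix(X)
  y <- as.numeric(y)
  n <- nrow(A)
  if (n <= ncol(A)) stop("need n > p + 1 observations", call. = FALSE)
  .check_full_rank(A)
  w <- if (is.null(weights)) rep(1, n) else as.numeric(weights)

  sol <- .qr_ip_engine(A, y, tau = tau, w = w)
  beta <- stats::setNames(sol$coefficients, colnames(A))
  res <- y - drop(A %*% beta)
  ztol <- 1e-8 * (1 + stats::median(abs(y)))
  out <- list(
    tau = tau,
    coefficients = beta,
    objective = 2 * sol$loss_standard,
    objective_standard = sol$loss_standard,
    residuals = res,
    fitted = y - res,
    n = n, p = ncol(A) - 1L,
    n_below = sum(res < -ztol),
    n_above = sum(res > ztol),
    n_zero = sum(abs(res) <= ztol),
    method = list(solver = "frisch-newton interior point + vertex polish",
                  iterations = sol$iterations, duality_gap = sol$gap,
                  polished = sol$polished, converged = sol$converged)
  )
  class(out) <- "quantile_fit"
  out
}

#' @export
print.quantile_fit <- function(x, ...) {
  cat(sprintf("Quantile regression fit (tau = %g, n = %d, p = %d)\n",
              x$tau, x$n, x$p))
  cat(sprintf("  objective (factor-2 check loss): %.6g\n", x$objective))
  cat(sprintf("  residual signs: %d below, %d zero, %d above\n",
              x$n_below, x$n_zero, x$n_above))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.quantile_fit <- function(object, ...) object$coefficients

#' Residual-sign optimality diagnostic
#'
#' At an exact check-loss optimum the conditional-quantile property
#' \eqn{P(e \le 0 \mid X = x) = \tau} shows up in finite samples as the LP
#' sign bounds: at most \eqn{n\tau} strictly negative and at most
#' \eqn{n(1-\tau)} strictly positive residuals.
#'
#' @param fit a [fit_quantreg()] result.
#' @return list with `share_below` (fraction of strictly negative
#'   residuals) and `bound_ok` (do both LP optimality bounds hold?).
#' @export
residual_sign_diagnostic <- function(fit) {
  stopifnot(inherits(fit, "quantile_fit"))
  n <- fit$n
  list(share_below = fit$n_below / n,
       bound_ok = (fit$n_below <= n * fit$tau + 1e-9) &&
                  (fit$n_above <= n * (1 - fit$tau) + 1e-9))
}

# Evaluate RNG-dependent code under a seed, restoring the caller's stream.
.with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

#' Bootstrap confidence intervals for quantile-regression coefficients
#'
#' xy-pair bootstrap: resamples rows with replacement, refits, and forms
#' percentile intervals. The pair bootstrap is valid under the
#' heteroscedastic (location-scale) error structure that quantile-varying
#' coefficients imply, which is why it is preferred here over residual
#' resampling. Also returns a proportion-based two-sided p-value analogue
#' per coefficient (the usual significance flag source for per-quantile
#' coefficient tables).
#'
#' @param X covariate matrix (no intercept column).
#' @param y response vector.
#' @param tau quantile level.
#' @param B number of bootstrap replicates (>= 100).
#' @param level two-sided confidence level.
#' @param seed integer seed; resampling is deterministic given it.
#' @return class `"quantile_boot"`: `estimate`, `ci_lower`, `ci_upper`,
#'   `p_value` (proportion-based analogue, floored at 1/B), `B`, `level`,
#'   `n_redraws` (rank-deficient resamples that were redrawn), and the
#'   replicate matrix `replicates` (B x (p+1)).
#' @export
bootstrap_ci <- function(X, y, tau, B = 1000L, level = 0.95, seed = 1L) {
  stopifnot(B >= 100L, level > 0, level < 1)
  A <- .design_matrix(X)
  y <- as.numeric(y)
  n <- nrow(A)
  fit <- fit_quantreg(X, y, tau)
  k <- ncol(A)

  reps <- matrix(NA_real_, B, k, dimnames = list(NULL, colnames(A)))
  n_redraws <- 0L
  .with_seed(seed, {
    for (bb in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Ab <- A[idx, , drop = FALSE]
        if (qr(Ab)$rank == k) break
        n_redraws <- n_redraws + 1L
      }
      reps[bb, ] <- .qr_ip_engine(Ab, y[idx], tau = tau, w = rep(1, n))$coefficients
    }
  })

  alpha <- 1 - level
  ci <- apply(reps, 2L, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  pneg <- colMeans(reps <= 0)
  ppos <- colMeans(reps >= 0)
  pval <- pmin(1, pmax(2 * pmin(pneg, ppos), 1 / B))

  out <- list(tau = tau, estimate = fit$coefficients,
              ci_lower = ci[1L, ], ci_upper = ci[2L, ],
              p_value = pval, B = B, level = level, seed = seed,
              n_redraws = n_redraws, replicates = reps)
  class(out) <- "quantile_boot"
  out
}

#' @export
print.quantile_boot <- function(x, ...) {
  cat(sprintf("Bootstrap intervals (tau = %g, B = %d, level = %g)\n",
              x$tau, x$B, x$level))
  print(data.frame(estimate = round(x$estimate, 5),
                   lower = round(x$ci_lower, 5),
                   upper = round(x$ci_upper, 5),
                   p_analogue = signif(x$p_value, 3)))
  invisible(x)
}

#' Significance stars for coefficient tables
#'
#' Maps p-values to the star scheme `[0, 0.001) -> ***`,
#' `[0.001, 0.01) -> **`, `[0.01, 0.05) -> *`, else blank.
#' @param p numeric vector of p-values.
#' @return character vector of star flags.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
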