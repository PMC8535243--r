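#' Check (pinball) loss
#'
#' Asymmetric absolute loss whose population minimizer is the conditional
#' tau-quantile. Two conventions are supported: the `"factor2"` convention
#' \eqn{\rho_\tau(e) = e\,(2\tau - 2 I(e < 0))} and the `"standard"`
#' (Koenker) convention \eqn{\rho_\tau(e) = e\,(\tau - I(e < 0))}. The
#' factor-2 convention is exactly twice the standard one, so both have identical
#' minimizers; objectives reported by [fit_quantreg()] use the factor-2
#' convention.
#'
#' @param e numeric vector of residuals.
#' @param tau quantile level in (0, 1).
#' @param convention `"factor2"` or `"standard"`.
#' @return Non-negative numeric vector of losses, same length as `e`.
#' @examples
#' check_loss(3, tau = 0.5)              # 3: reduces to |e|
#' check_loss(-2, tau = 0.25)            # 3 = 2 * (-2) * (0.25 - 1)
#' check_loss(1, 0.3, "standard")        # half the factor-2 value
#' @export
check_loss <- function(e, tau, convention = c("factor2", "standard")) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0, tau < 1)
  v <- e * (tau - (e < 0))
  if (convention == "factor2") 2 * v else v
}

#' Asymmetric Laplace distribution
#'
#' Density, distribution function, quantile function and random generation
#' for the asymmetric Laplace distribution (ALD) parameterized as
#' \deqn{f(e) = \tau(1-\tau)\,\sigma^{-1} \exp\{-\rho_\tau(e-\mu)/(2\sigma)\},}
#' with \eqn{\rho_\tau} the factor-2 check loss. Under this law
#' \eqn{P(E \le \mu) = \tau}: the location parameter is the tau-quantile,
#' which is what makes check-loss minimization a maximum-likelihood fit.
#'
#' Random generation uses the exact exponential-mixture representation:
#' with probability `tau` the draw is `mu` minus an Exponential with rate
#' \eqn{(1-\tau)/\sigma}, otherwise `mu` plus an Exponential with rate
#' \eqn{\tau/\sigma}. One uniform and one exponential are consumed per draw,
#' in that order, so streams are stable under a fixed seed.
#'
#' @param x,q,e numeric vector of values.
#' @param p numeric vector of probabilities.
#' @param n number of draws.
#' @param mu location (the tau-quantile).
#' @param sigma scale, strictly positive.
#' @param tau asymmetry in (0, 1).
#' @param log logical; return log-density?
#' @return `dald`/`ald_logpdf` the (log) density, `pald` the CDF, `qald`
#'   the quantile function, `rald` random draws, `ald_moments` a list with
#'   `mean`, `var` and `skewness`.
#' @examples
#' dald(0, sigma = 0.5)                  # tau(1-tau)/sigma = 0.5
#' pald(0, tau = 0.3)                    # 0.3: location is the tau-quantile
#' qald(pald(1.3, tau = 0.7), tau = 0.7) # 1.3
#' @name ald
NULL

.ald_check <- function(sigma, tau) {
  if (any(sigma <= 0)) stop("ALD scale `sigma` must be > 0", call. = FALSE)
  if (any(tau <= 0 | tau >= 1)) stop("ALD asymmetry `tau` must lie in (0, 1)", call. = FALSE)
}

#' @rdname ald
#' @export
dald <- function(x, mu = 0, sigma = 1, tau = 0.5, log = FALSE) {
  .ald_check(sigma, tau)
  ld <- log(tau) + log1p(-tau) - log(sigma) - check_loss(x - mu, tau) / (2 * sigma)
  if (log) ld else exp(ld)
}

#' @rdname ald
#' @export
ald_logpdf <- function(e, mu = 0, sigma = 1, tau = 0.5) {
  dald(e, mu = mu, sigma = sigma, tau = tau, log = TRUE)
}

#' @rdname ald
#' @export
pald <- function(q, mu = 0, sigma = 1, tau = 0.5) {
  .ald_check(sigma, tau)
  z <- q - mu
  ifelse(z < 0,
         tau * exp((1 - tau) * z / sigma),
         1 - (1 - tau) * exp(-tau * z / sigma))
}

#' @rdname ald
#' @export
qald <- function(p, mu = 0, sigma = 1, tau = 0.5) {
  .ald_check(sigma, tau)
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  mu + ifelse(p < tau,
              sigma / (1 - tau) * log(p / tau),
              -sigma / tau * log((1 - p) / (1 - tau)))
}

#' @rdname ald
#' @export
rald <- function(n, mu = 0, sigma = 1, tau = 0.5) {
  .ald_check(sigma, tau)
  side <- stats::runif(n) < tau
  ex <- stats::rexp(n)
  mu + ifelse(side, -sigma * ex / (1 - tau), sigma * ex / tau)
}

#' @rdname ald
#' @export
ald_moments <- function(mu = 0, sigma = 1, tau = 0.5) {
  .ald_check(sigma, tau)
  # mixture of +/- exponentials: E[X^k] from exponential moments
  m1 <- (1 - tau) * sigma / tau - tau * sigma / (1 - tau)
  m2 <- (1 - tau) * 2 * sigma^2 / tau^2 + tau * 2 * sigma^2 / (1 - tau)^2
  m3 <- (1 - tau) * 6 * sigma^3 / tau^3 - tau * 6 * sigma^3 / (1 - tau)^3
  v <- m2 - m1^2
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  list(mean = mu + m1, var = v, skewness = mu3 / v^1.5)
}

#' Scale giving an ALD unit target standard deviation
#'
#' Convenience inverse of [ald_moments()]: the `sigma` for which the ALD
#' with asymmetry `tau` has standard deviation `sd`.
#' @param sd target standard deviation.
#' @param tau asymmetry in (0, 1).
#' @return positive scalar scale.
#' @export
ald_sigma_for_sd <- function(sd, tau = 0.5) {
  stopifnot(sd > 0)
  sd / sqrt(ald_moments(sigma = 1, tau = tau)$var)
}
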