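# Independent oracles and fixture builders used across the suite.

# Exhaustive basic-solution oracle for quantile regression: an optimal
# check-loss fit passes through p+1 observations, so the global minimum is
# the best exact fit over all (p+1)-subsets. Standard-convention loss.
oracle_quantreg_objective <- function(X, y, tau) {
  A <- cbind(1, as.matrix(X))
  n <- nrow(A); k <- ncol(A)
  best <- Inf
  for (S in utils::combn(n, k, simplify = FALSE)) {
    B <- A[S, , drop = FALSE]
    b <- tryCatch(solve(B, y[S]), error = function(e) NULL)
    if (is.null(b)) next
    obj <- sum(check_loss(y - drop(A %*% b), tau, "standard"))
    best <- min(best, obj)
  }
  best
}

# 2-D grid-search oracle for the p = 1 penalized problem on the
# standardized scale (the scale the penalty applies on).
oracle_penalized_objective <- function(x, y, tau, lambda,
                                       n0 = 321L, n1 = 321L) {
  xs <- (x - mean(x)) / stats::sd(x)
  n <- length(y)
  obj <- function(b0, b1) {
    sum(check_loss(y - b0 - b1 * xs, tau)) + lambda * n * abs(b1)
  }
  g0 <- seq(min(y) - 1, max(y) + 1, length.out = n0)
  g1 <- seq(-5, 5, length.out = n1)
  min(outer(g0, g1, Vectorize(obj)))
}

# Small claims CSV written from a data.frame of partial fields; defaults
# fill in a valid individual/facility mammography line.
write_claims_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  defaults <- data.frame(
    provider_id = NA_character_, procedure_code = "77055",
    place_of_service = "facility", entity_type = "individual",
    provider_type = "Diagnostic Radiology", state = "AL", zip = "35004",
    line_service_count = 10, unique_beneficiary_count = 8,
    avg_submitted_charge = 120, avg_allowed_payment = 35,
    avg_medicare_payment = 28, avg_standardized_payment = 33,
    stringsAsFactors = FALSE)
  out <- defaults[rep(1L, nrow(rows)), , drop = FALSE]
  for (cc in names(rows)) out[[cc]] <- rows[[cc]]
  utils::write.csv(out, path, row.names = FALSE)
  path
}

strong_signal_truth <- function(noise_sd = 1) {
  synthetic_truth(
    b_std = c(avg_standardized_payment = -1, gpci_work = 1,
              percent_medicaid_eligible = 1),
    g_std = stats::setNames(numeric(0), character(0)),
    noise = list(family = "asymmetric_laplace",
                 sigma = ald_sigma_for_sd(noise_sd), tau0 = 0.5))
}

null_truth <- function(noise_sd = 1) {
  synthetic_truth(
    b_std = stats::setNames(numeric(0), character(0)),
    g_std = stats::setNames(numeric(0), character(0)),
    noise = list(family = "asymmetric_laplace",
                 sigma = ald_sigma_for_sd(noise_sd), tau0 = 0.5))
}

# analysis covariate matrix + response directly from the generator (no
# claims-format positivity floor), for estimation studies
simulate_xy <- function(n, seed, truth = synthetic_truth()) {
  des <- generate_design(n, seed = seed)
  resp <- generate_response(des$X, truth, seed = seed + 1L)
  agg <- provider_type_aggregates(data.frame(
    provider_type = des$provider$provider_type, aggressiveness = resp$y,
    stringsAsFactors = FALSE))
  idx <- match(des$provider$provider_type, agg$provider_type)
  X14 <- cbind(des$X, mean_agg_provider_type = agg$mean_agg[idx],
               sd_agg_provider_type = agg$sd_agg[idx])
  list(X = as.matrix(X14), y = resp$y, truth = resp$truth)
}

true_support_idx <- function() {
  match(c("avg_standardized_payment", "gpci_work", "percent_medicaid_eligible"),
        qbill_covariates())
}
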