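# Synthetic claims generator with known quantile-varying coefficients.
#
# Location-scale construction: y = b0 + x~'b + (1 + x~'g) * eps, with x~
# the standardized covariates and eps iid from a chosen noise family.
# Under it the conditional tau-quantile of y given x is exactly linear,
#     beta(tau) = (b0 + F^-1(tau), b + g * F^-1(tau)),
# so every downstream estimator can be scored against closed-form truth.
# The two provider-type aggregate covariates (mean/sd of aggressiveness by
# provider type) are computed from the realized response -- exactly as the
# claims feature engineering computes them -- and carry true coefficient 0.

.covariate_names <- c(
  "line_service_count", "unique_beneficiary_count", "avg_allowed_payment",
  "avg_standardized_payment", "gpci_work", "ma_participation_rate",
  "average_age", "percent_female", "percent_nonhispanic_white",
  "percent_medicaid_eligible", "average_hcc_score",
  "std_risk_adjusted_per_capita_cost",
  "mean_agg_provider_type", "sd_agg_provider_type")

.exogenous_covariates <- .covariate_names[1:12]

#' Names of the 14 analysis covariates, in canonical column order
#' @return character vector of length 14.
#' @export
qbill_covariates <- function() .covariate_names

.rbeta_mean <- function(n, mean, conc) stats::rbeta(n, mean * conc, (1 - mean) * conc)

#' Default covariate specification for the claims generator
#'
#' Marginals chosen to emulate a mammography-style provider-procedure
#' claims extract: negative-binomial service counts, lognormal payment
#' amounts (allowed amounts around $35), beta-distributed state
#' proportions, GPCI and HCC indices centered at the national average of
#' 1.0, and a provider-type mix dominated by diagnostic radiology.
#' `type_offsets` adds a per-type location shift to the response; the
#' default is zero for every type because a nonzero shift leaks into the
#' realized type-aggregate covariates and makes them endogenous (the same
#' leakage caveat the real feature engineering carries).
#'
#' @param n_states number of states to simulate (at most 50).
#' @param type_offsets named numeric vector of per-provider-type response
#'   offsets (names must be provider types).
#' @return a list spec consumed by [generate_design()].
#' @export
covariate_spec_default <- function(n_states = 30L, type_offsets = NULL) {
  types <- c("Diagnostic Radiology", "Internal Medicine", "General Surgery",
             "Family Practice", "Obstetrics/Gynecology")
  off <- stats::setNames(rep(0, length(types)), types)
  if (!is.null(type_offsets)) {
    stopifnot(all(names(type_offsets) %in% types))
    off[names(type_offsets)] <- type_offsets
  }
  list(
    n_states = as.integer(n_states),
    provider_types = types,
    type_probs = c(0.70, 0.12, 0.08, 0.06, 0.04),
    type_offsets = off,
    service_count = list(size = 5, mu = 80),
    bene_fraction = list(shape1 = 1.4, shape2 = 0.6),
    allowed = list(meanlog = log(35), sdlog = 0.25),
    standardized_ratio = list(meanlog = -0.05, sdlog = 0.25),
    gpci = list(mean = 1.0, sd = 0.05),
    ma_participation = list(mean = 0.33, conc = 30),
    average_age = list(mean = 71, sd = 1.5),
    percent_female = list(mean = 0.55, conc = 250),
    percent_nonhispanic_white = list(mean = 0.72, conc = 40),
    percent_medicaid_eligible = list(mean = 0.20, conc = 60),
    hcc = list(meanlog = 0, sdlog = 0.08),
    per_capita_cost = list(mean = 9800, sd = 900)
  )
}

#' Generate synthetic covariates and provider metadata
#'
#' Draws the 12 exogenous covariates (the two provider-type aggregates are
#' response-derived and appended later by [simulate_claims_study()]):
#' state-level variables are drawn once per state and shared by that
#' state's providers, provider-level variables once per provider.
#' Deterministic given `seed`; draw order is states (one variable at a
#' time), then provider state assignment, type, counts and payments.
#'
#' @param n number of providers (>= 1).
#' @param seed integer seed.
#' @param covariate_spec see [covariate_spec_default()].
#' @return list with `X` (n x 12 data.frame), `provider` (provider_id,
#'   provider_type, state, zip), `states` (state-level covariate table) and
#'   `locality` (state -> locality_id, gpci_work).
#' @export
generate_design <- function(n, seed = 1L, covariate_spec = covariate_spec_default()) {
  stopifnot(n >= 1)
  sp <- covariate_spec
  if (is.null(sp$n_states) || sp$n_states < 1 || sp$n_states > 50)
    stop("covariate_spec$n_states must be in 1..50", call. = FALSE)
  .with_seed(seed, {
    ns <- sp$n_states
    st <- datasets::state.abb[seq_len(ns)]
    states <- data.frame(
      state = st,
      ma_participation_rate = .rbeta_mean(ns, sp$ma_participation$mean, sp$ma_participation$conc),
      average_age = stats::rnorm(ns, sp$average_age$mean, sp$average_age$sd),
      percent_female = .rbeta_mean(ns, sp$percent_female$mean, sp$percent_female$conc),
      percent_nonhispanic_white = .rbeta_mean(ns, sp$percent_nonhispanic_white$mean,
                                              sp$percent_nonhispanic_white$conc),
      percent_medicaid_eligible = .rbeta_mean(ns, sp$percent_medicaid_eligible$mean,
                                              sp$percent_medicaid_eligible$conc),
      average_hcc_score = stats::rlnorm(ns, sp$hcc$meanlog, sp$hcc$sdlog),
      std_risk_adjusted_per_capita_cost = stats::rnorm(ns, sp$per_capita_cost$mean,
                                                       sp$per_capita_cost$sd),
      stringsAsFactors = FALSE)
    locality <- data.frame(
      state = st,
      locality_id = sprintf("%02d", seq_len(ns)),
      gpci_work = pmax(0.5, stats::rnorm(ns, sp$gpci$mean, sp$gpci$sd)),
      stringsAsFactors = FALSE)

    s_idx <- sample.int(ns, n, replace = TRUE)
    ptype <- sample(sp$provider_types, n, replace = TRUE, prob = sp$type_probs)
    svc <- stats::rnbinom(n, size = sp$service_count$size, mu = sp$service_count$mu) + 1L
    bene <- pmax(1L, as.integer(round(svc * stats::rbeta(n, sp$bene_fraction$shape1,
                                                         sp$bene_fraction$shape2))))
    allowed <- stats::rlnorm(n, sp$allowed$meanlog, sp$allowed$sdlog)
    std_pay <- allowed * stats::rlnorm(n, sp$standardized_ratio$meanlog,
                                       sp$standardized_ratio$sdlog)

    X <- data.frame(
      line_service_count = as.numeric(svc),
      unique_beneficiary_count = as.numeric(bene),
      avg_allowed_payment = allowed,
      avg_standardized_payment = std_pay,
      gpci_work = locality$gpci_work[s_idx],
      states[s_idx, setdiff(names(states), "state")],
      row.names = NULL)
    names(X) <- .exogenous_covariates
    provider <- data.frame(
      provider_id = sprintf("NPI%07d", seq_len(n)),
      provider_type = ptype,
      state = st[s_idx],
      zip = sprintf("%05d", 10000 + match(st[s_idx], st) * 100),
      stringsAsFactors = FALSE)
    list(X = X, provider = provider, states = states, locality = locality)
  })
}

#' Ground truth for the synthetic response
#'
#' Coefficients are specified on the standardized-covariate scale (unit
#' signal scale): `b_std` are location slopes, `g_std` heteroscedasticity
#' loadings. Defaults: intercept 4 (a typical mammography
#' charge-to-allowed ratio), three active covariates with unit-magnitude
#' slopes, and a scale loading of 0.2 on the standardized payment amount
#' so that its true coefficient varies across quantiles; symmetric
#' asymmetric-Laplace noise with sigma = 0.1 (sd about 0.28), a
#' strong-signal regime typical of support-recovery simulation studies.
#'
#' @param b0 intercept (baseline aggressiveness ratio).
#' @param b_std named vector of nonzero location slopes (standardized
#'   scale); names must be among the 12 exogenous covariates.
#' @param g_std named vector of nonzero scale loadings, same convention.
#' @param noise list with `family` in `"asymmetric_laplace"`,
#'   `"lognormal_shifted"`, `"student_t"` and its parameters
#'   (`sigma`,`tau0` / `meanlog`,`sdlog` / `df`,`scale`).
#' @param scale_floor lower clip for the scale factor 1 + g'x (positivity).
#' @return class `"synthetic_truth"`; fields `b` and `g` are full
#'   length-15 vectors (intercept + 14 covariates) on the standardized
#'   scale, `support` the indices (1..14) of truly active covariates.
#' @export
synthetic_truth <- function(b0 = 4,
                            b_std = c(avg_standardized_payment = -1,
                                      gpci_work = 1,
                                      percent_medicaid_eligible = 1),
                            g_std = c(avg_standardized_payment = 0.2),
                            noise = list(family = "asymmetric_laplace",
                                         sigma = 0.1, tau0 = 0.5),
                            scale_floor = 0.05) {
  stopifnot(all(names(b_std) %in% .exogenous_covariates),
            all(names(g_std) %in% .exogenous_covariates))
  b <- stats::setNames(rep(0, 14), .covariate_names)
  g <- b
  b[names(b_std)] <- b_std
  g[names(g_std)] <- g_std
  family <- match.arg(noise$family,
                      c("asymmetric_laplace", "lognormal_shifted", "student_t"))
  noise$family <- family
  if (family == "asymmetric_laplace") {
    noise$sigma <- noise$sigma %||% 0.1
    noise$tau0 <- noise$tau0 %||% 0.5
  } else if (family == "lognormal_shifted") {
    # defaults put the response in the strongly right-skewed regime of
    # real billing-aggressiveness data (sample skewness around 8-9)
    noise$meanlog <- noise$meanlog %||% 0
    noise$sdlog <- noise$sdlog %||% 1.2
  } else {
    noise$df <- noise$df %||% 4
    noise$scale <- noise$scale %||% 0.25
  }
  out <- list(b0 = b0, b = c(`(Intercept)` = b0, b), g = c(`(Intercept)` = 0, g),
              noise = noise, scale_floor = scale_floor,
              support = which(b != 0 | g != 0),
              n = NA_integer_, seed = NA_integer_,
              center = NULL, scale = NULL)
  class(out) <- "synthetic_truth"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Noise quantile function of a synthetic truth
#' @param truth a [synthetic_truth()] object.
#' @param tau probability (vectorized).
#' @return F^-1(tau) of the noise family.
#' @export
noise_quantile <- function(truth, tau) {
  nz <- truth$noise
  switch(nz$family,
    asymmetric_laplace = qald(tau, 0, nz$sigma, nz$tau0),
    lognormal_shifted = stats::qlnorm(tau, nz$meanlog, nz$sdlog) -
      exp(nz$meanlog + nz$sdlog^2 / 2),
    student_t = nz$scale * stats::qt(tau, nz$df))
}

.noise_sample <- function(truth, n) {
  nz <- truth$noise
  switch(nz$family,
    asymmetric_laplace = rald(n, 0, nz$sigma, nz$tau0),
    lognormal_shifted = stats::rlnorm(n, nz$meanlog, nz$sdlog) -
      exp(nz$meanlog + nz$sdlog^2 / 2),
    student_t = nz$scale * stats::rt(n, nz$df))
}

#' Generate the synthetic response from covariates and a truth object
#'
#' \deqn{y_i = b_0 + \tilde x_i^T b + (1 + \tilde x_i^T g)\,\varepsilon_i,}
#' where \eqn{\tilde x} are the covariates standardized by their sample
#' mean and standard deviation (stored in the returned realized truth so
#' true coefficients can be expressed on either scale). The scale factor
#' is clipped below at `truth$scale_floor` with a logged count; more than
#' 10% clipped is an error.
#'
#' @param X covariate matrix/data.frame (the 12 exogenous covariates, or
#'   any columns whose names cover the truth's active set).
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed for the noise draws.
#' @return list with `y`, `epsilon`, `scale_factor`, `n_scale_clipped`,
#'   and the realized `truth` (center/scale/n/seed filled in).
#' @export
generate_response <- function(X, truth, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"))
  Xm <- .design_matrix(X, intercept = FALSE)
  nms <- colnames(Xm)
  active <- names(truth$b[-1L])[truth$b[-1L] != 0 | truth$g[-1L] != 0]
  if (!all(active %in% nms))
    stop("covariates missing for active truth coefficients: ",
         paste(setdiff(active, nms), collapse = ", "), call. = FALSE)
  ctr <- colMeans(Xm)
  scl <- apply(Xm, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xm, 2L, ctr), 2L, scl, "/")
  b <- truth$b[-1L][nms]; b[is.na(b)] <- 0
  g <- truth$g[-1L][nms]; g[is.na(g)] <- 0
  loc <- truth$b0 + drop(Xs %*% b)
  sf_raw <- 1 + drop(Xs %*% g)
  sf <- pmax(sf_raw, truth$scale_floor)
  n_clip <- sum(sf_raw < truth$scale_floor)
  if (n_clip > 0.10 * nrow(Xm))
    stop("scale factor clipped for >10% of observations; reduce g", call. = FALSE)
  eps <- .with_seed(seed, .noise_sample(truth, nrow(Xm)))
  y <- loc + sf * eps
  truth$n <- nrow(Xm); truth$seed <- seed
  truth$center <- stats::setNames(ctr, nms)
  truth$scale <- stats::setNames(scl, nms)
  list(y = y, epsilon = eps, scale_factor = sf, n_scale_clipped = n_clip,
       truth = truth)
}

#' True quantile-coefficient function of the generator
#'
#' Under the location-scale construction the true coefficient vector at
#' quantile `tau` is \eqn{\beta(\tau) = b + g\,F^{-1}(\tau)} on the
#' standardized scale (intercept \eqn{b_0 + F^{-1}(\tau)}); `scale =
#' "raw"` converts with the realized standardization constants.
#'
#' @param truth a realized `synthetic_truth` (as returned inside
#'   [generate_response()] or [simulate_claims_study()]).
#' @param tau quantile level.
#' @param scale `"standardized"` or `"raw"`.
#' @return named coefficient vector (intercept first).
#' @export
true_beta <- function(truth, tau, scale = c("standardized", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(truth, "synthetic_truth"))
  Finv <- noise_quantile(truth, tau)
  beta_std <- truth$b + truth$g * Finv
  beta_std[1L] <- truth$b0 + Finv
  if (scale == "standardized") return(beta_std)
  if (is.null(truth$center))
    stop("raw-scale truth needs a realized truth (center/scale unset)", call. = FALSE)
  nms <- names(truth$center)
  slopes <- beta_std[-1L][nms] / truth$scale
  b0 <- beta_std[1L] - sum(beta_std[-1L][nms] * truth$center / truth$scale)
  stats::setNames(c(b0, slopes), c("(Intercept)", nms))
}

#' Sample skewness
#' @param x numeric vector.
#' @return m3 / m2^(3/2), the moment-based skewness coefficient.
#' @export
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

#' Simulate a complete analysis-ready claims study
#'
#' Generates covariates and response, computes the realized provider-type
#' aggregate covariates from the simulated aggressiveness (true
#' coefficient zero), applies any per-type offsets, clips the response at
#' a small positive floor (aggressiveness is a positive ratio; the count
#' is recorded and is zero under default parameters), and assembles the
#' canonical analysis table.
#'
#' @param n number of providers.
#' @param seed integer seed (design uses `seed`, noise `seed + 1`).
#' @param truth a [synthetic_truth()] object.
#' @param covariate_spec see [covariate_spec_default()].
#' @param y_floor positive response floor.
#' @return list with `design` (the analysis table: provider_id,
#'   provider_type, y, then the 14 covariates), `truth` (realized, with
#'   standardization constants for all 14 covariates), `raw` (the
#'   generator tables: provider, states, locality), `n_y_clipped`,
#'   `n_scale_clipped`.
#' @export
simulate_claims_study <- function(n, seed = 7L, truth = synthetic_truth(),
                                  covariate_spec = covariate_spec_default(),
                                  y_floor = 0.01) {
  des <- generate_design(n, seed, covariate_spec)
  resp <- generate_response(des$X, truth, seed = seed + 1L)
  y <- resp$y + covariate_spec$type_offsets[des$provider$provider_type]
  n_y_clip <- sum(y < y_floor)
  y <- pmax(y, y_floor)

  agg <- provider_type_aggregates(data.frame(
    provider_type = des$provider$provider_type, aggressiveness = y,
    stringsAsFactors = FALSE))
  idx <- match(des$provider$provider_type, agg$provider_type)
  X14 <- cbind(des$X,
               mean_agg_provider_type = agg$mean_agg[idx],
               sd_agg_provider_type = agg$sd_agg[idx])

  truth_r <- resp$truth
  truth_r$center <- c(truth_r$center,
                      colMeans(X14[, 13:14]))
  sc2 <- apply(X14[, 13:14], 2L, stats::sd)
  sc2[sc2 == 0] <- 1
  truth_r$scale <- c(truth_r$scale, sc2)

  design <- data.frame(provider_id = des$provider$provider_id,
                       provider_type = des$provider$provider_type,
                       y = unname(y),
                       X14, row.names = NULL, stringsAsFactors = FALSE)
  class(design) <- c("analysis_table", "data.frame")
  list(design = design, truth = truth_r,
       raw = list(provider = des$provider, states = des$states,
                  locality = des$locality),
       n_y_clipped = n_y_clip, n_scale_clipped = resp$n_scale_clipped)
}

#' Write generator output as raw claims-shaped CSV files
#'
#' Inverts the feature engineering: one claim line per provider whose
#' submitted charge equals aggressiveness times the allowed amount (so
#' [assemble_design()] under the default denominator reproduces `y`
#' exactly), plus the state-covariate and locality lookup tables that
#' reproduce the covariates, plus the realized truth as JSON. All rows are
#' individual-entity, facility place-of-service lines for the focal
#' procedure, so they pass [filter_study_population()] unchanged.
#'
#' @param sim result of [simulate_claims_study()].
#' @param outdir output directory (created if needed).
#' @param procedure_code HCPCS-like code to stamp on every claim line.
#' @return invisibly, the paths of the four written files.
#' @export
emit_raw_files <- function(sim, outdir, procedure_code = "77055") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  d <- sim$design
  claims <- data.frame(
    provider_id = d$provider_id,
    procedure_code = procedure_code,
    place_of_service = "facility",
    entity_type = "individual",
    provider_type = d$provider_type,
    state = sim$raw$provider$state,
    zip = sim$raw$provider$zip,
    line_service_count = d$line_service_count,
    unique_beneficiary_count = d$unique_beneficiary_count,
    avg_submitted_charge = d$y * d$avg_allowed_payment,
    avg_allowed_payment = d$avg_allowed_payment,
    avg_medicare_payment = 0.8 * d$avg_allowed_payment,
    avg_standardized_payment = d$avg_standardized_payment,
    stringsAsFactors = FALSE)
  paths <- file.path(outdir, c("claims.csv", "state_covariates.csv",
                               "locality.csv", "truth.json"))
  utils::write.csv(claims, paths[1], row.names = FALSE)
  utils::write.csv(sim$raw$states, paths[2], row.names = FALSE)
  utils::write.csv(sim$raw$locality, paths[3], row.names = FALSE)
  tr <- sim$truth
  jsonlite::write_json(
    list(b0 = tr$b0, b = as.list(tr$b), g = as.list(tr$g), noise = tr$noise,
         scale_floor = tr$scale_floor, support = tr$support,
         n = tr$n, seed = tr$seed,
         center = as.list(tr$center), scale = as.list(tr$scale)),
    paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a truth JSON written by [emit_raw_files()]
#' @param path truth.json path.
#' @return a realized `synthetic_truth` object.
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(b0 = j$b0, b = unlist(j$b), g = unlist(j$g),
              noise = j$noise, scale_floor = j$scale_floor,
              support = j$support, n = j$n, seed = j$seed,
              center = unlist(j$center), scale = unlist(j$scale))
  class(out) <- "synthetic_truth"
  out
}
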