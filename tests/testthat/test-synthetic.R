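test_that("design generation is deterministic and respects distribution supports", {
  d1 <- generate_design(5, seed = 1)
  d2 <- generate_design(5, seed = 1)
  expect_identical(d1, d2)
  d3 <- generate_design(5, seed = 2)
  expect_false(identical(d1$X, d3$X))

  d <- generate_design(800, seed = 3)
  prop_cols <- c("ma_participation_rate", "percent_female",
                 "percent_nonhispanic_white", "percent_medicaid_eligible")
  for (cc in prop_cols) {
    expect_true(all(d$X[[cc]] >= 0 & d$X[[cc]] <= 1))
  }
  expect_true(all(d$X$line_service_count >= 1))
  expect_true(all(d$X$unique_beneficiary_count >= 1))
  expect_true(all(d$X$unique_beneficiary_count <= d$X$line_service_count))
  expect_true(all(d$X$avg_allowed_payment > 0))
  expect_true(all(d$X$gpci_work > 0))
  expect_identical(names(d$X), qbill_covariates()[1:12])
})

test_that("GPCI work index centers on the national average of 1", {
  d <- generate_design(5000, seed = 4, covariate_spec = covariate_spec_default(n_states = 50))
  se <- sd(d$X$gpci_work) / sqrt(50)   # state-level draws, 50 effective values
  expect_lt(abs(mean(d$locality$gpci_work) - 1), 3 * 0.05 / sqrt(50))
  expect_gt(mean(d$X$gpci_work), 0.9)
})

test_that("degenerate noise reproduces the location part exactly", {
  d <- generate_design(50, seed = 5)
  tr <- synthetic_truth(noise = list(family = "student_t", df = 4, scale = 0))
  resp <- generate_response(d$X, tr, seed = 6)
  Xs <- scale(as.matrix(d$X))
  b <- tr$b[-1L][colnames(d$X)]
  expect_equal(resp$y, drop(4 + Xs %*% b), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(noise_quantile(tr, c(0.1, 0.9)), c(0, 0))
})

test_that("ALD noise with g = 0 puts tau0 of the mass below the location plane", {
  d <- generate_design(10000, seed = 8)
  tr <- synthetic_truth(g_std = setNames(numeric(0), character(0)),
                        noise = list(family = "asymmetric_laplace",
                                     sigma = 0.4, tau0 = 0.3))
  resp <- generate_response(d$X, tr, seed = 9)
  Xs <- scale(as.matrix(d$X))
  loc <- drop(4 + Xs %*% tr$b[-1L][colnames(d$X)])
  share <- mean(resp$y < loc)
  expect_lt(abs(share - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("the conditional tau-quantile is linear with slope b + g F^-1(tau)", {
  d <- generate_design(20000, seed = 10)
  tr <- synthetic_truth()
  resp <- generate_response(d$X, tr, seed = 11)
  # with ALD noise the identity P(y <= x'beta(tau)) = tau holds exactly
  Xs <- cbind(1, scale(as.matrix(d$X)))
  for (tau in c(0.25, 0.75, 0.95)) {
    bt <- true_beta(resp$truth, tau)
    plane <- drop(Xs %*% c(bt[1L], bt[-1L][colnames(d$X)]))
    expect_lt(abs(mean(resp$y <= plane) - tau),
              3 * sqrt(tau * (1 - tau) / 20000))
  }
  # binned-slope oracle on the scale-loaded covariate at tau = 0.75:
  # within narrow bins of x_j, the empirical 0.75-quantile moves with the
  # true standardized slope
  xj <- scale(as.matrix(d$X))[, "avg_standardized_payment"]
  other <- drop(scale(as.matrix(d$X))[, setdiff(colnames(d$X), "avg_standardized_payment")] %*%
                  true_beta(resp$truth, 0.75)[-1L][setdiff(colnames(d$X), "avg_standardized_payment")])
  resid <- resp$y - other   # strip the other covariates' true contribution
  bins <- cut(xj, breaks = quantile(xj, seq(0, 1, 0.1)), include.lowest = TRUE)
  q_bin <- tapply(resid, bins, quantile, probs = 0.75)
  x_bin <- tapply(xj, bins, mean)
  slope_hat <- unname(coef(lm(q_bin ~ x_bin))[2L])
  slope_true <- unname(true_beta(resp$truth, 0.75)["avg_standardized_payment"])
  expect_lt(abs(slope_hat - slope_true), 0.1 * abs(slope_true))
})

test_that("raw-scale truth reproduces the standardized conditional quantile", {
  sim <- simulate_xy(2000, seed = 12)
  bt_raw <- true_beta(sim$truth, 0.5, scale = "raw")
  bt_std <- true_beta(sim$truth, 0.5)
  Xr <- cbind(1, sim$X[, names(bt_raw)[-1L]])
  plane_raw <- drop(Xr %*% bt_raw)
  Xs <- cbind(1, scale(sim$X[, names(bt_raw)[-1L]],
                       center = sim$truth$center, scale = sim$truth$scale))
  plane_std <- drop(Xs %*% c(bt_std[1L], bt_std[-1L][names(bt_raw)[-1L]]))
  expect_equal(plane_raw, plane_std, tolerance = 1e-9)
})

test_that("shifted-lognormal noise produces the heavy right-skew regime", {
  tr <- synthetic_truth(noise = list(family = "lognormal_shifted"))
  d <- generate_design(2000, seed = 13)
  resp <- generate_response(d$X, tr, seed = 14)
  expect_gt(sample_skewness(resp$y), 2)
  # noise quantile function matches the shifted-lognormal closed form
  expect_equal(noise_quantile(tr, 0.5), 1 - exp(0.72), tolerance = 1e-12)
})

test_that("scale-factor positivity is enforced with a clipping budget", {
  d <- generate_design(200, seed = 15)
  tr_extreme <- synthetic_truth(g_std = c(avg_standardized_payment = 5))
  expect_error(generate_response(d$X, tr_extreme, seed = 16), ">10%")
  tr_ok <- synthetic_truth()
  r <- generate_response(d$X, tr_ok, seed = 16)
  expect_equal(r$n_scale_clipped, 0L)
  expect_true(all(r$scale_factor >= tr_ok$scale_floor))
})

test_that("emitted raw files reproduce the analysis table through the loaders", {
  sim <- simulate_claims_study(200, seed = 7)
  td <- tempfile()
  emit_raw_files(sim, td)
  cl <- load_claims(file.path(td, "claims.csv"))
  expect_equal(nrow(cl), 200L)                       # every line validates
  flt <- filter_study_population(cl, "77055")
  expect_equal(nrow(flt), 200L)                      # and passes the filter
  at <- assemble_design(flt, load_state_covariates(file.path(td, "state_covariates.csv")),
                        load_locality(file.path(td, "locality.csv")))
  o <- match(sim$design$provider_id, at$provider_id)
  expect_equal(as.matrix(at[o, c("y", qbill_covariates())]),
               as.matrix(sim$design[, c("y", qbill_covariates())]),
               tolerance = 1e-9, ignore_attr = TRUE)
  tr2 <- read_truth(file.path(td, "truth.json"))
  expect_equal(tr2$b, sim$truth$b)
  expect_equal(tr2$center, sim$truth$center, tolerance = 1e-12)
  expect_equal(tr2$support, sim$truth$support, ignore_attr = TRUE)
})

test_that("full simulation is deterministic given the seed", {
  s1 <- simulate_claims_study(100, seed = 42)
  s2 <- simulate_claims_study(100, seed = 42)
  expect_identical(s1$design, s2$design)
  expect_identical(s1$truth$center, s2$truth$center)
})
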