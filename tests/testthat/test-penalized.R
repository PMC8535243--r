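test_that("penalty limits: lambda = 0 is the plain fit, huge lambda only an intercept", {
  set.seed(21)
  X <- matrix(rnorm(150), 50, 3)
  y <- 2 + X %*% c(1.5, 0, -1) + rald(50, sigma = 0.4)
  for (tau in c(0.25, 0.5, 0.9)) {
    f0 <- fit_l1_quantreg(X, y, tau, lambda = 0)
    fu <- fit_quantreg(X, y, tau)
    expect_equal(unname(f0$coefficients), unname(fu$coefficients),
                 tolerance = 1e-6)
    fL <- fit_l1_quantreg(X, y, tau, lambda = 1e6)
    expect_equal(unname(fL$coefficients[-1L]), c(0, 0, 0))
    # the free intercept solves the intercept-only problem: its check loss
    # cannot beat the best over the observed values (where a vertex lies)
    obj_best <- min(vapply(y, function(b0) sum(check_loss(y - b0, tau)),
                           numeric(1)))
    expect_equal(sum(check_loss(y - fL$coefficients[1L], tau)), obj_best,
                 tolerance = 1e-9)
  }
})

test_that("penalized objective matches a 2-D grid-search oracle at p = 1", {
  set.seed(77)
  for (r in 1:12) {
    n <- sample(6:10, 1)
    x <- rnorm(n); y <- rnorm(n)
    tau <- sample(c(0.3, 0.5, 0.8), 1)
    lambda <- runif(1, 0.02, 0.6)
    f <- fit_l1_quantreg(matrix(x), y, tau, lambda)
    oracle <- oracle_penalized_objective(x, y, tau, lambda)
    expect_lte(f$objective, oracle + 1e-9)   # exact LP beats any grid point
    expect_lt(oracle - f$objective, 0.05)    # and the grid gets close back
  }
})

test_that("threshold rule zeroes strictly-below-cut slopes, never the intercept", {
  b <- c(`(Intercept)` = 0.0004, x1 = 0.0005, x2 = 0.5)
  th <- threshold_support(b)
  expect_equal(unname(th$beta), c(0.0004, 0, 0.5))
  expect_equal(th$support, 2L)
  b2 <- c(`(Intercept)` = 1, x1 = 0.001, x2 = -0.001)
  th2 <- threshold_support(b2)   # boundary values are kept: rule is strict "<"
  expect_equal(th2$support, c(1L, 2L))
  th3 <- threshold_support(c(`(Intercept)` = 2, x1 = 0, x2 = 0))
  expect_length(th3$support, 0)
})

test_that("modified BIC matches direct arithmetic and is monotone in |S|", {
  expect_equal(bic_quantile(1, 0, 100), 0)
  expect_equal(bic_quantile(1, 2, 100),
               2 * log(100) / 200 * log(log(100)), tolerance = 1e-12)
  expect_equal(bic_quantile(1, 2, 100), 0.0703292, tolerance = 1e-6)
  bics <- vapply(0:5, function(s) bic_quantile(2.5, s, 500), numeric(1))
  expect_true(all(diff(bics) > 0))
  expect_equal(bic_quantile(3, 1, 200, Cn_spec = 5),
               log(3) + log(200) / 400 * 5)
  expect_equal(bic_quantile(3, 2, 200, Cn_spec = "log_p", p = 14),
               log(3) + 2 * log(200) / 400 * log(14))
  expect_warning(v <- bic_quantile(0, 1, 50), "interpolation")
  expect_identical(v, -Inf)
  expect_error(bic_quantile(1, 1, 2), "n >= 3")
})

test_that("a single-point grid returns that lambda", {
  set.seed(2)
  X <- matrix(rnorm(200), 100, 2)
  y <- 1 + X[, 1] + rnorm(100)
  s <- select_lambda(X, y, 0.5, lambda_grid = 0.05)
  expect_equal(s$lambda_hat, 0.05)
  expect_equal(nrow(s$path), 1L)
})

test_that("strong-signal selection recovers the true support (seed 11)", {
  sim <- simulate_xy(1000, seed = 11, truth = strong_signal_truth())
  s <- select_lambda(sim$X, sim$y, 0.5)
  expect_setequal(s$support, true_support_idx())
  # zero pattern of the reported coefficients matches the support exactly
  expect_setequal(which(s$coefficients[-1L] != 0), s$support)
  # BIC at lambda_hat is the path minimum and is recomputable from its parts
  i <- which(s$path$lambda == s$lambda_hat)
  expect_equal(s$path$bic[i], min(s$path$bic))
  expect_equal(s$path$bic[i],
               log(s$path$loss[i]) +
                 s$path$support_size[i] * log(s$n) / (2 * s$n) * s$Cn,
               tolerance = 1e-12)
})

test_that("refit reporting keeps the selected support but drops shrinkage", {
  sim <- simulate_xy(800, seed = 13, truth = strong_signal_truth())
  s0 <- select_lambda(sim$X, sim$y, 0.5, refit = FALSE)
  s1 <- select_lambda(sim$X, sim$y, 0.5, refit = TRUE)
  expect_identical(s0$support, s1$support)
  rf <- fit_quantreg(sim$X[, s1$support, drop = FALSE], sim$y, 0.5)
  expect_equal(unname(s1$coefficients[1L + s1$support]),
               unname(rf$coefficients[-1L]), tolerance = 1e-9)
})

test_that("slope L1 norm is non-increasing along the path; endpoints behave", {
  set.seed(41)
  X <- matrix(rnorm(600), 200, 3)
  y <- 0.5 + X %*% c(1, -0.5, 0) + rald(200, sigma = 0.5)
  s <- select_lambda(X, y, 0.3, lambda_grid = lambda_grid_default(length_out = 30))
  expect_true(all(diff(s$path$l1_norm) <= 1e-8))
  expect_error(select_lambda(X, y, 0.3, lambda_grid = numeric(0)), "empty")
})

test_that("selection table reports zeros off-support across quantiles", {
  sim <- simulate_xy(500, seed = 17, truth = strong_signal_truth())
  sels <- lapply(c(0.25, 0.75), function(tt) select_lambda(sim$X, sim$y, tt))
  tab <- selection_table(sels)
  expect_identical(names(tab), c("variable", "tau_0.25", "tau_0.75"))
  expect_equal(nrow(tab), 15L)
  for (j in 1:2) {
    sel <- sels[[j]]
    col <- tab[[j + 1L]][-1L]
    expect_setequal(which(col != 0), sel$support)
  }
  s_empty <- select_lambda(sim$X[, 1:3], rnorm(500), 0.5)
  tab2 <- selection_table(list(s_empty))
  expect_true(all(tab2[[2L]][-1L] == 0) || length(s_empty$support) > 0)
})
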