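test_that("invalid claim rows are rejected and counted by reason", {
  path <- write_claims_fixture(data.frame(
    provider_id = c("A", "B", "C"),
    avg_submitted_charge = c(120, 0, 150)))
  expect_message(cl <- load_claims(path), "rejected 1")
  expect_equal(nrow(cl), 2L)
  v <- attr(cl, "validation")
  expect_equal(v$n_read, 3L)
  expect_equal(v$rejections$nonpositive_currency, 1L)

  path2 <- write_claims_fixture(data.frame(
    provider_id = c("A", "B", "C", "D"),
    place_of_service = c("facility", "spaceship", "O", "F"),
    line_service_count = c(10, 10, 10, NA)))
  suppressMessages(cl2 <- load_claims(path2))
  expect_equal(nrow(cl2), 2L)
  v2 <- attr(cl2, "validation")
  expect_equal(v2$rejections$unknown_enum, 1L)
  expect_equal(v2$rejections$missing_field, 1L)
  # PUF single-letter codes normalize onto the canonical enums
  expect_setequal(cl2$place_of_service, c("facility", "non_facility"))

  path3 <- write_claims_fixture(data.frame(
    provider_id = "A", line_service_count = 5, unique_beneficiary_count = 9))
  suppressMessages(cl3 <- load_claims(path3))
  expect_equal(nrow(cl3), 0L)
  expect_equal(attr(cl3, "validation")$rejections$invalid_counts, 1L)
})

test_that("schema renames reproduce the canonical-header result", {
  rows <- data.frame(provider_id = c("P1", "P2"),
                     avg_submitted_charge = c(100, 140))
  canon <- write_claims_fixture(rows)
  df <- utils::read.csv(canon, stringsAsFactors = FALSE)
  puf <- puf_schema_config()
  names(df) <- unname(puf[names(df)])
  df$place_of_service <- "F"; df$nppes_entity_code <- "I"
  renamed <- tempfile(fileext = ".csv")
  utils::write.csv(df, renamed, row.names = FALSE)
  a <- load_claims(canon)
  b <- load_claims(renamed, schema_config = puf)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("missing required columns and empty files are fatal", {
  df <- data.frame(provider_id = "A", procedure_code = "77055")
  p <- tempfile(fileext = ".csv")
  utils::write.csv(df, p, row.names = FALSE)
  expect_error(load_claims(p), "avg_submitted_charge")
  p2 <- tempfile(fileext = ".csv")
  writeLines("provider_id,procedure_code", p2)
  expect_error(load_claims(p2), "empty")
  expect_error(load_claims(tempfile()), "not found")
})

test_that("study-population filter keeps individual facility rows for the procedure", {
  path <- write_claims_fixture(data.frame(
    provider_id = c("P1", "P2", "P3", "P4"),
    procedure_code = c("77055", "77055", "77055", "99213"),
    place_of_service = c("facility", "non_facility", "facility", "facility"),
    entity_type = c("individual", "individual", "organization", "individual")))
  cl <- load_claims(path)
  f <- filter_study_population(cl, "77055")
  expect_equal(nrow(f), 1L)
  expect_equal(f$provider_id, "P1")
  fc <- attr(f, "filter_counts")
  expect_equal(unlist(fc), c(input = 4, procedure = 3, individual = 2, facility = 1))
  expect_error(filter_study_population(cl, "00000"), "no rows left")
})

test_that("multiple qualifying rows collapse by service-weighted means", {
  path <- write_claims_fixture(data.frame(
    provider_id = c("P1", "P1"),
    line_service_count = c(10, 30),
    unique_beneficiary_count = c(8, 20),
    avg_submitted_charge = c(100, 200)))
  f <- filter_study_population(load_claims(path), "77055")
  expect_equal(nrow(f), 1L)
  expect_equal(f$avg_submitted_charge, 175)  # (10*100 + 30*200) / 40
  expect_equal(f$line_service_count, 40)
  expect_equal(f$unique_beneficiary_count, 28)
})

test_that("aggressiveness is the charge-to-payment ratio for each denominator", {
  df <- data.frame(avg_submitted_charge = c(100, 50),
                   avg_allowed_payment = c(25, 50),
                   avg_medicare_payment = c(20, 10),
                   avg_standardized_payment = c(40, 25))
  expect_equal(compute_aggressiveness(df), c(4, 1))
  expect_equal(compute_aggressiveness(df, "medicare_payment"), c(5, 5))
  expect_equal(compute_aggressiveness(df, "standardized"), c(2.5, 2))
  df$avg_allowed_payment[1] <- 0
  expect_error(compute_aggressiveness(df), "denominator")
})

test_that("provider-type aggregates use sample sd with singleton types at 0", {
  df <- data.frame(provider_type = c("A", "A", "A", "B"),
                   aggressiveness = c(2, 4, 6, 5.5))
  agg <- provider_type_aggregates(df)
  expect_equal(agg$mean_agg[agg$provider_type == "A"], 4)
  expect_equal(agg$sd_agg[agg$provider_type == "A"], 2)
  expect_equal(agg$mean_agg[agg$provider_type == "B"], 5.5)
  expect_equal(agg$sd_agg[agg$provider_type == "B"], 0)
})

test_that("type means are recovered from simulated two-type data", {
  set.seed(123)
  n <- 2000
  ptype <- rep(c("low", "high"), each = n / 2)
  agg_true <- c(low = 3, high = 6)
  y <- agg_true[ptype] + rnorm(n, sd = 0.8)
  agg <- provider_type_aggregates(data.frame(provider_type = ptype,
                                             aggressiveness = y))
  se <- 0.8 / sqrt(n / 2)
  expect_lt(abs(agg$mean_agg[agg$provider_type == "low"] - 3), 3 * se)
  expect_lt(abs(agg$mean_agg[agg$provider_type == "high"] - 6), 3 * se)
})

test_that("assemble_design joins lookups, drops unmatched rows, stays consistent", {
  claims_path <- write_claims_fixture(data.frame(
    provider_id = c("P1", "P2", "P3"),
    state = c("AL", "AK", "WY"),   # WY missing from the lookups
    avg_submitted_charge = c(100, 140, 90)))
  cl <- load_claims(claims_path)
  st <- data.frame(state = c("AL", "AK"), ma_participation_rate = c(0.3, 0.2),
                   average_age = c(71, 70), percent_female = c(0.55, 0.52),
                   percent_nonhispanic_white = c(0.7, 0.6),
                   percent_medicaid_eligible = c(0.2, 0.25),
                   average_hcc_score = c(1.0, 1.1),
                   std_risk_adjusted_per_capita_cost = c(9500, 9800))
  lo <- data.frame(state = c("AL", "AK"), locality_id = c("01", "02"),
                   gpci_work = c(1.0, 1.05))
  flt <- filter_study_population(cl, "77055")
  expect_message(at <- assemble_design(flt, st, lo), "dropped 1")
  expect_equal(nrow(at), 2L)
  expect_equal(ncol(at), 3L + 14L)
  expect_identical(names(at)[4:17], qbill_covariates())
  expect_equal(attr(at, "join_report")$n_dropped, 1L)
  # self-consistency: each row's type aggregate equals the group mean
  for (i in seq_len(nrow(at))) {
    grp <- at$y[at$provider_type == at$provider_type[i]]
    expect_equal(at$mean_agg_provider_type[i], mean(grp))
  }
  # all-unmatched joins are a schema error, not silent dropping
  lo_bad <- transform(lo, state = c("XX", "YY"))
  expect_error(assemble_design(flt, st, lo_bad), "schema mismatch")
})

test_that("percent columns given on the 0-100 scale are detected and rescaled", {
  st <- data.frame(state = "AL", ma_participation_rate = 33,
                   average_age = 71, percent_female = 55,
                   percent_nonhispanic_white = 70,
                   percent_medicaid_eligible = 20,
                   average_hcc_score = 1, std_risk_adjusted_per_capita_cost = 9500)
  p <- tempfile(fileext = ".csv")
  utils::write.csv(st, p, row.names = FALSE)
  expect_warning(out <- load_state_covariates(p), "0-100")
  expect_equal(out$ma_participation_rate, 0.33)
  st$percent_female <- -5
  utils::write.csv(st, p, row.names = FALSE)
  suppressWarnings(expect_error(load_state_covariates(p), "\\[0,1\\]"))
})

test_that("assembly is invariant to input row order", {
  sim <- simulate_claims_study(80, seed = 21)
  td <- tempfile(); emit_raw_files(sim, td)
  cl <- load_claims(file.path(td, "claims.csv"))
  st <- load_state_covariates(file.path(td, "state_covariates.csv"))
  lo <- load_locality(file.path(td, "locality.csv"))
  a1 <- assemble_design(filter_study_population(cl, "77055"), st, lo)
  set.seed(5)
  perm <- sample.int(nrow(cl))
  cl_shuf <- cl[perm, , drop = FALSE]
  class(cl_shuf) <- class(cl)
  a2 <- assemble_design(filter_study_population(cl_shuf, "77055"), st, lo)
  a2 <- a2[match(a1$provider_id, a2$provider_id), , drop = FALSE]
  rownames(a2) <- NULL
  expect_equal(as.data.frame(a1), as.data.frame(a2))
})
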