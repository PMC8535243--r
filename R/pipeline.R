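# Orchestration: simulate or ingest -> assemble -> OLS -> per-quantile
# fits with bootstrap bands -> penalized selection -> report artifacts.
#
# Every artifact is CSV/JSON, each CSV carries a `# qbill` provenance
# comment line (config hash + seed) and the full config snapshot is
# written next to the outputs, so any run is reproducible from its
# output directory alone.

#' Build a pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic study) or `"ingest"`
#'   (read claims/state/locality CSVs).
#' @param n number of providers (simulate mode).
#' @param seed integer master seed; every random stage derives from it.
#' @param claims,state_cov,locality input CSV paths (ingest mode).
#' @param procedure_code focal procedure (ingest mode filter).
#' @param denominator aggressiveness denominator, see
#'   [compute_aggressiveness()].
#' @param quantiles quantile levels to fit; default the seven-level set
#'   {0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99}.
#' @param bootstrap_B,bootstrap_level bootstrap replicates and band level.
#' @param lambda_min,lambda_max,lambda_points penalty grid (log-spaced).
#' @param Cn_spec,threshold,refit see [select_lambda()].
#' @param lilliefors_reps Monte-Carlo null size for the normality test.
#' @param truth optional [synthetic_truth()] (simulate mode).
#' @param outdir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       n = 500L, seed = 7L,
                       claims = NULL, state_cov = NULL, locality = NULL,
                       procedure_code = "77055",
                       denominator = "allowed",
                       quantiles = c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99),
                       bootstrap_B = 1000L, bootstrap_level = 0.95,
                       lambda_min = 0.01, lambda_max = 1, lambda_points = 100L,
                       Cn_spec = "loglog_n", threshold = 0.001, refit = FALSE,
                       lilliefors_reps = 10000L,
                       truth = NULL, outdir = tempfile("qbill_run_")) {
  cfg <- list(mode = match.arg(mode), n = as.integer(n), seed = as.integer(seed),
              claims = claims, state_cov = state_cov, locality = locality,
              procedure_code = procedure_code, denominator = denominator,
              quantiles = quantiles, bootstrap_B = as.integer(bootstrap_B),
              bootstrap_level = bootstrap_level,
              lambda_min = lambda_min, lambda_max = lambda_max,
              lambda_points = as.integer(lambda_points),
              Cn_spec = Cn_spec, threshold = threshold, refit = refit,
              lilliefors_reps = as.integer(lilliefors_reps),
              truth = truth, outdir = outdir)
  class(cfg) <- "run_config"
  cfg
}

# hash of the config (seed- and path-independent parts included verbatim);
# no digest dependency: serialize to a canonical YAML tempfile and md5 it.
.config_hash <- function(cfg) {
  ser <- cfg[setdiff(names(cfg), c("outdir", "truth"))]
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(ser, tf)
  unname(tools::md5sum(tf))
}

.write_csv_prov <- function(df, path, hash, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# qbill config=%s seed=%d", hash, seed), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Read a pipeline CSV artifact (skipping the provenance comment)
#' @param path CSV path.
#' @return data.frame.
#' @export
read_artifact <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' OLS-versus-quantile comparison table
#'
#' Long-format table with one row per (variable, estimate source): the
#' OLS estimate with its classical 95% confidence interval, and each
#' quantile estimate with its bootstrap band. Quantile estimates falling
#' outside the OLS interval are flagged — the tabular form of the usual
#' coefficient-versus-quantile panel plot.
#'
#' @param ols an [fit_ols()] result.
#' @param qboots named list of [bootstrap_ci()] results (one per tau).
#' @return data.frame: `variable`, `tau` (`"OLS"` or the level),
#'   `estimate`, `lower`, `upper`, `outside_ols_ci`.
#' @export
comparison_report <- function(ols, qboots) {
  stopifnot(inherits(ols, "ols_fit"), length(qboots) >= 1L)
  vars <- names(ols$coefficients)
  for (qb in qboots) {
    if (!identical(names(qb$estimate), vars))
      stop("variable sets differ between OLS and quantile fits", call. = FALSE)
  }
  tcrit <- stats::qt(0.975, df = ols$n - ols$p - 1L)
  rows <- list(data.frame(
    variable = vars, tau = "OLS",
    estimate = unname(ols$coefficients),
    lower = unname(ols$coefficients - tcrit * ols$se),
    upper = unname(ols$coefficients + tcrit * ols$se),
    outside_ols_ci = FALSE, stringsAsFactors = FALSE))
  ols_lo <- ols$coefficients - tcrit * ols$se
  ols_hi <- ols$coefficients + tcrit * ols$se
  for (qb in qboots) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = vars, tau = format(qb$tau),
      estimate = unname(qb$estimate),
      lower = unname(qb$ci_lower), upper = unname(qb$ci_upper),
      outside_ols_ci = unname(qb$estimate < ols_lo | qb$estimate > ols_hi),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Run the full billing-aggressiveness study
#'
#' Executes the pipeline defined by a [run_config()]: obtain the analysis
#' table (simulated or ingested), fit the OLS baseline with Lilliefors
#' and Q-Q diagnostics, fit each quantile with bootstrap bands and
#' significance flags, run modified-BIC penalized selection per quantile,
#' and write all artifacts to `config$outdir`:
#' `analysis_table.csv`, `ols.csv`, `qq.csv`, `quantile_coefficients.csv`,
#' `selection.csv`, `comparison.csv`, `diagnostics.json`, `config.yaml`,
#' `run.log` (plus the raw claims CSVs and `truth.json` in simulate mode).
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`design`, `ols`,
#'   `lilliefors`, `qfits`, `qboots`, `selections`, `comparison`,
#'   `artifacts` paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(cfg)
  logf <- file.path(cfg$outdir, "run.log")
  cat(sprintf("qbill run | mode=%s seed=%d config=%s\n", cfg$mode, cfg$seed, hash),
      file = logf)
  logline <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(fmt, ...)), file = logf, append = TRUE)
  }
  t_all <- proc.time()[3]

  # --- stage 1: analysis table ---
  truth <- NULL
  if (cfg$mode == "simulate") {
    truth <- cfg$truth %||% synthetic_truth()
    sim <- simulate_claims_study(cfg$n, seed = cfg$seed, truth = truth)
    emit_raw_files(sim, cfg$outdir, procedure_code = cfg$procedure_code)
    design <- sim$design
    truth <- sim$truth
    logline("simulate", "n=%d providers, %d y-clipped, %d scale-clipped",
            nrow(design), sim$n_y_clipped, sim$n_scale_clipped)
  } else {
    cl <- load_claims(cfg$claims)
    v <- attr(cl, "validation")
    logline("load", "claims: %d read, %d valid", v$n_read, v$n_valid)
    st <- load_state_covariates(cfg$state_cov)
    lo <- load_locality(cfg$locality)
    flt <- filter_study_population(cl, cfg$procedure_code)
    fc <- attr(flt, "filter_counts")
    logline("filter", "procedure=%d individual=%d facility=%d providers=%d",
            fc$procedure, fc$individual, fc$facility, nrow(flt))
    design <- assemble_design(flt, st, lo, denominator = cfg$denominator)
    jr <- attr(design, "join_report")
    logline("assemble", "%d providers, %d dropped on joins", jr$n_output, jr$n_dropped)
  }
  dm <- design_matrix_of(design)
  .write_csv_prov(design, file.path(cfg$outdir, "analysis_table.csv"), hash, cfg$seed)

  # --- stage 2: OLS baseline + diagnostics ---
  ols <- fit_ols(dm$X, dm$y)
  lil <- lilliefors_test(ols$residuals, mc_reps = cfg$lilliefors_reps,
                         seed = cfg$seed + 1L)
  qq <- qq_data(ols$residuals)
  .write_csv_prov(ols$table, file.path(cfg$outdir, "ols.csv"), hash, cfg$seed)
  .write_csv_prov(qq, file.path(cfg$outdir, "qq.csv"), hash, cfg$seed)
  logline("ols", "R2=%.4f Lilliefors D=%.4f p=%.3g", ols$r_squared,
          lil$statistic, lil$p_value)

  # --- stage 3: per-quantile fits with bands ---
  qfits <- list(); qboots <- list()
  qtab <- data.frame(variable = names(ols$coefficients), stringsAsFactors = FALSE)
  for (i in seq_along(cfg$quantiles)) {
    tau <- cfg$quantiles[i]
    qfits[[i]] <- fit_quantreg(dm$X, dm$y, tau)
    qboots[[i]] <- bootstrap_ci(dm$X, dm$y, tau, B = cfg$bootstrap_B,
                                level = cfg$bootstrap_level,
                                seed = cfg$seed + 100L + i)
    qtab[[sprintf("tau_%g", tau)]] <- unname(qfits[[i]]$coefficients)
    qtab[[sprintf("sig_%g", tau)]] <- significance_stars(qboots[[i]]$p_value)
    logline("quantreg", "tau=%g objective=%.5g share_below=%.3f", tau,
            qfits[[i]]$objective, residual_sign_diagnostic(qfits[[i]])$share_below)
  }
  .write_csv_prov(qtab, file.path(cfg$outdir, "quantile_coefficients.csv"),
                  hash, cfg$seed)

  # --- stage 4: OLS vs quantile comparison ---
  comparison <- comparison_report(ols, qboots)
  .write_csv_prov(comparison, file.path(cfg$outdir, "comparison.csv"), hash, cfg$seed)

  # --- stage 5: penalized selection per quantile ---
  grid <- lambda_grid_default(cfg$lambda_min, cfg$lambda_max, cfg$lambda_points)
  selections <- lapply(cfg$quantiles, function(tau) {
    s <- select_lambda(dm$X, dm$y, tau, lambda_grid = grid,
                       Cn_spec = cfg$Cn_spec, cut = cfg$threshold,
                       refit = cfg$refit)
    logline("select", "tau=%g lambda_hat=%.4g |S|=%d [%s]", tau, s$lambda_hat,
            length(s$support), paste(s$support_names, collapse = ","))
    s
  })
  sel_tab <- selection_table(selections)
  .write_csv_prov(sel_tab, file.path(cfg$outdir, "selection.csv"), hash, cfg$seed)

  diagnostics <- list(
    config_hash = hash, seed = cfg$seed, n = nrow(design),
    lilliefors = lil[c("statistic", "p_value", "mc_reps")],
    ols_r_squared = ols$r_squared,
    response_skewness = sample_skewness(dm$y),
    lambda_hat = stats::setNames(vapply(selections, `[[`, numeric(1), "lambda_hat"),
                                 sprintf("tau_%g", cfg$quantiles)),
    support_sizes = stats::setNames(vapply(selections, function(s) length(s$support),
                                           integer(1)),
                                    sprintf("tau_%g", cfg$quantiles)))
  jsonlite::write_json(diagnostics, file.path(cfg$outdir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(cfg[setdiff(names(cfg), "truth")]),
                   file.path(cfg$outdir, "config.yaml"))
  logline("done", "elapsed=%.1fs", proc.time()[3] - t_all)

  invisible(list(design = design, truth = truth, ols = ols, lilliefors = lil,
                 qq = qq, qfits = qfits, qboots = qboots,
                 selections = selections, comparison = comparison,
                 config = cfg, config_hash = hash,
                 artifacts = file.path(cfg$outdir,
                   c("analysis_table.csv", "ols.csv", "qq.csv",
                     "quantile_coefficients.csv", "comparison.csv",
                     "selection.csv", "diagnostics.json", "config.yaml",
                     "run.log"))))
}
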