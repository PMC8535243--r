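# Reading, validating, filtering and joining claims-shaped tables.
#
# The canonical claims schema mirrors the CMS provider-procedure summary
# ("Physician and Other Supplier") layout: one row per provider x
# procedure x place of service carrying per-service averages of submitted
# charge and the three payment amounts plus utilization counts. A
# schema_config map lets files with PUF-style headers
# (average_submitted_chrg_amt, line_srvc_cnt, ...) be renamed onto the
# canonical names at load time.

.claims_required <- c(
  "provider_id", "procedure_code", "place_of_service", "entity_type",
  "provider_type", "state", "zip", "line_service_count",
  "unique_beneficiary_count", "avg_submitted_charge", "avg_allowed_payment",
  "avg_medicare_payment", "avg_standardized_payment")

.currency_cols <- c("avg_submitted_charge", "avg_allowed_payment",
                    "avg_medicare_payment", "avg_standardized_payment")

#' PUF-style column mapping for claims files
#'
#' A ready-made `schema_config` for files using the public-use-file
#' header names; entries map canonical names to file column names.
#' @return named character vector (canonical = file column).
#' @export
puf_schema_config <- function() {
  c(provider_id = "npi",
    procedure_code = "hcpcs_code",
    place_of_service = "place_of_service",
    entity_type = "nppes_entity_code",
    provider_type = "provider_type",
    state = "nppes_provider_state",
    zip = "nppes_provider_zip",
    line_service_count = "line_srvc_cnt",
    unique_beneficiary_count = "bene_unique_cnt",
    avg_submitted_charge = "average_submitted_chrg_amt",
    avg_allowed_payment = "average_medicare_allowed_amt",
    avg_medicare_payment = "average_medicare_payment_amt",
    avg_standardized_payment = "average_medicare_standard_amt")
}

.normalize_enum <- function(x, map) {
  key <- tolower(trimws(as.character(x)))
  out <- unname(map[key])
  out
}

#' Load and validate a claims summary CSV
#'
#' Reads the file, applies any `schema_config` renames, checks that every
#' required canonical column is present, normalizes the place-of-service
#' and entity-type enums (accepting the PUF single-letter codes `F`/`O`
#' and `I`/`O`), and validates rows. Invalid rows are dropped and counted
#' by reason: missing field, nonpositive currency, unknown enum, or
#' beneficiary count exceeding service count.
#'
#' @param path CSV path (UTF-8, header row; `#` lines are comments).
#' @param schema_config optional named character vector/list mapping
#'   canonical column names to the file's column names, e.g.
#'   [puf_schema_config()].
#' @return a `claim_lines` data.frame of valid rows; attribute
#'   `validation` holds `n_read`, `n_valid` and the per-reason rejection
#'   counts.
#' @export
load_claims <- function(path, schema_config = NULL) {
  if (!file.exists(path)) stop("claims file not found: ", path, call. = FALSE)
  # read everything as character first: bare "F" place-of-service codes
  # would otherwise be parsed as logical FALSE
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        colClasses = "character")
  if (nrow(df) == 0L) stop("claims file is empty: ", path, call. = FALSE)
  if (!is.null(schema_config)) {
    sc <- unlist(schema_config)
    for (canon in names(sc)) {
      if (sc[[canon]] %in% names(df) && canon != sc[[canon]]) {
        names(df)[names(df) == sc[[canon]]] <- canon
      }
    }
  }
  missing_cols <- setdiff(.claims_required, names(df))
  if (length(missing_cols)) {
    stop("claims file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[, .claims_required]
  df$provider_id <- as.character(df$provider_id)
  df$procedure_code <- as.character(df$procedure_code)
  df$state <- as.character(df$state)
  df$zip <- as.character(df$zip)

  pos_map <- c(facility = "facility", non_facility = "non_facility",
               f = "facility", o = "non_facility")
  ent_map <- c(individual = "individual", organization = "organization",
               i = "individual", o = "organization")
  pos <- .normalize_enum(df$place_of_service, pos_map)
  ent <- .normalize_enum(df$entity_type, ent_map)

  num_cols <- c("line_service_count", "unique_beneficiary_count", .currency_cols)
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))

  reasons <- character(nrow(df))
  has_missing <- rowSums(is.na(df[, num_cols])) > 0 |
    is.na(df$provider_id) | df$provider_id == "" | is.na(df$procedure_code)
  reasons[has_missing] <- "missing_field"
  bad_enum <- (is.na(pos) | is.na(ent)) & reasons == ""
  reasons[bad_enum] <- "unknown_enum"
  bad_curr <- reasons == "" &
    apply(df[, .currency_cols] <= 0, 1L, any)
  reasons[bad_curr] <- "nonpositive_currency"
  bad_cnt <- reasons == "" & (df$line_service_count < 0 |
    df$unique_beneficiary_count < 0 |
    (df$line_service_count > 0 & df$unique_beneficiary_count > 0 &
       df$unique_beneficiary_count > df$line_service_count))
  reasons[bad_cnt] <- "invalid_counts"

  keep <- reasons == ""
  out <- df[keep, , drop = FALSE]
  out$place_of_service <- pos[keep]
  out$entity_type <- ent[keep]
  rej <- table(reasons[!keep])
  if (any(!keep)) {
    message(sprintf("load_claims: rejected %d of %d row(s) [%s]",
                    sum(!keep), nrow(df),
                    paste(sprintf("%s=%d", names(rej), as.integer(rej)),
                          collapse = ", ")))
  }
  attr(out, "validation") <- list(n_read = nrow(df), n_valid = sum(keep),
                                  rejections = as.list(rej))
  class(out) <- c("claim_lines", "data.frame")
  rownames(out) <- NULL
  out
}

.proportion_cols <- c("ma_participation_rate", "percent_female",
                      "percent_nonhispanic_white", "percent_medicaid_eligible")

#' Load a state-level covariate table
#'
#' One row per state. Proportion columns must lie in \[0,1\]; columns that
#' look like 0-100 percentages (any value above 1.5) are rescaled to
#' proportions with a warning.
#'
#' @param path CSV path.
#' @return data.frame with one row per state.
#' @export
load_state_covariates <- function(path) {
  if (!file.exists(path)) stop("state covariate file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("state", .proportion_cols, "average_age", "average_hcc_score",
            "std_risk_adjusted_per_capita_cost")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("state covariate file missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$state)) stop("duplicate state rows", call. = FALSE)
  for (cc in .proportion_cols) {
    if (any(df[[cc]] > 1.5, na.rm = TRUE)) {
      warning(sprintf("column %s looks like 0-100 percentages; rescaling to [0,1]", cc))
      df[[cc]] <- df[[cc]] / 100
    }
    if (any(df[[cc]] < 0 | df[[cc]] > 1, na.rm = TRUE))
      stop("proportion column out of [0,1]: ", cc, call. = FALSE)
  }
  df
}

#' Load a locality / GPCI lookup table
#'
#' Simplified two-column lookup from a state (or zip-prefix) key to a
#' locality id and its physician-work GPCI.
#'
#' @param path CSV path.
#' @return data.frame with columns `state` (or `zip_prefix`),
#'   `locality_id`, `gpci_work`.
#' @export
load_locality <- function(path) {
  if (!file.exists(path)) stop("locality file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  key <- intersect(c("state", "zip_prefix"), names(df))
  if (!length(key) || !all(c("locality_id", "gpci_work") %in% names(df)))
    stop("locality file needs a state/zip_prefix key, locality_id and gpci_work",
         call. = FALSE)
  if (any(df$gpci_work <= 0)) stop("gpci_work must be positive", call. = FALSE)
  if (anyDuplicated(df[[key[1L]]])) stop("duplicate locality keys", call. = FALSE)
  df
}

#' Restrict claims to the study population and collapse to providers
#'
#' Keeps rows for the focal procedure billed by individual entities at a
#' facility place of service, then collapses to one row per provider:
#' currency fields are combined by service-count-weighted means (the
#' source averages are per-service means, so weighting by service count
#' recovers the pooled mean) and counts are summed.
#'
#' @param claims a validated `claim_lines` data.frame.
#' @param procedure_code focal HCPCS-like code.
#' @return one-row-per-provider `claim_lines` data.frame; attribute
#'   `filter_counts` reports rows surviving each filter.
#' @export
filter_study_population <- function(claims, procedure_code) {
  stopifnot(is.data.frame(claims))
  n0 <- nrow(claims)
  f1 <- claims[claims$procedure_code == procedure_code, , drop = FALSE]
  f2 <- f1[f1$entity_type == "individual", , drop = FALSE]
  f3 <- f2[f2$place_of_service == "facility", , drop = FALSE]
  counts <- list(input = n0, procedure = nrow(f1), individual = nrow(f2),
                 facility = nrow(f3))
  if (nrow(f3) == 0L) {
    stop(sprintf(paste0("no rows left after filtering (input=%d, procedure=%d, ",
                        "individual=%d, facility=%d)"),
                 n0, nrow(f1), nrow(f2), nrow(f3)), call. = FALSE)
  }
  sp <- split(f3, f3$provider_id)
  agg <- lapply(sp, function(d) {
    w <- d$line_service_count
    if (sum(w) <= 0) w <- rep(1, nrow(d))
    out <- d[1L, , drop = FALSE]
    for (cc in .currency_cols) out[[cc]] <- sum(d[[cc]] * w) / sum(w)
    out$line_service_count <- sum(d$line_service_count)
    out$unique_beneficiary_count <- sum(d$unique_beneficiary_count)
    out
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  attr(out, "filter_counts") <- counts
  class(out) <- c("claim_lines", "data.frame")
  out
}

#' Billing aggressiveness of a claim row
#'
#' The ratio of the average submitted charge to the average payment
#' amount. The payment field is configurable because "payment amount" can
#' be read as the allowed amount (default, the usual convention for this
#' ratio), the Medicare-paid amount, or the geographically standardized
#' amount.
#'
#' @param claims `claim_lines` data.frame (or any data.frame with the
#'   currency columns).
#' @param denominator `"allowed"`, `"medicare_payment"`, or
#'   `"standardized"`.
#' @return positive numeric vector of ratios.
#' @export
compute_aggressiveness <- function(claims,
                                   denominator = c("allowed", "medicare_payment",
                                                   "standardized")) {
  denominator <- match.arg(denominator)
  den_col <- switch(denominator,
                    allowed = "avg_allowed_payment",
                    medicare_payment = "avg_medicare_payment",
                    standardized = "avg_standardized_payment")
  den <- claims[[den_col]]
  if (any(den <= 0)) stop("nonpositive denominator in ", den_col, call. = FALSE)
  claims$avg_submitted_charge / den
}

#' Per-provider-type aggressiveness aggregates
#'
#' Mean and sample standard deviation (ddof = 1) of aggressiveness within
#' each provider type; a type with a single provider gets sd = 0 so the
#' design matrix stays complete. These become every provider's
#' `mean_agg_provider_type` and `sd_agg_provider_type` covariates (the
#' focal provider is included in its own type's aggregate — a documented
#' leakage caveat of this feature).
#'
#' @param df data.frame with `provider_type` and `aggressiveness` columns.
#' @return data.frame with `provider_type`, `mean_agg`, `sd_agg`, `n`.
#' @export
provider_type_aggregates <- function(df) {
  stopifnot(all(c("provider_type", "aggressiveness") %in% names(df)))
  sp <- split(df$aggressiveness, df$provider_type)
  data.frame(provider_type = names(sp),
             mean_agg = vapply(sp, mean, numeric(1)),
             sd_agg = vapply(sp, function(v) if (length(v) < 2) 0 else stats::sd(v),
                             numeric(1)),
             n = vapply(sp, length, integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assemble the analysis-ready design table
#'
#' Joins provider-level claims (already filtered to one row per provider)
#' with the state covariate and locality tables, computes the
#' aggressiveness response and the provider-type aggregate covariates,
#' and returns the canonical analysis table: `provider_id`,
#' `provider_type`, `y`, then the 14 covariates in [qbill_covariates()]
#' order. Rows whose state fails either join are dropped with a logged
#' count; more than 50% unmatched is an error (that is a schema mismatch,
#' not missing data).
#'
#' @param claims one-row-per-provider `claim_lines`.
#' @param state_cov [load_state_covariates()] table.
#' @param locality [load_locality()] table.
#' @param denominator see [compute_aggressiveness()].
#' @return an `analysis_table` data.frame; attribute `join_report` holds
#'   drop counts.
#' @export
assemble_design <- function(claims, state_cov, locality,
                            denominator = c("allowed", "medicare_payment",
                                            "standardized")) {
  denominator <- match.arg(denominator)
  n0 <- nrow(claims)
  key <- if ("state" %in% names(locality)) "state" else "zip_prefix"
  loc_idx <- match(claims$state, locality[[key]])
  st_idx <- match(claims$state, state_cov$state)
  unmatched <- is.na(loc_idx) | is.na(st_idx)
  if (mean(unmatched) > 0.5) {
    stop(sprintf("%d of %d providers failed the state/locality join; likely a schema mismatch",
                 sum(unmatched), n0), call. = FALSE)
  }
  if (any(unmatched)) {
    message(sprintf("assemble_design: dropped %d provider(s) with unmatched joins",
                    sum(unmatched)))
  }
  cl <- claims[!unmatched, , drop = FALSE]
  loc_idx <- loc_idx[!unmatched]; st_idx <- st_idx[!unmatched]

  y <- compute_aggressiveness(cl, denominator)
  agg <- provider_type_aggregates(data.frame(provider_type = cl$provider_type,
                                             aggressiveness = y,
                                             stringsAsFactors = FALSE))
  t_idx <- match(cl$provider_type, agg$provider_type)

  out <- data.frame(
    provider_id = cl$provider_id,
    provider_type = cl$provider_type,
    y = y,
    line_service_count = cl$line_service_count,
    unique_beneficiary_count = cl$unique_beneficiary_count,
    avg_allowed_payment = cl$avg_allowed_payment,
    avg_standardized_payment = cl$avg_standardized_payment,
    gpci_work = locality$gpci_work[loc_idx],
    ma_participation_rate = state_cov$ma_participation_rate[st_idx],
    average_age = state_cov$average_age[st_idx],
    percent_female = state_cov$percent_female[st_idx],
    percent_nonhispanic_white = state_cov$percent_nonhispanic_white[st_idx],
    percent_medicaid_eligible = state_cov$percent_medicaid_eligible[st_idx],
    average_hcc_score = state_cov$average_hcc_score[st_idx],
    std_risk_adjusted_per_capita_cost = state_cov$std_risk_adjusted_per_capita_cost[st_idx],
    mean_agg_provider_type = agg$mean_agg[t_idx],
    sd_agg_provider_type = agg$sd_agg[t_idx],
    row.names = NULL, stringsAsFactors = FALSE)
  if (anyNA(out[, c("y", .covariate_names)]))
    stop("internal error: missing values after assembly", call. = FALSE)
  attr(out, "join_report") <- list(n_input = n0, n_dropped = sum(unmatched),
                                   n_output = nrow(out),
                                   denominator = denominator)
  class(out) <- c("analysis_table", "data.frame")
  out
}

#' Extract the response and covariate matrix from an analysis table
#' @param design an `analysis_table`.
#' @return list with `y` and numeric matrix `X` (n x 14).
#' @export
design_matrix_of <- function(design) {
  stopifnot(all(c("y", .covariate_names) %in% names(design)))
  list(y = design$y,
       X = as.matrix(design[, .covariate_names]))
}
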