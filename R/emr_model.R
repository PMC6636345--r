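# Tabular EMR schemas, code sets, study configuration and CSV I/O.

CW_SETTINGS <- c("outpatient", "inpatient", "emergency")
CW_SEXES <- c("female", "male")

#' Construct a diagnosis/prescription code set
#'
#' A code set names a collection of codes together with a matching rule.
#' `exact` matches set membership; `prefix` matches any code for which a
#' member of the set is a leading substring (so `"I48"` captures `"I48.0"`).
#' Code sets are deliberately coding-system agnostic (ICD-9, ICD-10, ATC,
#' local drug codes all work).
#'
#' @param name Unique name of the set within a study configuration.
#' @param codes Non-empty character vector of codes.
#' @param match_mode `"exact"` or `"prefix"`.
#' @return An object of class `code_set`.
#' @export
code_set <- function(name, codes, match_mode = c("exact", "prefix")) {
  match_mode <- match.arg(match_mode)
  codes <- unique(as.character(codes))
  if (length(codes) == 0 || !nzchar(name)) {
    cw_config_error("code set must have a name and at least one code")
  }
  structure(list(name = name, codes = codes, match_mode = match_mode),
            class = "code_set")
}

#' Test codes against a code set
#'
#' @param code Character vector of codes to test.
#' @param cs A [code_set()].
#' @return Logical vector, one element per input code.
#' @export
code_matches <- function(code, cs) {
  stopifnot(inherits(cs, "code_set"))
  code <- as.character(code)
  if (cs$match_mode == "exact") {
    code %in% cs$codes
  } else {
    hit <- rep(FALSE, length(code))
    for (p in cs$codes) hit <- hit | startsWith(code, p)
    hit
  }
}

validate_patients <- function(df) {
  cw_stopifnot_cols(df, c("patient_id", "birth_date", "sex", "data_end_date"), "patients")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    cw_validation_error(sprintf("patients: duplicated patient_id '%s'",
                                df$patient_id[duplicated(df$patient_id)][1]))
  }
  df$birth_date <- cw_parse_date(df$birth_date, "patients$birth_date")
  df$data_end_date <- cw_parse_date(df$data_end_date, "patients$data_end_date")
  bad <- which(!df$sex %in% CW_SEXES)
  if (length(bad) > 0) {
    cw_validation_error(sprintf("patients: invalid sex '%s' at row %d",
                                df$sex[bad[1]], bad[1]))
  }
  bad <- which(df$birth_date > df$data_end_date)
  if (length(bad) > 0) {
    cw_validation_error(sprintf("patients: birth_date after data_end_date at row %d", bad[1]))
  }
  df[c("patient_id", "birth_date", "sex", "data_end_date")]
}

validate_diagnoses <- function(df) {
  cw_stopifnot_cols(df, c("patient_id", "date", "code", "setting"), "diagnoses")
  df$patient_id <- as.character(df$patient_id)
  df$code <- as.character(df$code)
  df$date <- cw_parse_date(df$date, "diagnoses$date")
  bad <- which(!df$setting %in% CW_SETTINGS)
  if (length(bad) > 0) {
    cw_validation_error(sprintf(
      "diagnoses: invalid setting '%s' at row %d (must be one of %s)",
      df$setting[bad[1]], bad[1], paste(CW_SETTINGS, collapse = "/")))
  }
  df[c("patient_id", "date", "code", "setting")]
}

validate_prescriptions <- function(df) {
  cw_stopifnot_cols(df, c("patient_id", "drug_code", "start_date", "days_supplied"), "prescriptions")
  df$patient_id <- as.character(df$patient_id)
  df$drug_code <- as.character(df$drug_code)
  df$start_date <- cw_parse_date(df$start_date, "prescriptions$start_date")
  ds <- suppressWarnings(as.integer(df$days_supplied))
  bad <- which(is.na(ds) | ds < 1)
  if (length(bad) > 0) {
    cw_validation_error(sprintf(
      "prescriptions: days_supplied must be a positive integer (row %d has '%s')",
      bad[1], df$days_supplied[bad[1]]))
  }
  df$days_supplied <- ds
  df[c("patient_id", "drug_code", "start_date", "days_supplied")]
}

#' Read and validate the three EMR tables
#'
#' Reads `patients.csv`, `diagnoses.csv` and `prescriptions.csv` (schema by
#' column name, not position), parses ISO-8601 dates, and enforces the row
#' level invariants (known sex/setting levels, positive days supplied,
#' unique patient ids, birth before end of data coverage). Row order is
#' preserved.
#'
#' @param patients,diagnoses,prescriptions File paths.
#' @param sep Field delimiter (default comma).
#' @return A list of class `emr_tables` with elements `patients`,
#'   `diagnoses`, `prescriptions` (data frames with `Date` columns).
#' @export
read_emr_tables <- function(patients, diagnoses, prescriptions, sep = ",") {
  for (p in c(patients, diagnoses, prescriptions)) {
    if (!file.exists(p)) cw_validation_error(sprintf("input file not found: %s", p))
  }
  rd <- function(p) utils::read.csv(p, sep = sep, colClasses = "character",
                                    stringsAsFactors = FALSE, check.names = TRUE)
  emr_tables(rd(patients), rd(diagnoses), rd(prescriptions))
}

#' Assemble validated EMR tables from in-memory data frames
#'
#' @param patients,diagnoses,prescriptions Data frames following the
#'   standard column schemas.
#' @return A validated `emr_tables` list.
#' @export
emr_tables <- function(patients, diagnoses, prescriptions) {
  structure(list(
    patients = validate_patients(patients),
    diagnoses = validate_diagnoses(diagnoses),
    prescriptions = validate_prescriptions(prescriptions)
  ), class = "emr_tables")
}

#' Write the three EMR tables as CSV
#'
#' Inverse of [read_emr_tables()]: writing then reading reproduces the
#' tables field-for-field.
#'
#' @param tables An `emr_tables` list.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the three file paths.
#' @export
write_emr_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "emr_tables"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("patients.csv", "diagnoses.csv", "prescriptions.csv"))
  utils::write.csv(tables$patients, paths[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$diagnoses, paths[2], row.names = FALSE, quote = FALSE)
  utils::write.csv(tables$prescriptions, paths[3], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

as_code_set <- function(x, name = NULL) {
  if (inherits(x, "code_set")) return(x)
  code_set(name %||% x$name, x$codes, x$match_mode %||% "exact")
}

code_set_map <- function(lst) {
  if (is.null(lst) || length(lst) == 0) return(list())
  out <- list()
  for (nm in names(lst)) out[[nm]] <- as_code_set(lst[[nm]], nm)
  out
}

#' Construct a study configuration
#'
#' Holds every scalar constant of the study design: the accrual window, the
#' new-user washout (default 365 days), the covariate lookback (default 365
#' days = "12 months before the index date"), the follow-up horizon (default
#' 730 days = 2 years), the refill grace gap (default 30 days, strict
#' inequality: a gap must *exceed* it to count as discontinuation), the
#' matching caliper (default 0.2 on the scale of the standard deviation of
#' the logit propensity score), the balance threshold (default |SMD| < 0.1)
#' and the two-sided significance level (default 0.05).
#'
#' @param study_window Length-2 vector of dates (start, end), start < end.
#' @param exposure_sets Named list of exactly two [code_set()]s of drug
#'   codes, one per comparison arm.
#' @param outcome_sets Named list of outcome diagnosis code sets.
#' @param incident_exclusion_sets Named list (by outcome) of diagnosis code
#'   sets whose pre-index presence removes a subject from that outcome's
#'   incident subcohort. Outcomes without an entry get no exclusion.
#' @param treated_group Name of the exposure group coded 1 in analyses.
#' @param washout_days,lookback_days,max_followup_days,gap_days Day counts.
#' @param caliper,caliper_scale Matching caliper and its scale
#'   (`"logit_sd"` or `"raw"`).
#' @param smd_threshold,alpha Balance threshold and significance level.
#' @param criteria List of [criterion()] objects applied after new-user
#'   identification, in order.
#' @param covariate_templates Named list of covariate spec lists (the
#'   template library); `active_template` selects one.
#' @param active_template Template name, or `NULL` to use `covariates`.
#' @param covariates Inline list of [covariate_spec()]s.
#' @param ps_covariates,cox_covariates Character vectors of covariate
#'   names entering the propensity model and the Cox adjustment set.
#' @param code_sets Named list of auxiliary code sets referenced by
#'   criteria/covariates.
#' @param risk_scores Named list of risk score definitions.
#' @param seed Integer seed driving every stochastic step.
#' @return An object of class `study_config`.
#' @export
study_config <- function(study_window,
                         exposure_sets,
                         outcome_sets,
                         incident_exclusion_sets = list(),
                         treated_group = names(exposure_sets)[1],
                         washout_days = 365,
                         lookback_days = 365,
                         max_followup_days = 730,
                         gap_days = 30,
                         caliper = 0.2,
                         caliper_scale = c("logit_sd", "raw"),
                         smd_threshold = 0.1,
                         alpha = 0.05,
                         criteria = list(),
                         covariate_templates = list(),
                         active_template = NULL,
                         covariates = list(),
                         ps_covariates = character(),
                         cox_covariates = character(),
                         code_sets = list(),
                         risk_scores = list(),
                         seed = 1L) {
  caliper_scale <- match.arg(caliper_scale)
  study_window <- as.Date(study_window)
  if (length(study_window) != 2 || anyNA(study_window)) {
    cw_config_error("study_window must be two parseable dates")
  }
  if (study_window[1] >= study_window[2]) {
    cw_config_error("study_window: start must precede end")
  }
  for (f in c("washout_days", "lookback_days", "max_followup_days", "gap_days")) {
    v <- get(f)
    if (!is.finite(v) && !(f == "washout_days" && is.infinite(v))) {
      cw_config_error(sprintf("%s must be a finite nonnegative number", f))
    }
    if (v < 0) cw_config_error(sprintf("%s must be >= 0", f))
  }
  if (!(alpha > 0 && alpha < 1)) cw_config_error("alpha must lie in (0, 1)")
  if (!(caliper > 0)) cw_config_error("caliper must be positive")
  if (!(smd_threshold > 0)) cw_config_error("smd_threshold must be positive")
  exposure_sets <- code_set_map(exposure_sets)
  if (length(exposure_sets) != 2) {
    cw_config_error("exactly 2 exposure groups are required per comparison")
  }
  if (!treated_group %in% names(exposure_sets)) {
    cw_config_error(sprintf("treated_group '%s' is not an exposure set", treated_group))
  }
  outcome_sets <- code_set_map(outcome_sets)
  if (length(outcome_sets) == 0) cw_config_error("at least one outcome set is required")
  incident_exclusion_sets <- code_set_map(incident_exclusion_sets)
  unknown <- setdiff(names(incident_exclusion_sets), names(outcome_sets))
  if (length(unknown) > 0) {
    cw_config_error(sprintf("incident_exclusion_sets refer to undefined outcome(s): %s",
                            paste(unknown, collapse = ", ")))
  }
  code_sets <- code_set_map(code_sets)
  if (!is.null(active_template)) {
    if (!active_template %in% names(covariate_templates)) {
      cw_config_error(sprintf("unknown covariate template '%s'", active_template))
    }
    covariates <- covariate_templates[[active_template]]
  }
  structure(list(
    study_window = study_window,
    washout_days = washout_days, lookback_days = lookback_days,
    max_followup_days = max_followup_days, gap_days = gap_days,
    caliper = caliper, caliper_scale = caliper_scale,
    smd_threshold = smd_threshold, alpha = alpha,
    exposure_sets = exposure_sets, treated_group = treated_group,
    outcome_sets = outcome_sets,
    incident_exclusion_sets = incident_exclusion_sets,
    criteria = criteria,
    covariate_templates = covariate_templates,
    active_template = active_template,
    covariates = covariates,
    ps_covariates = ps_covariates, cox_covariates = cox_covariates,
    code_sets = code_sets, risk_scores = risk_scores,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Load a study configuration from JSON
#'
#' The configuration dialect is JSON mirroring the [study_config()] fields
#' by name. Absent optional scalars fall back to the documented defaults
#' (365 / 365 / 730 / 30 / 0.2 logit_sd / 0.1 / 0.05). Criteria and
#' covariate specs reference code sets by name; references are resolved
#' here and unknown names fail fast.
#'
#' @param path Path to a JSON file.
#' @return A validated `study_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) cw_config_error(sprintf("config file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  sets <- code_set_map(raw$code_sets)
  resolve <- function(ref, where) {
    if (is.null(ref)) return(NULL)
    if (is.list(ref)) return(as_code_set(ref, ref$name %||% where))
    all_sets <- c(sets, code_set_map(raw$exposure_sets), code_set_map(raw$outcome_sets))
    if (!ref %in% names(all_sets)) {
      cw_config_error(sprintf("%s references undefined code set '%s'", where, ref))
    }
    all_sets[[ref]]
  }
  crits <- lapply(raw$criteria %||% list(), function(cr) {
    criterion(
      label = cr$label, kind = cr$kind,
      code_set = resolve(cr$code_set, sprintf("criterion '%s'", cr$label)),
      window = if (!is.null(cr$window)) as.numeric(cr$window) else c(-Inf, 0),
      settings = cr$settings %||% CW_SETTINGS,
      min_count = cr$min_count %||% 1L,
      min_age = cr$min_age %||% NULL
    )
  })
  parse_specs <- function(lst) lapply(lst, function(cv) {
    covariate_spec(
      name = cv$name, source = cv$source,
      code_set = resolve(cv$code_set, sprintf("covariate '%s'", cv$name)),
      window_days = cv$window_days %||% 365,
      min_count = cv$min_count %||% 1L,
      risk_score = cv$risk_score %||% NULL
    )
  })
  templates <- lapply(raw$covariate_templates %||% list(), parse_specs)
  risk_scores <- lapply(raw$risk_scores %||% list(), function(rs) {
    risk_score_def(rs$name, rs$components)
  })
  names(risk_scores) <- vapply(risk_scores, function(r) r$name, "")
  study_config(
    study_window = raw$study_window,
    exposure_sets = raw$exposure_sets,
    outcome_sets = raw$outcome_sets,
    incident_exclusion_sets = raw$incident_exclusion_sets %||% list(),
    treated_group = raw$treated_group %||% names(raw$exposure_sets)[1],
    washout_days = raw$washout_days %||% 365,
    lookback_days = raw$lookback_days %||% 365,
    max_followup_days = raw$max_followup_days %||% 730,
    gap_days = raw$gap_days %||% 30,
    caliper = raw$caliper %||% 0.2,
    caliper_scale = raw$caliper_scale %||% "logit_sd",
    smd_threshold = raw$smd_threshold %||% 0.1,
    alpha = raw$alpha %||% 0.05,
    criteria = crits,
    covariate_templates = templates,
    active_template = raw$active_template %||% NULL,
    covariates = if (is.null(raw$active_template)) parse_specs(raw$covariates %||% list()) else list(),
    ps_covariates = as.character(raw$ps_covariates %||% character()),
    cox_covariates = as.character(raw$cox_covariates %||% character()),
    code_sets = raw$code_sets %||% list(),
    risk_scores = risk_scores,
    seed = raw$seed %||% 1L
  )
}
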