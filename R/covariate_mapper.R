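# Analysis-ready dataset assembly: demographics, lookback comorbidity and
# comedication flags, additive risk scores, and a small template library.

#' Define one baseline covariate
#'
#' @param name Column name in the analysis-ready dataset.
#' @param source One of `demographic` (built-ins `age`, `sex`),
#'   `diagnosis_flag`, `prescription_flag`, `risk_score`.
#' @param code_set [code_set()] for flag sources.
#' @param window_days Lookback window (default 365 = "within 12 months
#'   before the index date"); the interval is `[index - window_days, index)`.
#' @param min_count Records needed to set the flag (default 1).
#' @param risk_score A [risk_score_def()] or the name of one declared in
#'   the study config, for `source = "risk_score"`.
#' @return An object of class `covariate_spec`.
#' @export
covariate_spec <- function(name, source, code_set = NULL, window_days = 365,
                           min_count = 1L, risk_score = NULL) {
  sources <- c("demographic", "diagnosis_flag", "prescription_flag", "risk_score")
  if (!source %in% sources) cw_config_error(sprintf("unknown covariate source '%s'", source))
  if (source %in% c("diagnosis_flag", "prescription_flag") && is.null(code_set)) {
    cw_config_error(sprintf("covariate '%s' (%s) requires a code set", name, source))
  }
  structure(list(name = name, source = source, code_set = code_set,
                 window_days = as.numeric(window_days),
                 min_count = as.integer(min_count), risk_score = risk_score),
            class = "covariate_spec")
}

flag_counts <- function(members, tab, datecol, codecol, cs, index, window_days,
                        settings = CW_SETTINGS) {
  idx_of <- stats::setNames(index$index_date, index$patient_id)
  rows <- tab[tab$patient_id %in% members, , drop = FALSE]
  if ("setting" %in% names(rows)) rows <- rows[rows$setting %in% settings, , drop = FALSE]
  rows <- rows[code_matches(rows[[codecol]], cs), , drop = FALSE]
  ref <- idx_of[rows$patient_id]
  rows <- rows[rows[[datecol]] >= ref - window_days & rows[[datecol]] < ref, , drop = FALSE]
  as.integer(table(factor(rows$patient_id, levels = members)))
}

#' Assemble the analysis-ready dataset
#'
#' One row per cohort member, ordered by `patient_id`: identifier, index
#' date, binary group (1 = treated-of-interest), age in completed years at
#' index, sex (1 = female), then one column per covariate spec. Flags are
#' 1 iff at least `min_count` matching records fall in
#' `[index - window_days, index)`; there are never missing values.
#'
#' @param node `cohort_node` whose members form the dataset.
#' @param index Index assignments (with `index_group`).
#' @param tables `emr_tables`.
#' @param specs List of [covariate_spec()]s.
#' @param treated_group Exposure group coded 1.
#' @param risk_scores Named list of [risk_score_def()]s for specs that
#'   reference scores by name.
#' @return Data frame of class `analysis_ready`.
#' @export
assemble_analysis_ready <- function(node, index, tables, specs = list(),
                                    treated_group, risk_scores = list()) {
  members <- sort(node$members)
  pos <- match(members, index$patient_id)
  if (anyNA(pos)) cw_structural_error("cohort member lacks an index assignment")
  idx <- index[pos, , drop = FALSE]
  pts <- tables$patients[match(members, tables$patients$patient_id), , drop = FALSE]
  out <- data.frame(
    patient_id = members,
    index_date = idx$index_date,
    group = as.integer(idx$index_group == treated_group),
    age_years = cw_age_years(pts$birth_date, idx$index_date),
    sex = as.integer(pts$sex == "female"),
    stringsAsFactors = FALSE
  )
  for (sp in specs) {
    col <- switch(sp$source,
      demographic = {
        if (sp$name == "age") out$age_years
        else if (sp$name == "sex") out$sex
        else cw_config_error(sprintf("unknown demographic covariate '%s'", sp$name))
      },
      diagnosis_flag = as.integer(
        flag_counts(members, tables$diagnoses, "date", "code", sp$code_set,
                    idx, sp$window_days) >= sp$min_count),
      prescription_flag = as.integer(
        flag_counts(members, tables$prescriptions, "start_date", "drug_code",
                    sp$code_set, idx, sp$window_days) >= sp$min_count),
      risk_score = {
        def <- sp$risk_score
        if (is.character(def)) {
          if (!def %in% names(risk_scores)) {
            cw_config_error(sprintf("unknown risk score '%s'", def))
          }
          def <- risk_scores[[def]]
        }
        vapply(seq_along(members), function(i) {
          compute_risk_score(
            patient_context(members[i], tables, idx$index_date[i]), def)
        }, 1L)
      }
    )
    out[[sp$name]] <- col
  }
  class(out) <- c("analysis_ready", "data.frame")
  out
}

#' Bundle one subject's records for risk scoring
#'
#' @param patient_id Subject id.
#' @param tables `emr_tables`.
#' @param index_date The subject's index date.
#' @return A list with demographics, index date and the subject's
#'   diagnosis/prescription rows.
#' @export
patient_context <- function(patient_id, tables, index_date) {
  p <- tables$patients[tables$patients$patient_id == patient_id, , drop = FALSE]
  if (nrow(p) == 0) cw_structural_error(sprintf("unknown patient '%s'", patient_id))
  list(
    patient_id = patient_id,
    sex = p$sex[1],
    age_years = cw_age_years(p$birth_date[1], index_date),
    index_date = index_date,
    diagnoses = tables$diagnoses[tables$diagnoses$patient_id == patient_id, , drop = FALSE],
    prescriptions = tables$prescriptions[tables$prescriptions$patient_id == patient_id, , drop = FALSE]
  )
}

#' Define an additive risk score
#'
#' Components are granted independently and summed; points are nonnegative
#' so the score is monotone in satisfied components. Component types:
#' `age_at_least` / `age_between` (completed years), `sex` (value
#' `"female"`/`"male"`), `diagnosis` / `prescription` (a code set matched
#' in the pre-index lookback window).
#'
#' @param name Score name.
#' @param components List of lists with fields `type`, `points`, and the
#'   type-specific fields (`value`, `min`/`max`, `code_set`,
#'   `window_days`).
#' @return Object of class `risk_score_def`.
#' @export
risk_score_def <- function(name, components) {
  comps <- lapply(components, function(cp) {
    if (is.null(cp$type) || is.null(cp$points)) {
      cw_config_error(sprintf("risk score '%s': component needs type and points", name))
    }
    if (cp$points < 0) cw_config_error("risk score points must be nonnegative")
    if (cp$type %in% c("diagnosis", "prescription") && !is.null(cp$code_set) &&
        !inherits(cp$code_set, "code_set")) {
      cp$code_set <- as_code_set(cp$code_set, cp$name %||% "component")
    }
    cp
  })
  structure(list(name = name, components = comps), class = "risk_score_def")
}

#' Evaluate an additive risk score for one subject
#'
#' @param ctx A [patient_context()].
#' @param def A [risk_score_def()].
#' @return Integer score (sum of points over satisfied components).
#' @export
compute_risk_score <- function(ctx, def) {
  stopifnot(inherits(def, "risk_score_def"))
  total <- 0L
  for (cp in def$components) {
    hit <- switch(cp$type,
      age_at_least = ctx$age_years >= cp$value,
      age_between = ctx$age_years >= cp$min && ctx$age_years <= cp$max,
      sex = identical(ctx$sex, cp$value),
      diagnosis = {
        w <- cp$window_days %||% 365
        d <- ctx$diagnoses
        any(code_matches(d$code, cp$code_set) &
              d$date >= ctx$index_date - w & d$date < ctx$index_date)
      },
      prescription = {
        w <- cp$window_days %||% 365
        d <- ctx$prescriptions
        any(code_matches(d$drug_code, cp$code_set) &
              d$start_date >= ctx$index_date - w & d$start_date < ctx$index_date)
      },
      cw_config_error(sprintf("unknown risk component type '%s'", cp$type))
    )
    if (isTRUE(hit)) total <- total + as.integer(cp$points)
  }
  total
}

#' Default stroke-risk score definition
#'
#' Ships the conventional CHA2DS2-VASc component/point table as editable
#' data (JSON under `extdata/`), not code: congestive heart failure 1,
#' hypertension 1, age >= 75 two, diabetes 1, prior stroke/TIA 2, vascular
#' disease 1, age 65-74 one, female sex 1. Any additive definition may be
#' substituted via the study config.
#'
#' @return A [risk_score_def()].
#' @export
default_risk_score <- function() {
  path <- system.file("extdata", "cha2ds2vasc.json", package = "cohortwatch")
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  risk_score_def(raw$name, raw$components)
}

#' Save / load covariate templates
#'
#' The template library is a named section of the study configuration: a
#' saved template is a named list of covariate specs that can be re-used
#' across studies. Saving under an existing name errors (names are
#' unique); loading an unknown name errors.
#'
#' @param config A `study_config`.
#' @param name Template name.
#' @param specs List of [covariate_spec()]s.
#' @return `save_template` returns the updated config; `load_template`
#'   returns the spec list.
#' @export
save_template <- function(config, name, specs) {
  stopifnot(inherits(config, "study_config"))
  if (name %in% names(config$covariate_templates)) {
    cw_config_error(sprintf("template '%s' already exists", name))
  }
  config$covariate_templates[[name]] <- specs
  config
}

#' @rdname save_template
#' @export
load_template <- function(config, name) {
  stopifnot(inherits(config, "study_config"))
  if (!name %in% names(config$covariate_templates)) {
    cw_config_error(sprintf("unknown template '%s'", name))
  }
  config$covariate_templates[[name]]
}
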