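# Synthetic EMR generator with known ground truth: confounded logistic
# treatment assignment, exponential (constant-baseline-hazard) outcome
# times under a configurable true hazard ratio, refill chains with
# stochastic gaps, pre-index history to exercise washout and incident
# exclusion filters, and administrative end-of-data censoring.
#
# The latent truth table is returned separately and is never consumed by
# any pipeline stage (the orchestrator accepts only the three EMR tables).

#' Specify a synthetic EMR simulation
#'
#' Defaults describe a plausible anticoagulant comparison in an atrial
#' fibrillation population: age ~ N(70, 10) years, 55% female, common
#' cardiovascular comorbidities, moderate confounding of treatment choice
#' (log-odds coefficients around 0.2-0.5), a baseline outcome hazard of
#' 5e-5 events per person-day (a few events per 100 subjects over two
#' years), a true treatment hazard ratio of 0.5, refill chains of 30/60/90
#' day supplies with exponential inter-refill gaps (mean 10 days, so a
#' tail of gaps exceeds the 30-day grace period and exercises the
#' discontinuation rule).
#'
#' @param n_patients Number of subjects (>= 2).
#' @param covariate_defs List of lists: `name`, `type` (`binary` /
#'   `continuous`), and `prevalence` or `mean`/`sd`; binary covariates
#'   named `rx_*` are realized as comedication prescriptions, all other
#'   binary covariates as lookback diagnoses.
#' @param treatment_model Named numeric: `intercept` plus log-odds per
#'   covariate (continuous covariates are standardized before entering).
#' @param outcome_models Named list per outcome: `baseline_hazard`
#'   (events per person-day), `log_hr_treatment` (the recoverable truth),
#'   `log_hr` (named numeric per covariate), `code` (diagnosis code
#'   written when the event is realized).
#' @param refill_model List: `supply_choices`, `supply_probs`,
#'   `mean_refills` (Poisson mean of refill count), `gap_mean` (mean of
#'   the exponential inter-refill gap, days; 0 gives back-to-back
#'   refills that can never discontinue).
#' @param history_model List: `prior_exposure_prob` (washout-violating
#'   prior exposure), `prior_outcome_prob` (per outcome, pre-index
#'   outcome diagnosis).
#' @param study_window Accrual window (dates).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_patients = 2000,
                            covariate_defs = list(
                              list(name = "age", type = "continuous", mean = 70, sd = 10),
                              list(name = "sex", type = "binary", prevalence = 0.55),
                              list(name = "hypertension", type = "binary", prevalence = 0.50),
                              list(name = "diabetes", type = "binary", prevalence = 0.30),
                              list(name = "heart_failure", type = "binary", prevalence = 0.20),
                              list(name = "rx_antiplatelet", type = "binary", prevalence = 0.30)
                            ),
                            treatment_model = c(intercept = -0.2, age = 0.30,
                                                sex = 0.10, hypertension = 0.40,
                                                diabetes = 0.30, heart_failure = 0.50,
                                                rx_antiplatelet = 0.20),
                            outcome_models = list(
                              stroke = list(baseline_hazard = 5e-5,
                                            log_hr_treatment = log(0.5),
                                            log_hr = c(age = 0.30, hypertension = 0.20,
                                                       diabetes = 0.20, heart_failure = 0.30),
                                            code = "I63.9")
                            ),
                            refill_model = list(supply_choices = c(30, 60, 90),
                                                supply_probs = c(0.5, 0.3, 0.2),
                                                mean_refills = 8,
                                                gap_mean = 10),
                            history_model = list(prior_exposure_prob = 0.05,
                                                 prior_outcome_prob = 0.05),
                            study_window = as.Date(c("2010-01-01", "2015-12-31")),
                            seed = 1L) {
  if (n_patients < 2) cw_config_error("n_patients must be >= 2")
  for (om in outcome_models) {
    if (!(om$baseline_hazard > 0)) cw_config_error("baseline hazard must be positive")
  }
  for (cd in covariate_defs) {
    if (cd$type == "binary" && !(cd$prevalence > 0 && cd$prevalence < 1)) {
      cw_config_error(sprintf("prevalence of '%s' must lie in (0,1)", cd$name))
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 covariate_defs = covariate_defs,
                 treatment_model = treatment_model,
                 outcome_models = outcome_models,
                 refill_model = refill_model,
                 history_model = history_model,
                 study_window = as.Date(study_window),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic EMR table set with ground truth
#'
#' Treatment is drawn from the logistic model on baseline covariates;
#' per-outcome event times are exponential with hazard
#' `lambda0 * exp(x'beta + treatment * logHR)` and are realized as a
#' diagnosis row (outcome code, random care setting) when they precede
#' the subject's end of data; exposure is realized as a refill chain whose
#' gaps follow the refill model; binary covariates are realized as
#' lookback diagnosis/prescription rows so the covariate mapper can
#' recover them exactly; a small fraction of subjects receive
#' washout-violating prior exposure or pre-index outcome diagnoses to
#' exercise the cohort filters.
#'
#' @param spec A [simulation_spec()].
#' @return List: `tables` (an `emr_tables`), `truth` (per-patient latent
#'   data frame: group, linear predictors, latent event times), and
#'   `covariate_specs` (ready-made [covariate_spec()]s matching the
#'   generated history codes).
#' @export
generate_emr <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_patients
  ids <- sprintf("S%05d", seq_len(n))
  win <- spec$study_window
  win_days <- cw_days(win[1], win[2])

  # covariates
  Z <- list()
  for (cd in spec$covariate_defs) {
    Z[[cd$name]] <- if (cd$type == "binary") stats::rbinom(n, 1, cd$prevalence)
                    else stats::rnorm(n, cd$mean, cd$sd)
  }
  Z <- as.data.frame(Z)
  # standardized copies for the linear models
  Zs <- Z
  for (cd in spec$covariate_defs) {
    if (cd$type == "continuous") Zs[[cd$name]] <- (Z[[cd$name]] - cd$mean) / cd$sd
  }

  lin_trt <- rep(spec$treatment_model[["intercept"]], n)
  for (nm in setdiff(names(spec$treatment_model), "intercept")) {
    lin_trt <- lin_trt + spec$treatment_model[[nm]] * Zs[[nm]]
  }
  treated <- stats::rbinom(n, 1, stats::plogis(lin_trt))

  index <- win[1] + sample.int(win_days, n, replace = TRUE) - 1L
  data_end <- index + round(stats::runif(n, 365, 1460))
  age <- if ("age" %in% names(Z)) pmax(20, round(Z$age)) else rep(70L, n)
  birth <- index - round(age * 365.25) - sample.int(364L, n, replace = TRUE)
  sex <- if ("sex" %in% names(Z)) ifelse(Z$sex == 1, "female", "male")
         else sample(CW_SEXES, n, replace = TRUE)

  patients <- data.frame(patient_id = ids, birth_date = birth, sex = sex,
                         data_end_date = data_end, stringsAsFactors = FALSE)

  dx <- list(); rx <- list()
  add_dx <- function(pid, date, code, setting = NULL) {
    dx[[length(dx) + 1]] <<- data.frame(
      patient_id = pid, date = date, code = code,
      setting = setting %||% sample(CW_SETTINGS, length(pid), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  add_rx <- function(pid, drug, start, days) {
    rx[[length(rx) + 1]] <<- data.frame(
      patient_id = pid, drug_code = drug, start_date = start,
      days_supplied = as.integer(days), stringsAsFactors = FALSE)
  }

  # qualifying condition for all subjects (scattered over the lookback)
  add_dx(ids, index - sample.int(365L, n, replace = TRUE), "I48.0")

  # lookback comorbidity / comedication history mirroring the covariates
  for (cd in spec$covariate_defs) {
    if (cd$type != "binary" || cd$name == "sex") next
    has <- which(Z[[cd$name]] == 1)
    if (length(has) == 0) next
    when <- index[has] - sample.int(365L, length(has), replace = TRUE)
    if (startsWith(cd$name, "rx_")) {
      add_rx(ids[has], paste0("RX_", toupper(sub("^rx_", "", cd$name))), when, 30L)
    } else {
      add_dx(ids[has], when, paste0("DX_", toupper(cd$name)))
    }
  }

  # exposure refill chains (index drug class by arm)
  rm <- spec$refill_model
  n_refills <- 1L + stats::rpois(n, rm$mean_refills)
  drug <- ifelse(treated == 1, "NOAC_A", "WARF")
  for (i in seq_len(n)) {
    k <- n_refills[i]
    supplies <- sample(rm$supply_choices, k, replace = TRUE, prob = rm$supply_probs)
    gaps <- if (rm$gap_mean <= 0) rep(0, k) else round(stats::rexp(k, 1 / rm$gap_mean))
    starts <- index[i] + cumsum(c(0, supplies[-k] + gaps[-k]))
    keep <- starts < data_end[i]
    add_rx(rep(ids[i], sum(keep)), drug[i], starts[keep], supplies[keep])
  }

  # washout-violating prior exposure: must precede the study window (so it
  # cannot itself become the index) while staying within 365 days of the
  # index -- only subjects indexed early in the window can carry one
  hm <- spec$history_model
  prior_user <- stats::rbinom(n, 1, hm$prior_exposure_prob) == 1 &
    cw_days(win[1], index) <= 300
  if (any(prior_user)) {
    slack <- 364 - cw_days(win[1], index[prior_user])
    off <- 1L + floor(stats::runif(sum(prior_user)) * slack)
    add_rx(ids[prior_user], drug[prior_user], win[1] - off, 30L)
  }

  # outcomes: latent exponential times, realized when before data_end
  truth <- data.frame(patient_id = ids, treated = treated,
                      index_date = index, data_end_date = data_end,
                      ps_linear = lin_trt, prior_user = prior_user,
                      stringsAsFactors = FALSE)
  for (nm in names(Z)) truth[[nm]] <- Z[[nm]]
  for (onm in names(spec$outcome_models)) {
    om <- spec$outcome_models[[onm]]
    lin <- rep(0, n)
    for (cn in names(om$log_hr)) lin <- lin + om$log_hr[[cn]] * Zs[[cn]]
    rate <- om$baseline_hazard * exp(lin + treated * om$log_hr_treatment)
    t_lat <- stats::rexp(n, rate)
    realized <- ceiling(t_lat) < cw_days(index, data_end)
    if (any(realized)) {
      add_dx(ids[realized], index[realized] + ceiling(t_lat[realized]), om$code)
    }
    truth[[paste0("latent_time_", onm)]] <- t_lat
    truth[[paste0("event_", onm)]] <- as.integer(realized)
    # pre-index outcome history (incident-exclusion fodder)
    prior_out <- stats::rbinom(n, 1, hm$prior_outcome_prob) == 1
    if (any(prior_out)) {
      add_dx(ids[prior_out],
             index[prior_out] - sample.int(365L, sum(prior_out), replace = TRUE),
             om$code)
    }
    truth[[paste0("prior_", onm)]] <- as.integer(prior_out)
  }

  dx <- do.call(rbind, dx); rx <- do.call(rbind, rx)
  dx <- dx[order(dx$patient_id, dx$date, dx$code), , drop = FALSE]
  rx <- rx[order(rx$patient_id, rx$start_date, rx$drug_code), , drop = FALSE]
  rownames(dx) <- rownames(rx) <- NULL

  cov_specs <- list()
  for (cd in spec$covariate_defs) {
    if (cd$name == "sex") next
    if (cd$type == "continuous") next
    cov_specs[[length(cov_specs) + 1]] <- if (startsWith(cd$name, "rx_")) {
      covariate_spec(cd$name, "prescription_flag",
                     code_set(cd$name, paste0("RX_", toupper(sub("^rx_", "", cd$name))), "exact"))
    } else {
      covariate_spec(cd$name, "diagnosis_flag",
                     code_set(cd$name, paste0("DX_", toupper(cd$name)), "exact"))
    }
  }

  list(tables = emr_tables(patients, dx, rx), truth = truth,
       covariate_specs = cov_specs)
}

#' Hand-written worked fixture
#'
#' A 16-patient EMR table set committed under `extdata/fixture/`, covering
#' every branch of the pipeline: prior-use (washout) exclusion, same-day
#' dual exposure, a required-diagnosis failure, an under-age subject, a
#' lookback cancer exclusion, a pre-index outcome removed from one
#' incident subcohort only, refill gaps of exactly 30 (continuous) and 31
#' (discontinued) days, an event falling after AT censoring but inside
#' ITT follow-up, and administrative censoring before the 730-day
#' horizon. Hand-traced expected outputs live beside it under
#' `extdata/fixture/oracle/`.
#'
#' @return List with `tables` (an `emr_tables`), `config_path`, and
#'   `oracle_dir`.
#' @export
worked_fixture <- function() {
  dir <- system.file("extdata", "fixture", package = "cohortwatch")
  list(
    tables = read_emr_tables(file.path(dir, "patients.csv"),
                             file.path(dir, "diagnoses.csv"),
                             file.path(dir, "prescriptions.csv")),
    config_path = file.path(dir, "study.json"),
    input_dir = dir,
    oracle_dir = file.path(dir, "oracle")
  )
}
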