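# ITT / AT follow-up construction: treatment episodes from refill chains
# with a strict >gap_days discontinuation rule, outcome ascertainment, and
# incidence summaries with exact binomial confidence intervals.
#
# Prescription end date is start + days_supplied (exclusive). A refill
# whose start is no more than gap_days after the running episode end
# continues the episode; a gap strictly greater than gap_days closes it,
# with discontinuation at the end of the last supply. Overlapping supplies
# extend the running end by max().

#' Build treatment episodes from a prescription chain
#'
#' @param prescriptions Prescription rows (already restricted to the drug
#'   class of interest); any row order accepted.
#' @param gap_days Grace gap in days (default 30). The rule is strict: a
#'   gap equal to `gap_days` does NOT discontinue.
#' @return Data frame `patient_id`, `episode_start`, `episode_end`
#'   (end exclusive), episodes per patient disjoint, ordered, separated by
#'   gaps greater than `gap_days`.
#' @export
build_episodes <- function(prescriptions, gap_days = 30) {
  rx <- prescriptions[order(prescriptions$patient_id, prescriptions$start_date), , drop = FALSE]
  out <- list()
  for (pid in unique(rx$patient_id)) {
    r <- rx[rx$patient_id == pid, , drop = FALSE]
    starts <- r$start_date
    ends <- r$start_date + r$days_supplied
    ep_start <- starts[1]; ep_end <- ends[1]
    for (i in seq_len(nrow(r))[-1]) {
      if (cw_days(ep_end, starts[i]) > gap_days) {
        out[[length(out) + 1]] <- data.frame(patient_id = pid,
                                             episode_start = ep_start,
                                             episode_end = ep_end)
        ep_start <- starts[i]; ep_end <- ends[i]
      } else {
        ep_end <- max(ep_end, ends[i])
      }
    }
    out[[length(out) + 1]] <- data.frame(patient_id = pid,
                                         episode_start = ep_start,
                                         episode_end = ep_end)
  }
  if (length(out) == 0) {
    return(data.frame(patient_id = character(),
                      episode_start = as.Date(character()),
                      episode_end = as.Date(character())))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Earliest qualifying outcome diagnosis after index
#'
#' Outcomes are ascertained strictly after the index date (a same-day
#' diagnosis is treated as prevalent and is the business of the incident
#' subcohort filter, not follow-up), in any care setting.
#'
#' @param diagnoses Diagnosis rows for one subject.
#' @param outcome_set Outcome [code_set()].
#' @param index_date Index date.
#' @return A `Date`, or `NA` if no qualifying diagnosis exists.
#' @export
first_outcome <- function(diagnoses, outcome_set, index_date) {
  hit <- diagnoses[code_matches(diagnoses$code, outcome_set) &
                     diagnoses$date > index_date, , drop = FALSE]
  if (nrow(hit) == 0) return(as.Date(NA))
  min(hit$date)
}

#' Construct one subject's follow-up record
#'
#' Candidate end points are: the outcome date; `index + max_followup_days`;
#' the subject's administrative `data_end`; and, in AT mode only, the
#' discontinuation date (end of the first treatment episode, which starts
#' at index). Follow-up ends at the earliest candidate ("whichever came
#' first"); on exact ties the reason precedence is outcome,
#' discontinuation, max_followup, data_end. The event indicator is 1 iff
#' the end reason is the outcome.
#'
#' @param index_date Index date.
#' @param mode `"ITT"` or `"AT"`.
#' @param episodes Episode data frame for this subject (AT only; the first
#'   episode must cover the index date).
#' @param outcome_date Outcome date or `NA`.
#' @param max_followup_days Follow-up horizon in days (default 730).
#' @param data_end Administrative end of data coverage.
#' @return List `time_days`, `event`, `end_reason`, `end_date`.
#' @export
build_followup <- function(index_date, mode = c("ITT", "AT"), episodes = NULL,
                           outcome_date = as.Date(NA), max_followup_days = 730,
                           data_end) {
  mode <- match.arg(mode)
  cand <- c(
    outcome = if (!is.na(outcome_date)) as.numeric(outcome_date) else Inf,
    max_followup = as.numeric(index_date) + max_followup_days,
    data_end = as.numeric(data_end)
  )
  if (mode == "AT") {
    if (is.null(episodes) || nrow(episodes) == 0) {
      cw_structural_error("AT follow-up requires treatment episodes")
    }
    ep <- episodes[order(episodes$episode_start), , drop = FALSE]
    if (!(ep$episode_start[1] <= index_date && ep$episode_end[1] > index_date)) {
      cw_structural_error("first treatment episode must cover the index date")
    }
    cand <- c(cand, discontinuation = as.numeric(ep$episode_end[1]))
  }
  precedence <- c("outcome", "discontinuation", "max_followup", "data_end")
  cand <- cand[order(match(names(cand), precedence))]
  end <- min(cand)
  reason <- names(cand)[which(cand == end)[1]]
  time_days <- as.integer(end - as.numeric(index_date))
  if (time_days < 0) cw_structural_error("negative follow-up time")
  list(time_days = time_days,
       event = as.integer(reason == "outcome"),
       end_reason = reason,
       end_date = as.Date(end, origin = "1970-01-01"))
}

#' Follow-up records for a cohort under one mode and outcome
#'
#' Builds, per member: the episode chain of the subject's index drug class
#' (by default within-class switching continues the episode and the other
#' comparison arm does not contribute, so an arm switch censors AT
#' follow-up), the first post-index outcome, and the [build_followup()]
#' record.
#'
#' @param members Patient ids (e.g. matched subjects).
#' @param index Index assignments with `index_group`.
#' @param tables `emr_tables`.
#' @param exposure_sets Named list of exposure code sets.
#' @param outcome_set Outcome [code_set()].
#' @param mode `"ITT"` or `"AT"`.
#' @param gap_days,max_followup_days Study constants.
#' @return Data frame `patient_id`, `group`, `mode`, `time_days`, `event`,
#'   `end_reason`, ordered by `patient_id`.
#' @export
followup_table <- function(members, index, tables, exposure_sets, outcome_set,
                           mode = c("ITT", "AT"), gap_days = 30,
                           max_followup_days = 730) {
  mode <- match.arg(mode)
  members <- sort(members)
  idx <- index[match(members, index$patient_id), , drop = FALSE]
  if (anyNA(idx$patient_id)) cw_structural_error("member lacks index assignment")
  pts <- tables$patients[match(members, tables$patients$patient_id), , drop = FALSE]
  exposure_sets <- code_set_map(exposure_sets)
  recs <- lapply(seq_along(members), function(i) {
    pid <- members[i]
    dx <- tables$diagnoses[tables$diagnoses$patient_id == pid, , drop = FALSE]
    od <- first_outcome(dx, outcome_set, idx$index_date[i])
    eps <- NULL
    if (mode == "AT") {
      cls <- exposure_sets[[idx$index_group[i]]]
      rx <- tables$prescriptions[tables$prescriptions$patient_id == pid, , drop = FALSE]
      rx <- rx[code_matches(rx$drug_code, cls), , drop = FALSE]
      eps <- build_episodes(rx, gap_days)
    }
    fu <- build_followup(idx$index_date[i], mode, eps, od,
                         max_followup_days, pts$data_end_date[i])
    data.frame(patient_id = pid, group = idx$index_group[i], mode = mode,
               time_days = fu$time_days, event = fu$event,
               end_reason = fu$end_reason, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, recs)
  rownames(res) <- NULL
  res
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form: lower `qbeta(alpha/2, x, n - x + 1)` (0 when
#' `x = 0`), upper `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`).
#'
#' @param x Number of events.
#' @param n Number of trials.
#' @param alpha Two-sided level complement (default 0.05).
#' @return Numeric length-2 vector (lower, upper) on the proportion scale.
#' @export
exact_binomial_ci <- function(x, n, alpha = 0.05) {
  if (n < 1 || x < 0 || x > n) cw_validation_error("need 0 <= x <= n, n >= 1")
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Exact Poisson (Garwood) confidence interval for a count
#'
#' Chi-square/gamma form: lower `qgamma(alpha/2, x)` (0 when `x = 0`),
#' upper `qgamma(1 - alpha/2, x + 1)`, on the count scale.
#'
#' @param x Number of events.
#' @param alpha Two-sided level complement (default 0.05).
#' @return Numeric length-2 vector (lower, upper) on the count scale.
#' @export
exact_poisson_ci <- function(x, alpha = 0.05) {
  if (x < 0) cw_validation_error("need x >= 0")
  c(lower = if (x == 0) 0 else stats::qgamma(alpha / 2, x),
    upper = stats::qgamma(1 - alpha / 2, x + 1))
}

#' Incidence summary for one group/mode/outcome cell
#'
#' Incidence density is `100000 * events / person_days` (per 100,000
#' person-days); cumulative incidence is `100 * events / n_subjects` with
#' an exact 95% CI reported in percent. The default CI treats the event
#' count as Poisson and scales its exact (Garwood) interval by
#' `n_subjects` -- the form that reproduces published incidence tables of
#' this design to the printed precision; the exact binomial
#' (Clopper-Pearson) interval is available via `ci_method`. The method
#' used is reported in the output.
#'
#' @param records Follow-up records (one group/mode), or pass the
#'   aggregates directly via `events`, `person_days`, `n_subjects`.
#' @param events,person_days,n_subjects Aggregates (used when `records`
#'   is `NULL`).
#' @param alpha CI level complement.
#' @param ci_method `"exact_poisson"` (default) or `"clopper_pearson"`.
#' @return List of class `incidence_summary`: `n_subjects`, `events`,
#'   `person_days`, `incidence_density`, `cumulative_incidence_pct`,
#'   `ci95` (percent), `ci_method`.
#' @export
incidence <- function(records = NULL, events = NULL, person_days = NULL,
                      n_subjects = NULL, alpha = 0.05,
                      ci_method = c("exact_poisson", "clopper_pearson")) {
  ci_method <- match.arg(ci_method)
  if (!is.null(records)) {
    events <- sum(records$event)
    person_days <- sum(records$time_days)
    n_subjects <- nrow(records)
  }
  if (n_subjects < 1) cw_validation_error("need at least one subject")
  if (person_days <= 0 && events > 0) {
    cw_structural_error("zero person-days with events > 0")
  }
  dens <- if (person_days > 0) 1e5 * events / person_days else 0
  ci <- if (ci_method == "clopper_pearson") {
    100 * exact_binomial_ci(events, n_subjects, alpha)
  } else {
    100 * exact_poisson_ci(events, alpha) / n_subjects
  }
  structure(list(
    n_subjects = n_subjects, events = events, person_days = person_days,
    incidence_density = dens,
    cumulative_incidence_pct = 100 * events / n_subjects,
    ci95 = unname(ci),
    ci_method = ci_method
  ), class = "incidence_summary")
}
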