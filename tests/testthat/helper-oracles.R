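# Independent oracles and tiny table builders used across the suite.
# These deliberately re-derive results by brute force / closed form and
# must stay independent of the implementation paths they check.

# naive code matching by explicit scan
naive_code_match <- function(code, codes, mode) {
  vapply(code, function(cd) {
    if (mode == "exact") any(vapply(codes, function(s) identical(cd, s), TRUE))
    else any(vapply(codes, function(s) substr(cd, 1, nchar(s)) == s, TRUE))
  }, TRUE, USE.NAMES = FALSE)
}

# loop-based Cox log partial likelihood (Breslow; equals Efron when untied)
naive_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force 1:1 nearest-available caliper matching: same seed-derived
# processing order convention, assignment by explicit scan
naive_greedy_match <- function(scores, group, ids, caliper, seed) {
  t_ids <- sort(ids[group == 1]); c_ids <- sort(ids[group == 0])
  xt <- scores[match(t_ids, ids)]; xc <- scores[match(c_ids, ids)]
  set.seed(seed)
  ord <- sample.int(length(t_ids))
  taken <- rep(FALSE, length(c_ids))
  pairs <- list()
  for (i in ord) {
    best_j <- NA; best_d <- Inf
    for (j in seq_along(c_ids)) {
      if (taken[j]) next
      d <- abs(xc[j] - xt[i])
      if (d > caliper + 1e-12) next
      if (d < best_d - 1e-15 ||
          (abs(d - best_d) <= 1e-15 && !is.na(best_j) && c_ids[j] < c_ids[best_j])) {
        best_d <- d; best_j <- j
      }
    }
    if (!is.na(best_j)) {
      taken[best_j] <- TRUE
      pairs[[length(pairs) + 1]] <- data.frame(
        treated_id = t_ids[i], control_id = c_ids[best_j],
        distance = best_d, stringsAsFactors = FALSE)
    }
  }
  if (length(pairs) == 0) return(data.frame(treated_id = character(),
                                            control_id = character(),
                                            distance = numeric()))
  out <- do.call(rbind, pairs)
  out[order(out$treated_id), ]
}

# minimal three-table builder for hand-constructed cases
mk_tables <- function(patients = NULL, diagnoses = NULL, prescriptions = NULL) {
  if (is.null(patients)) {
    patients <- data.frame(patient_id = "A", birth_date = "1950-01-01",
                           sex = "male", data_end_date = "2020-12-31")
  }
  if (is.null(diagnoses)) {
    diagnoses <- data.frame(patient_id = character(), date = character(),
                            code = character(), setting = character())
  }
  if (is.null(prescriptions)) {
    prescriptions <- data.frame(patient_id = character(), drug_code = character(),
                                start_date = character(), days_supplied = integer())
  }
  emr_tables(patients, diagnoses, prescriptions)
}

mk_index <- function(ids, dates, groups = NULL) {
  data.frame(patient_id = ids, index_date = as.Date(dates),
             index_group = groups %||% rep("a", length(ids)),
             stringsAsFactors = FALSE)
}

fixture_paths <- function() {
  dir <- system.file("extdata", "fixture", package = "cohortwatch")
  list(dir = dir, config = file.path(dir, "study.json"),
       oracle = file.path(dir, "oracle"))
}
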