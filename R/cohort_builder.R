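# Attrition "cohort tree": sequential inclusion/exclusion with provenance
# counts, new-user index assignment, incident-outcome subcohorts.
#
# Window convention: every pre/post-index window (a, b) means the half-open
# day interval [index + a, index + b). In particular [-365, 0) is "within 1
# year before the index date" and excludes the index date itself, so the
# index prescription or a same-day diagnosis never self-excludes a subject.

#' Define an attrition criterion
#'
#' @param label Human-readable label (also feeds the node id).
#' @param kind One of `require_diagnosis`, `exclude_diagnosis`,
#'   `require_prescription`, `exclude_prescription`, `age_at_least`,
#'   `custom_flag`.
#' @param code_set A [code_set()] (required for diagnosis/prescription
#'   kinds).
#' @param window Numeric length-2 offsets (days) relative to the index
#'   date; the interval is `[index + window[1], index + window[2])`.
#' @param settings Care settings considered for diagnosis criteria.
#' @param min_count Minimum number of matching records (default 1).
#' @param min_age Completed years, for `age_at_least`.
#' @param predicate For `custom_flag`: `function(patient_id, tables, index_row)`
#'   returning TRUE to retain.
#' @return An object of class `cw_criterion`.
#' @export
criterion <- function(label, kind, code_set = NULL, window = c(-Inf, 0),
                      settings = CW_SETTINGS, min_count = 1L,
                      min_age = NULL, predicate = NULL) {
  kinds <- c("require_diagnosis", "exclude_diagnosis", "require_prescription",
             "exclude_prescription", "age_at_least", "custom_flag")
  if (!kind %in% kinds) cw_config_error(sprintf("unknown criterion kind '%s'", kind))
  if (kind %in% kinds[1:4] && is.null(code_set)) {
    cw_config_error(sprintf("criterion '%s' (%s) requires a code set", label, kind))
  }
  if (length(window) != 2 || window[1] > window[2]) {
    cw_config_error(sprintf("criterion '%s': window offsets must be ordered", label))
  }
  if (min_count < 1) cw_config_error("min_count must be >= 1")
  if (kind == "age_at_least" && is.null(min_age)) {
    cw_config_error("age_at_least criterion requires min_age")
  }
  structure(list(label = label, kind = kind, code_set = code_set,
                 window = as.numeric(window), settings = settings,
                 min_count = as.integer(min_count), min_age = min_age,
                 predicate = predicate),
            class = "cw_criterion")
}

new_node <- function(label, members, parent = NULL, n_in = length(members)) {
  members <- sort(unique(as.character(members)))
  id <- cw_hash32(paste0(parent$node_id %||% "", "/", label))
  structure(list(node_id = id, label = label,
                 parent = parent$node_id %||% NA_character_,
                 members = members,
                 n_in = as.integer(n_in),
                 n_out = length(members),
                 n_dropped = as.integer(n_in) - length(members)),
            class = "cohort_node")
}

#' @export
print.cohort_node <- function(x, ...) {
  cat(sprintf("<cohort_node %s> %s: in %d, dropped %d, out %d\n",
              x$node_id, x$label, x$n_in, x$n_dropped, x$n_out))
  invisible(x)
}

#' Identify new users of the comparison drugs
#'
#' Implements the new-user design: the index date is the first start of any
#' exposure-set drug inside the study window; subjects with any exposure
#' prescription in the washout interval `[index - washout_days, index)` are
#' excluded (prevalent users), as are subjects whose index date carries
#' prescriptions from both comparison arms (ambiguous group). Every filter
#' emits a `cohort_node` so attrition is fully accounted.
#'
#' @param tables An `emr_tables` list.
#' @param exposure_sets Named list of exactly two drug [code_set()]s.
#' @param study_window Length-2 date vector.
#' @param washout_days Washout length in days; `Inf` means all recorded
#'   history disqualifies.
#' @return List with `index` (data frame `patient_id`, `index_date`,
#'   `index_group`) and `nodes` (list of `cohort_node`s: all patients,
#'   exposure-in-window, washout, single-group-at-index).
#' @export
identify_new_users <- function(tables, exposure_sets, study_window, washout_days = 365) {
  if (length(exposure_sets) == 0) cw_config_error("exposure_sets must be non-empty")
  exposure_sets <- code_set_map(exposure_sets)
  rx <- tables$prescriptions
  grp <- rep(NA_character_, nrow(rx))
  for (g in names(exposure_sets)) {
    grp[is.na(grp) & code_matches(rx$drug_code, exposure_sets[[g]])] <- g
  }
  exp_rx <- rx[!is.na(grp), , drop = FALSE]
  exp_grp <- grp[!is.na(grp)]

  root <- new_node("all patients", tables$patients$patient_id)

  in_win <- exp_rx$start_date >= study_window[1] & exp_rx$start_date <= study_window[2]
  win_rx <- exp_rx[in_win, , drop = FALSE]
  win_grp <- exp_grp[in_win]
  with_exposure <- intersect(root$members, unique(win_rx$patient_id))
  n_exposed <- new_node("exposure prescription within study window",
                        with_exposure, root, n_in = root$n_out)

  # index date: first in-window exposure start per patient
  ord <- order(win_rx$patient_id, win_rx$start_date)
  win_rx <- win_rx[ord, , drop = FALSE]; win_grp <- win_grp[ord]
  first_idx <- !duplicated(win_rx$patient_id)
  index <- data.frame(patient_id = win_rx$patient_id[first_idx],
                      index_date = win_rx$start_date[first_idx],
                      stringsAsFactors = FALSE)
  index <- index[index$patient_id %in% n_exposed$members, , drop = FALSE]

  # washout: any exposure prescription in [index - washout, index)
  idx_of <- stats::setNames(index$index_date, index$patient_id)
  pre <- exp_rx[exp_rx$patient_id %in% index$patient_id, , drop = FALSE]
  pre_idx <- idx_of[pre$patient_id]
  lower_ok <- if (is.infinite(washout_days)) rep(TRUE, nrow(pre)) else
    pre$start_date >= pre_idx - washout_days
  prior <- pre$start_date < pre_idx & lower_ok
  prior_users <- unique(pre$patient_id[prior])
  keep <- setdiff(n_exposed$members, prior_users)
  n_washout <- new_node(sprintf("no exposure prescription within %s days before index",
                                format(washout_days)),
                        keep, n_exposed, n_in = n_exposed$n_out)

  # group at index: all exposure groups with a prescription starting on index
  on_index <- win_rx[win_rx$start_date == idx_of[win_rx$patient_id], , drop = FALSE]
  on_grp <- win_grp[win_rx$start_date == idx_of[win_rx$patient_id]]
  ngrp <- tapply(on_grp, on_index$patient_id, function(g) length(unique(g)))
  dual <- names(ngrp)[ngrp > 1]
  keep <- setdiff(n_washout$members, dual)
  n_single <- new_node("single exposure group on index date",
                       keep, n_washout, n_in = n_washout$n_out)

  one_grp <- tapply(on_grp, on_index$patient_id, function(g) unique(g)[1])
  index$index_group <- unname(one_grp[index$patient_id])
  index <- index[index$patient_id %in% n_single$members, , drop = FALSE]
  index <- index[order(index$patient_id), , drop = FALSE]
  rownames(index) <- NULL

  list(index = index, nodes = list(root, n_exposed, n_washout, n_single))
}

count_matching <- function(members, crit, tables, index) {
  idx_of <- stats::setNames(index$index_date, index$patient_id)
  if (any(!members %in% names(idx_of))) {
    cw_structural_error("cohort member lacks an index assignment")
  }
  tab <- if (grepl("diagnosis", crit$kind)) tables$diagnoses else tables$prescriptions
  datecol <- if (grepl("diagnosis", crit$kind)) "date" else "start_date"
  rows <- tab[tab$patient_id %in% members, , drop = FALSE]
  if (grepl("diagnosis", crit$kind)) {
    rows <- rows[rows$setting %in% crit$settings, , drop = FALSE]
  }
  codecol <- if (grepl("diagnosis", crit$kind)) "code" else "drug_code"
  rows <- rows[code_matches(rows[[codecol]], crit$code_set), , drop = FALSE]
  ref <- idx_of[rows$patient_id]
  lo <- if (is.infinite(crit$window[1])) rep(TRUE, nrow(rows)) else
    rows[[datecol]] >= ref + crit$window[1]
  hi <- if (is.infinite(crit$window[2])) rep(TRUE, nrow(rows)) else
    rows[[datecol]] < ref + crit$window[2]
  rows <- rows[lo & hi, , drop = FALSE]
  counts <- table(factor(rows$patient_id, levels = members))
  as.integer(counts)
}

#' Apply one criterion, producing a child node
#'
#' `require_*` keeps members with at least `min_count` matching records in
#' the criterion window; `exclude_*` drops them. `age_at_least` keeps
#' members whose age in completed years at the index date reaches
#' `min_age` (the boundary is inclusive).
#'
#' @param node Parent `cohort_node`.
#' @param crit A [criterion()].
#' @param tables `emr_tables`.
#' @param index Index assignment data frame (from [identify_new_users()]).
#' @return The child `cohort_node`.
#' @export
apply_criterion <- function(node, crit, tables, index) {
  members <- node$members
  if (length(members) == 0) {
    return(new_node(crit$label, character(), node, n_in = 0L))
  }
  keep <- switch(crit$kind,
    age_at_least = {
      pts <- tables$patients[match(members, tables$patients$patient_id), , drop = FALSE]
      idx <- index$index_date[match(members, index$patient_id)]
      if (anyNA(idx)) cw_structural_error("cohort member lacks an index assignment")
      members[cw_age_years(pts$birth_date, idx) >= crit$min_age]
    },
    custom_flag = {
      ok <- vapply(members, function(p) {
        isTRUE(crit$predicate(p, tables, index[index$patient_id == p, , drop = FALSE]))
      }, TRUE)
      members[ok]
    },
    {
      n <- count_matching(members, crit, tables, index)
      hit <- n >= crit$min_count
      if (startsWith(crit$kind, "require")) members[hit] else members[!hit]
    }
  )
  new_node(crit$label, keep, node, n_in = node$n_out)
}

#' Build an incident-outcome subcohort
#'
#' Removes members with any exclusion-set diagnosis in
#' `[index - lookback_days, index)`, so that outcomes observed in follow-up
#' are incident (new) events. Several outcome subcohorts typically branch
#' from the same parent node.
#'
#' @param node Parent `cohort_node` (usually the main-cohort leaf).
#' @param exclusion_set [code_set()] of the outcome and its surrogates.
#' @param lookback_days Lookback length (days).
#' @param tables,index As in [apply_criterion()].
#' @param label Node label (defaults to a description of the set).
#' @return The subcohort `cohort_node`.
#' @export
build_incident_subcohort <- function(node, exclusion_set, lookback_days,
                                     tables, index, label = NULL) {
  if (is.null(exclusion_set)) {
    return(new_node(label %||% "incident subcohort (no exclusion)",
                    node$members, node, n_in = node$n_out))
  }
  crit <- criterion(label %||% sprintf("no %s diagnosis within %d days before index",
                                       exclusion_set$name, lookback_days),
                    "exclude_diagnosis", code_set = exclusion_set,
                    window = c(-lookback_days, 0))
  apply_criterion(node, crit, tables, index)
}

#' Tabulate an attrition tree
#'
#' @param tree List of `cohort_node`s in creation order.
#' @return Data frame with one row per node: `node_id`, `parent_id`,
#'   `label`, `n_in`, `n_dropped`, `n_out`. Along any parent chain the
#'   counts telescope: a node's `n_in` equals its parent's `n_out`.
#' @export
attrition_report <- function(tree) {
  ids <- vapply(tree, function(n) n$node_id, "")
  if (anyDuplicated(ids)) cw_structural_error("duplicate node ids in attrition tree")
  for (n in tree) {
    p <- n$parent
    if (!is.na(p)) {
      if (!p %in% ids) cw_structural_error(sprintf("node %s has unknown parent", n$node_id))
      parent <- tree[[match(p, ids)]]
      if (!all(n$members %in% parent$members)) {
        cw_structural_error(sprintf("node '%s' members are not a subset of parent", n$label))
      }
    }
  }
  # cycle check: walk each node to the root
  for (n in tree) {
    seen <- character()
    cur <- n
    while (!is.na(cur$parent)) {
      if (cur$node_id %in% seen) cw_structural_error("cycle detected in attrition tree")
      seen <- c(seen, cur$node_id)
      cur <- tree[[match(cur$parent, ids)]]
    }
  }
  data.frame(
    node_id = ids,
    parent_id = vapply(tree, function(n) n$parent, ""),
    label = vapply(tree, function(n) n$label, ""),
    n_in = vapply(tree, function(n) n$n_in, 1L),
    n_dropped = vapply(tree, function(n) n$n_dropped, 1L),
    n_out = vapply(tree, function(n) n$n_out, 1L),
    stringsAsFactors = FALSE
  )
}

#' Render an attrition tree as indented text
#'
#' @param tree List of `cohort_node`s.
#' @return Character vector, one line per node.
#' @export
format_attrition_tree <- function(tree) {
  ids <- vapply(tree, function(n) n$node_id, "")
  depth <- function(n) {
    d <- 0
    while (!is.na(n$parent)) { d <- d + 1; n <- tree[[match(n$parent, ids)]] }
    d
  }
  vapply(tree, function(n) {
    sprintf("%s- %s: n=%d (dropped %d of %d)",
            strrep("  ", depth(n)), n$label, n$n_out, n$n_dropped, n$n_in)
  }, "")
}
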