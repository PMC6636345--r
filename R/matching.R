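# Propensity scores by hand-rolled IRLS logistic regression, greedy 1:1
# nearest-neighbor caliper matching, and SMD balance diagnostics.

logit <- function(p) log(p / (1 - p))

#' Fit a logistic propensity model by IRLS
#'
#' Maximum-likelihood logistic regression of the treatment indicator on
#' the named covariates, implemented directly (iteratively reweighted
#' least squares with step-halving) rather than delegated, so that the
#' convergence and separation behavior is fully specified: convergence
#' when the score (gradient) components are all below `1e-8` in absolute
#' value or the relative log-likelihood change is below `1e-10`; at most
#' 100 iterations. Perfect separation (fitted probabilities within 1e-10
#' of 0/1 alongside diverging coefficients) raises a classed error, as
#' does a rank-deficient design (naming the collinear columns).
#'
#' @param rows An `analysis_ready` data frame (needs a 0/1 `group` column).
#' @param covariates Character vector of covariate column names (may be
#'   empty: intercept-only model).
#' @param group_col Name of the treatment column.
#' @return Object of class `propensity_fit`: `coefficients`, per-subject
#'   `scores` in (0,1), `converged`, `n_iterations`, `log_likelihood`,
#'   plus `patient_id` and `group` carried through for matching.
#' @export
fit_logistic <- function(rows, covariates = character(), group_col = "group") {
  y <- rows[[group_col]]
  if (is.null(y) || !all(y %in% c(0, 1))) {
    cw_validation_error("treatment column must be 0/1")
  }
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    cw_validation_error("need at least 2 subjects per group")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(rows[covariates], check.names = FALSE)))
  storage.mode(X) <- "double"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    cw_validation_error(sprintf("design matrix is rank deficient; collinear column(s): %s",
                                paste(bad, collapse = ", ")))
  }
  ll_of <- function(eta) sum(y * eta - log1p(exp(eta)))
  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  ll <- ll_of(eta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    p <- stats::plogis(eta)
    score <- drop(crossprod(X, y - p))
    if (max(abs(score)) <= 1e-8) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    # Newton step via weighted least squares
    XtWX <- crossprod(X * w, X)
    step <- solve(XtWX, score)
    new_beta <- beta + step
    new_eta <- drop(X %*% new_beta)
    new_ll <- ll_of(new_eta)
    halved <- 0
    while (!is.finite(new_ll) || new_ll < ll) {
      step <- step / 2
      halved <- halved + 1
      if (halved > 30) break
      new_beta <- beta + step
      new_eta <- drop(X %*% new_beta)
      new_ll <- ll_of(new_eta)
    }
    rel_change <- abs(new_ll - ll) / (abs(ll) + 1e-12)
    beta <- new_beta; eta <- new_eta
    ll <- new_ll
    if (rel_change <= 1e-10) {
      # likelihood has flattened; accept, subject to the separation check below
      converged <- TRUE
      break
    }
  }
  p <- stats::plogis(eta)
  if (any(p < 1e-6 | p > 1 - 1e-6) && max(abs(beta)) > 8) {
    cw_separation_error("perfect separation detected: fitted probabilities at 0/1 with diverging coefficients")
  }
  if (!converged && max(abs(drop(crossprod(X, y - p)))) > 1e-4) {
    cw_divergence_error("logistic regression failed to converge in 100 iterations")
  }
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    scores = unname(pmin(pmax(p, 1e-12), 1 - 1e-12)),
    converged = TRUE,
    n_iterations = iter,
    log_likelihood = ll,
    patient_id = rows$patient_id %||% as.character(seq_along(y)),
    group = as.integer(y),
    covariates = covariates
  ), class = "propensity_fit")
}

#' Greedy 1:1 nearest-neighbor caliper matching
#'
#' Treated subjects (group 1) are processed in a random order drawn from
#' `seed` (over the *sorted* treated ids, so the result is invariant to
#' input row order). Each takes the nearest available control on the
#' matching scale, provided the distance does not exceed the caliper; ties
#' go to the smallest control `patient_id`; matching is without
#' replacement. With `caliper_scale = "logit_sd"` both the distance and
#' the caliper live on the logit of the propensity score, and
#' `caliper_used = caliper * sd(logit(scores))` pooled over all subjects;
#' with `"raw"` the probabilities themselves are compared and the caliper
#' is taken as given.
#'
#' @param fit A [fit_logistic()] result, or a list with `scores`, `group`,
#'   `patient_id`.
#' @param caliper Positive caliper (default 0.2).
#' @param caliper_scale `"logit_sd"` or `"raw"`.
#' @param seed Integer seed for the processing order.
#' @return Object of class `matched_set`: `pairs` (data frame
#'   `treated_id`, `control_id`, `distance`), `caliper_used`,
#'   `unmatched_treated`, `unmatched_control`.
#' @export
ps_match <- function(fit, caliper = 0.2, caliper_scale = c("logit_sd", "raw"),
                     seed = 1L) {
  caliper_scale <- match.arg(caliper_scale)
  if (caliper <= 0) cw_config_error("caliper must be positive")
  scores <- fit$scores; group <- fit$group; ids <- fit$patient_id
  if (length(unique(group)) != 2) cw_validation_error("both groups must be present")
  if (caliper_scale == "logit_sd") {
    x <- logit(scores)
    caliper_used <- caliper * stats::sd(x)
    if (!is.finite(caliper_used)) caliper_used <- 0
  } else {
    x <- scores
    caliper_used <- caliper
  }
  t_ids <- sort(ids[group == 1]); c_ids <- sort(ids[group == 0])
  xt <- x[match(t_ids, ids)]; xc <- x[match(c_ids, ids)]
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  order_t <- sample.int(length(t_ids))
  avail <- rep(TRUE, length(c_ids))
  res_t <- character(0); res_c <- character(0); res_d <- numeric(0)
  for (i in order_t) {
    d <- abs(xc - xt[i])
    d[!avail] <- Inf
    ok <- which(d <= caliper_used + 1e-12)
    if (length(ok) == 0) next
    best <- ok[d[ok] == min(d[ok])]
    j <- best[order(c_ids[best])[1]]  # tie-break: smallest control id
    avail[j] <- FALSE
    res_t <- c(res_t, t_ids[i]); res_c <- c(res_c, c_ids[j]); res_d <- c(res_d, d[j])
  }
  ord <- order(res_t)
  structure(list(
    pairs = data.frame(treated_id = unname(res_t[ord]),
                       control_id = unname(res_c[ord]),
                       distance = unname(res_d[ord]),
                       stringsAsFactors = FALSE),
    caliper_used = caliper_used,
    caliper_scale = caliper_scale,
    unmatched_treated = setdiff(t_ids, res_t),
    unmatched_control = setdiff(c_ids, res_c)
  ), class = "matched_set")
}

smd_one <- function(x1, x0) {
  m1 <- mean(x1); m0 <- mean(x0)
  binary <- all(c(x1, x0) %in% c(0, 1))
  v <- if (binary) (m1 * (1 - m1) + m0 * (1 - m0)) / 2
       else (stats::var(x1) + stats::var(x0)) / 2
  if (v <= 0) {
    if (isTRUE(all.equal(m1, m0))) 0 else Inf
  } else {
    abs(m1 - m0) / sqrt(v)
  }
}

#' Standardized mean difference balance table
#'
#' Absolute SMDs per covariate, before matching (all rows) and, when a
#' matched set is supplied, after matching (paired rows only). Binary
#' covariates use the prevalence form
#' `|p1 - p0| / sqrt((p1(1-p1) + p0(1-p0))/2)`; continuous ones the
#' pooled-sample-variance form. A zero pooled variance with unequal means
#' reports `Inf` rather than failing.
#'
#' @param rows `analysis_ready` data frame.
#' @param covariates Covariate column names.
#' @param matched Optional [ps_match()] result.
#' @param smd_threshold Balance flag threshold (default 0.1).
#' @return Data frame `covariate`, `phase`, `mean_treated`,
#'   `mean_control`, `smd`, `balanced`.
#' @export
balance_table <- function(rows, covariates, matched = NULL, smd_threshold = 0.1) {
  one_phase <- function(df, phase) {
    do.call(rbind, lapply(covariates, function(cv) {
      x1 <- df[[cv]][df$group == 1]; x0 <- df[[cv]][df$group == 0]
      s <- smd_one(x1, x0)
      data.frame(covariate = cv, phase = phase,
                 mean_treated = mean(x1), mean_control = mean(x0),
                 smd = s, balanced = is.finite(s) && s < smd_threshold,
                 stringsAsFactors = FALSE)
    }))
  }
  out <- one_phase(rows, "before")
  if (!is.null(matched)) {
    keep <- rows$patient_id %in% c(matched$pairs$treated_id, matched$pairs$control_id)
    out <- rbind(out, one_phase(rows[keep, , drop = FALSE], "after"))
  }
  rownames(out) <- NULL
  out
}
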