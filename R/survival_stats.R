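# Kaplan-Meier product-limit estimation with Greenwood variance, and Cox
# proportional hazards by Newton-Raphson on the partial likelihood with
# Efron (default) or Breslow handling of tied event times.

#' Kaplan-Meier product-limit curve
#'
#' Steps only at distinct event times; censored-only times shrink the risk
#' set without adding a step. The variance follows Greenwood:
#' `Var(S) = S^2 * sum(d_i / (n_i (n_i - d_i)))`.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return Data frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `survival`, `se` at each distinct event time, S nonincreasing with
#'   S = 1 before the first event.
#' @export
km_curve <- function(time, event) {
  if (length(time) == 0) cw_validation_error("empty survival input")
  if (any(time <= 0)) cw_validation_error("times must be positive")
  tt <- sort(unique(time[event == 1]))
  if (length(tt) == 0) {
    return(structure(data.frame(time = numeric(0), n_risk = integer(0),
                                n_event = integer(0), survival = numeric(0),
                                se = numeric(0)),
                     class = c("km_curve", "data.frame")))
  }
  n_risk <- vapply(tt, function(t) sum(time >= t), 1L)
  n_event <- vapply(tt, function(t) sum(time == t & event == 1), 1L)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), Inf))
  se <- surv * sqrt(gw)
  se[surv == 0] <- 0
  structure(data.frame(time = tt, n_risk = n_risk, n_event = n_event,
                       survival = surv, se = se),
            class = c("km_curve", "data.frame"))
}

# Log partial likelihood, score and information at beta.
cox_derivs <- function(beta, time, event, X, ties) {
  n <- length(time); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time, -event)           # ascending time
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  eta <- eta[ord]; w <- w[ord]
  # reverse cumulative sums: S0(t_i) over subjects with time >= t_i
  revcum <- function(v) rev(cumsum(rev(v)))
  S0 <- revcum(w)
  S1 <- apply(X * w, 2, function(col) revcum(col))
  if (p == 1) S1 <- matrix(S1, ncol = 1)
  # S2 stored as p x p per position, built lazily inside the loop from
  # cumulative pairwise-product columns
  pair_idx <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  XP <- matrix(0, n, nrow(pair_idx))
  for (k in seq_len(nrow(pair_idx))) {
    XP[, k] <- X[, pair_idx[k, 1]] * X[, pair_idx[k, 2]] * w
  }
  S2flat <- apply(XP, 2, revcum)
  if (nrow(pair_idx) == 1) S2flat <- matrix(S2flat, ncol = 1)
  unpack_S2 <- function(i) {
    M <- matrix(0, p, p)
    for (k in seq_len(nrow(pair_idx))) {
      a <- pair_idx[k, 1]; b <- pair_idx[k, 2]
      M[a, b] <- S2flat[i, k]; M[b, a] <- S2flat[i, k]
    }
    M
  }
  ev_pos <- which(event == 1)
  ev_times <- unique(time[ev_pos])
  ll <- 0; U <- rep(0, p); I <- matrix(0, p, p)
  for (t in ev_times) {
    D <- which(time == t & event == 1)
    d <- length(D)
    first <- match(t, time)            # first position with this time
    s0 <- S0[first]; s1 <- S1[first, ]; s2 <- unpack_S2(first)
    ll <- ll + sum(eta[D])
    if (ties == "breslow" || d == 1) {
      ll <- ll - d * log(s0)
      U <- U + colSums(X[D, , drop = FALSE]) - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      # Efron: subtract the tied deaths' own contribution progressively
      wD <- w[D]
      s0d <- sum(wD)
      s1d <- colSums(X[D, , drop = FALSE] * wD)
      s2d <- matrix(0, p, p)
      for (j in D) s2d <- s2d + w[j] * tcrossprod(X[j, ])
      U <- U + colSums(X[D, , drop = FALSE])
      for (l in 0:(d - 1)) {
        f <- l / d
        s0l <- s0 - f * s0d
        s1l <- s1 - f * s1d
        s2l <- s2 - f * s2d
        ll <- ll - log(s0l)
        U <- U - s1l / s0l
        I <- I + s2l / s0l - tcrossprod(s1l / s0l)
      }
    }
  }
  list(ll = ll, U = U, I = I)
}

#' Fit a Cox proportional hazards model
#'
#' Newton-Raphson on the log partial likelihood with step-halving,
#' convergence when the absolute change in log-likelihood falls below
#' `1e-9` (at most 50 iterations); covariance is the inverse observed
#' information, Wald z and two-sided p-values, CI `exp(beta +/- z* se)`.
#' Efron's correction for tied event times is the default (day-granular
#' EMR data guarantees ties); Breslow is retained for cross-checks and
#' coincides exactly with Efron when no event times are tied.
#'
#' A monotone partial likelihood (a covariate that perfectly separates
#' events) raises a classed divergence error. A fit whose largest
#' coefficient standard error exceeds 2 is annotated `unstable = TRUE`
#' but still reported: such fits (e.g. a single event in one arm) are
#' statistically meaningless but must remain visible.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 indicators; at least one event required.
#' @param X Covariate matrix (columns named; no intercept).
#' @param ties `"efron"` or `"breslow"`.
#' @param alpha CI level complement (default 0.05).
#' @return Object of class `cox_fit`: `coefficients`, `hazard_ratios`,
#'   `se`, `wald_z`, `p_value`, `ci95` (matrix), `ties_method`,
#'   `converged`, `n_iterations`, `log_partial_likelihood`, `unstable`,
#'   `n`, `n_events`.
#' @export
cox_fit <- function(time, event, X, ties = c("efron", "breslow"), alpha = 0.05) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (any(time <= 0)) cw_validation_error("times must be positive")
  if (sum(event) < 1) cw_validation_error("at least one event is required")
  if (qr(X)$rank < ncol(X)) cw_validation_error("covariate matrix is rank deficient")
  p <- ncol(X)
  beta <- rep(0, p)
  dv <- cox_derivs(beta, time, event, X, ties)
  ll <- dv$ll
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(50L)) {
    step <- tryCatch(solve(dv$I, dv$U), error = function(e) NULL)
    if (is.null(step)) cw_divergence_error("singular information matrix in Cox fit")
    new_beta <- beta + step
    new_dv <- cox_derivs(new_beta, time, event, X, ties)
    halved <- 0
    while ((!is.finite(new_dv$ll) || new_dv$ll < ll) && halved < 30) {
      step <- step / 2; halved <- halved + 1
      new_beta <- beta + step
      new_dv <- cox_derivs(new_beta, time, event, X, ties)
    }
    delta_ll <- abs(new_dv$ll - ll)
    beta <- new_beta; dv <- new_dv; ll <- dv$ll
    if (max(abs(beta)) > 20) {
      cw_divergence_error(
        "monotone partial likelihood: a covariate perfectly separates events")
    }
    if (delta_ll <= 1e-9) { converged <- TRUE; break }
  }
  if (!converged) cw_divergence_error("Cox fit did not converge in 50 iterations")
  V <- solve(dv$I)
  se <- sqrt(diag(V))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  crit <- stats::qnorm(1 - alpha / 2)
  ci <- cbind(lower = exp(beta - crit * se), upper = exp(beta + crit * se))
  rownames(ci) <- colnames(X)
  structure(list(
    coefficients = stats::setNames(beta, colnames(X)),
    hazard_ratios = stats::setNames(exp(beta), colnames(X)),
    se = stats::setNames(se, colnames(X)),
    wald_z = stats::setNames(z, colnames(X)),
    p_value = stats::setNames(pv, colnames(X)),
    ci95 = ci,
    ties_method = ties,
    converged = converged,
    n_iterations = iter,
    log_partial_likelihood = ll,
    score_norm = sqrt(sum(dv$U^2)),
    unstable = any(se > 2),
    n = length(time),
    n_events = sum(event)
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n=%d, events=%d, loglik=%.4f%s\n",
              x$ties_method, x$n, x$n_events, x$log_partial_likelihood,
              if (x$unstable) " [UNSTABLE: se > 2]" else ""))
  print(data.frame(coef = x$coefficients, HR = x$hazard_ratios, se = x$se,
                   z = x$wald_z, p = x$p_value,
                   ci_low = x$ci95[, 1], ci_high = x$ci95[, 2]))
  invisible(x)
}

#' Summarize Cox fits as a hazard-ratio results table
#'
#' One reference row (HR printed as 1, p and CI blank) plus one row per
#' fit for the treated group, keyed by outcome and analysis mode.
#'
#' @param fits Named list: each element a list with `outcome`, `mode`,
#'   `fit` (a `cox_fit` or NULL for a failed fit), `events_ref`,
#'   `events_trt`, `ref_label`, `trt_label`, and optionally `note`.
#' @param treatment_term Name of the treatment coefficient in each fit.
#' @return Data frame mirroring a hazard-ratio table: `outcome`, `mode`,
#'   `group`, `events`, `hazard_ratio`, `p_value`, `ci_low`, `ci_high`,
#'   `unstable`, `note`.
#' @export
summarize_fits <- function(fits, treatment_term = "treatment") {
  if (length(fits) == 0) {
    return(data.frame(outcome = character(), mode = character(),
                      group = character(), events = integer(),
                      hazard_ratio = numeric(), p_value = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      unstable = logical(), note = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(fits, function(f) {
    ref <- data.frame(outcome = f$outcome, mode = f$mode, group = f$ref_label,
                      events = f$events_ref, hazard_ratio = 1,
                      p_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      unstable = FALSE, note = "", stringsAsFactors = FALSE)
    if (is.null(f$fit)) {
      trt <- data.frame(outcome = f$outcome, mode = f$mode, group = f$trt_label,
                        events = f$events_trt, hazard_ratio = NA_real_,
                        p_value = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        unstable = TRUE, note = f$note %||% "fit failed",
                        stringsAsFactors = FALSE)
    } else {
      k <- match(treatment_term, names(f$fit$coefficients))
      trt <- data.frame(outcome = f$outcome, mode = f$mode, group = f$trt_label,
                        events = f$events_trt,
                        hazard_ratio = unname(f$fit$hazard_ratios[k]),
                        p_value = unname(f$fit$p_value[k]),
                        ci_low = unname(f$fit$ci95[k, 1]),
                        ci_high = unname(f$fit$ci95[k, 2]),
                        unstable = f$fit$unstable,
                        note = f$note %||% "", stringsAsFactors = FALSE)
    }
    rbind(ref, trt)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
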