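# Hand-rolled logistic regression, greedy caliper matching, SMD balance.

test_that("logistic closed forms: intercept-only and saturated 2x2", {
  d <- data.frame(group = c(rep(1L, 30), rep(0L, 70)))
  f <- fit_logistic(d)
  expect_equal(unname(f$coefficients[1]), stats::qlogis(0.3), tolerance = 1e-8)
  # treated/covariate cross-table a=30, b=20, c=10, d=40 -> slope ln 6
  d2 <- data.frame(group = c(rep(1L, 50), rep(0L, 50)),
                   x = c(rep(1, 30), rep(0, 20), rep(1, 10), rep(0, 40)))
  f2 <- fit_logistic(d2, "x")
  expect_equal(unname(f2$coefficients["x"]), log(6), tolerance = 1e-7)
  expect_true(all(f2$scores > 0 & f2$scores < 1))
})

test_that("fitted coefficients are a local maximum of the likelihood", {
  set.seed(41)
  n <- 120
  d <- data.frame(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
  d$group <- rbinom(n, 1, stats::plogis(-0.3 + 0.8 * d$x1 - 0.5 * d$x2))
  f <- fit_logistic(d, c("x1", "x2"))
  X <- cbind(1, d$x1, d$x2)
  ll <- function(b) sum(d$group * (X %*% b) - log1p(exp(X %*% b)))
  at <- ll(f$coefficients)
  expect_equal(at, f$log_likelihood, tolerance = 1e-9)
  for (k in seq_along(f$coefficients)) {
    for (s in c(-1e-3, 1e-3)) {
      b <- f$coefficients; b[k] <- b[k] + s
      expect_lt(ll(b), at)
    }
  }
})

test_that("IRLS agrees with an independent numeric maximizer to 1e-6", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 80
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$group <- rbinom(n, 1, stats::plogis(0.2 + 0.6 * d$x1 - 0.4 * d$x2))
    if (sum(d$group) < 2 || sum(1 - d$group) < 2) next
    f <- fit_logistic(d, c("x1", "x2"))
    X <- cbind(1, d$x1, d$x2)
    nll <- function(b) -sum(d$group * (X %*% b) - log1p(exp(X %*% b)))
    opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    expect_equal(unname(f$coefficients), opt$par, tolerance = 1e-6)
  }
})

test_that("separation and rank deficiency raise classed errors", {
  d <- data.frame(group = c(rep(1L, 10), rep(0L, 10)),
                  x = c(rep(1, 10), rep(0, 10)))
  expect_error(fit_logistic(d, "x"), class = "cw_separation_error")
  d2 <- data.frame(group = rbinom(40, 1, 0.5), a = rnorm(40))
  d2$b <- 2 * d2$a
  expect_error(fit_logistic(d2, c("a", "b")), "b", class = "cw_validation_error")
})

test_that("matching follows nearest-within-caliper with id tie-breaks", {
  # identical scores: all treated matched at distance 0 until controls exhausted
  fit <- list(scores = rep(0.4, 7), group = c(1, 1, 1, 1, 0, 0, 0),
              patient_id = sprintf("P%d", 1:7))
  m <- ps_match(fit, caliper = 0.2, caliper_scale = "raw", seed = 5)
  expect_equal(nrow(m$pairs), 3)
  expect_true(all(m$pairs$distance == 0))
  expect_equal(length(m$unmatched_treated), 1)
  # enumeration case: single treated 0.30 against {0.10, 0.28, 0.50}, caliper .05
  fit2 <- list(scores = c(0.30, 0.10, 0.28, 0.50), group = c(1, 0, 0, 0),
               patient_id = c("T1", "C1", "C2", "C3"))
  m2 <- ps_match(fit2, caliper = 0.05, caliper_scale = "raw", seed = 1)
  expect_equal(m2$pairs$control_id, "C2")
  expect_equal(m2$pairs$distance, 0.02, tolerance = 1e-12)
  expect_equal(sort(m2$unmatched_control), c("C1", "C3"))
  expect_error(ps_match(fit2, caliper = 0), class = "cw_config_error")
})

test_that("greedy matcher equals brute-force nearest-available on small instances", {
  set.seed(43)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    ids <- sprintf("S%02d", sample(99, n))
    group <- c(1, 0, sample(c(0, 1), n - 2, TRUE))  # both groups present
    scores <- round(runif(n, 0.05, 0.95), 3)
    fit <- list(scores = scores, group = group, patient_id = ids)
    cal <- sample(c(0.05, 0.1, 0.3), 1)
    m <- ps_match(fit, caliper = cal, caliper_scale = "raw", seed = rep)
    o <- naive_greedy_match(scores, group, ids, cal, seed = rep)
    expect_equal(m$pairs$treated_id, o$treated_id)
    expect_equal(m$pairs$control_id, o$control_id)
    expect_equal(m$pairs$distance, o$distance, tolerance = 1e-12)
  }
})

test_that("pair distances respect the caliper and order-invariance holds", {
  set.seed(44)
  n <- 400
  d <- data.frame(x1 = rnorm(n), patient_id = sprintf("Q%04d", sample(9999, n)))
  d$group <- rbinom(n, 1, stats::plogis(0.5 * d$x1))
  f <- fit_logistic(d, "x1")
  m <- ps_match(f, caliper = 0.2, caliper_scale = "logit_sd", seed = 7)
  expect_true(all(m$pairs$distance <= m$caliper_used + 1e-12))
  # shuffle input rows: same seed -> identical pairs
  perm <- sample(n)
  d2 <- d[perm, ]
  f2 <- fit_logistic(d2, "x1")
  m2 <- ps_match(f2, caliper = 0.2, caliper_scale = "logit_sd", seed = 7)
  expect_equal(m$pairs, m2$pairs)
})

test_that("SMD formulas, degenerate cases, and self-match zeroing", {
  d <- data.frame(patient_id = sprintf("R%02d", 1:40),
                  group = rep(c(1, 0), each = 20),
                  bin = c(rep(1, 10), rep(0, 10), rep(1, 6), rep(0, 14)),
                  flat = 1)
  b <- balance_table(d, c("bin"))
  # p1 = .5, p0 = .3 -> 0.2/sqrt(0.23)
  expect_equal(b$smd[1], 0.2 / sqrt(0.23), tolerance = 1e-12)
  # p1 = p0 -> 0
  d0 <- d; d0$bin <- rep(c(1, 0), 20)
  expect_equal(balance_table(d0, "bin")$smd[1], 0)
  # zero pooled variance with unequal means -> Inf, not a crash
  dz <- d; dz$bin <- c(rep(1, 20), rep(0, 20))
  expect_true(is.infinite(balance_table(dz, "bin")$smd[1]))
  # constant everywhere -> equal means -> 0
  expect_equal(balance_table(d, "flat")$smd[1], 0)
  # perfect self-match: duplicate each treated as its own control
  dd <- data.frame(patient_id = c(sprintf("T%02d", 1:15), sprintf("C%02d", 1:15)),
                   group = rep(c(1, 0), each = 15),
                   x = rep(rnorm(15), 2))
  fitlike <- list(scores = rep(0.5, 30), group = dd$group, patient_id = dd$patient_id)
  mm <- ps_match(fitlike, caliper = 1, caliper_scale = "raw", seed = 1)
  after <- balance_table(dd, "x", mm)
  expect_equal(after$smd[after$phase == "after"], 0)
})

test_that("confounded synthetic cohort balances after matching", {
  sp <- simulation_spec(n_patients = 1200, seed = 45)
  g <- generate_emr(sp)
  tr <- g$truth
  tr$group <- tr$treated
  tr$patient_id <- tr$patient_id
  covs <- c("age", "sex", "hypertension", "diabetes", "heart_failure", "rx_antiplatelet")
  f <- fit_logistic(tr, covs)
  m <- ps_match(f, caliper = 0.2, caliper_scale = "logit_sd", seed = 45)
  bal <- balance_table(tr, covs, m)
  pre <- bal$smd[bal$phase == "before"]
  post <- bal$smd[bal$phase == "after"]
  expect_lt(mean(post), mean(pre))
  expect_gte(mean(post < 0.1), 0.9)
})
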