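---
title: "Methods and design decisions in cohortwatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions in cohortwatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The study design being automated

`cohortwatch` automates the comparative *new-user* (active-comparator)
cohort design for drug safety and effectiveness questions on structured
EMR extracts. The design restricts the cohort to subjects initiating one
of two comparison drugs after a drug-free washout, so that baseline
covariates are measured before exposure; confounding by indication is
then addressed by propensity-score matching, and outcome risk is
summarized by incidence measures, Kaplan-Meier curves and Cox hazard
ratios under two follow-up conventions (intention-to-treat and
as-treated). The running example throughout the package is oral
anticoagulation in nonvalvular atrial fibrillation — NOACs versus
warfarin, with ischemic stroke as the effectiveness outcome and
intracranial hemorrhage as the safety outcome — but every code set,
criterion, window and covariate is configuration, not code.

## Date and window conventions

All dates are ISO-8601 calendar dates and all intervals are half-open,
closed on the left: a window `(a, b)` relative to the index date means
`[index + a, index + b)` in whole days. Consequences worth knowing:

* "Within 1 year before the index date" is `[index − 365, index)`. The
  index date itself is *not* part of the pre-index period, so the index
  prescription can never wash itself out and a diagnosis coded on the
  index day never removes a subject from an incident subcohort.
* A prescription's end date is `start + days_supplied`, exclusive — the
  standard claims convention, since the data dictionary never defines
  "end of prescription" otherwise.
* Age at index is computed in completed years by calendar arithmetic
  (not division by 365.25), and "at least 20 years" is inclusive: a
  subject whose 20th birthday falls on the index date is retained.
* Outcomes are ascertained strictly *after* the index date. A same-day
  outcome diagnosis is treated as prevalent disease; it is the incident
  subcohort filter's business, not follow-up's. The boundary had to be
  chosen somewhere, and this choice keeps the two mechanisms disjoint.

## New-user identification

The index date is the first start of any exposure-set drug inside the
study window. Exclusions, in order, each with its own attrition node:
no exposure in the window at all; any exposure prescription in
`[index − washout, index)` (default washout 365 days; `Inf` gives an
all-history rule); prescriptions from *both* comparison arms starting on
the index date (group membership would be ambiguous). "Ever received"
prior exposure is operationalized as the washout window because the
surrounding convention in this design is the 1-year lookback; the
all-history mode is available by configuration.

Attrition nodes get deterministic identifiers (a 32-bit FNV-1a hash of
the parent id and the node label) rather than random UUIDs, so reruns
produce identical trees. The attrition report prints per-criterion drop
counts *and* the leaf size rather than assuming the drops are disjoint:
sequentially applied exclusions can overlap, and only the configured
order defines the per-step counts, while the leaf membership is
order-invariant (set intersection commutes — this is property-tested).

## Follow-up construction

Drug eras ("treatment episodes") are built per subject from the refill
chain of the *index drug class*: consecutive supplies merge when the gap
from the running episode end to the next start is at most `gap_days`
(default 30); a gap *strictly greater* than 30 days discontinues, with
the discontinuation instant at the end of the last supply, not at the
end of the grace gap — the conservative reading, since the gap rule
defines when a discontinuation happened but not the censoring instant.
Overlapping supplies extend the running end by `max()`. Switching
between drugs within the index class continues the episode; a switch to
the other comparison arm simply does not feed the episode chain and so
censors as-treated follow-up at supply exhaustion.

Follow-up ends at the earliest of: outcome; `index + 730` days; the
subject's administrative end of data; and, in AT mode only, the first
episode's discontinuation. On exact ties the end reason is resolved in
the order outcome, discontinuation, max-follow-up, data-end (the tie
precedence matters only for labeling; the person-time is identical).
Per subject, AT person-time and AT events can never exceed their ITT
counterparts — asserted property-style on generated data. Death is not
modeled as a competing risk; administrative data-end censoring subsumes
it.

## Incidence and its confidence interval

Incidence density is `100000 × events / person_days`. The column is
labeled per 100,000 person-days because that is what the arithmetic
produces; published tables of this design sometimes label the same
arithmetic "per 100,000 patient-years", so the label, not the number, is
the configurable part.

Cumulative incidence is `100 × events / n_subjects`, with an exact 95%
interval. Two exact methods are implemented and the summary reports
which one it used:

* `exact_poisson` (default): the Garwood interval for the event count —
  `qgamma(α/2, x)` to `qgamma(1 − α/2, x + 1)` — divided by `n`. This is
  the form that reproduces the reference tables this package's
  acceptance suite checks against, to all printed decimals, across both
  common and rare outcomes.
* `clopper_pearson`: the exact binomial interval via Beta quantiles.
  For rare events the two coincide to ~2 decimals in percent; the
  binomial form is the statistically tighter choice when `events/n` is
  not small, and its nominal-or-better coverage is verified by
  simulation in the test suite.

The Poisson form can exceed 100% for very small `n` — visible in the
worked fixture, where 1 event among 4 subjects yields an upper bound of
139%. That is a property of scaling a count interval by `n`, preserved
deliberately for fidelity to the published convention rather than
truncated.

## Propensity model, matching, and balance

The propensity model is logistic regression fit by iteratively
reweighted least squares, implemented in-package (not delegated to
`glm`) so its convergence contract is explicit: convergence when all
score components fall below 1e-8 or the relative log-likelihood change
falls below 1e-10, at most 100 iterations, with step-halving. Perfect
separation raises a classed error (fitted probabilities at 0/1 with
diverging coefficients), as does a rank-deficient design, naming the
collinear columns. An independent BFGS maximizer of the same likelihood
agrees to 1e-6 in the tests.

Matching is greedy 1:1 nearest-neighbor without replacement. The caliper
default is 0.2 × SD of the logit of the propensity score — when a bare
"caliper of 0.2" is quoted in the applied literature, the prevailing
convention is the logit-SD scale, but because the raw-probability
reading is also defensible both scales are first-class
(`caliper_scale = "raw"`). Distance is measured on the same scale as the
caliper. Treated subjects are processed in a random order drawn from the
seed over the *sorted* treated ids, so results are invariant to input
row order; ties go to the smallest control id. Greedy (not optimal)
matching is intentional: "nearest neighbor matching" in this tradition
is the sequential algorithm, and the brute-force oracle in the tests
checks exactly that semantics.

Balance uses absolute standardized mean differences with the pooled
two-group variance, `|SMD| < 0.1` flagging balance; a zero pooled
variance with unequal means reports `Inf` rather than failing.

## Survival estimation

Kaplan-Meier steps only at event times; censored-only times shrink the
risk set silently. Variance is Greenwood's. The Cox model maximizes the
log partial likelihood by Newton-Raphson with step-halving (convergence
|Δ log-lik| ≤ 1e-9, max 50 iterations), covariance from the inverse
observed information, Wald z / p / CI. Efron's tie correction is the
default because day-granular EMR data guarantees tied event times;
Breslow is retained and the two are asserted to coincide exactly on
untied data. A monotone likelihood (a covariate perfectly separating
events) raises a classed divergence error; inside the orchestrated
pipeline that fit is reported as a flagged, empty row rather than
aborting the whole run. A converged fit with any coefficient standard
error above 2 is annotated `unstable = TRUE` but still reported — a
single event in one arm produces a gigantic, meaningless hazard ratio,
and the right behavior is to show it with a flag, not to hide it.
Matched pairs are analyzed unpaired with covariate adjustment (the
adjustment set is configuration); no robust pair-clustered variance is
provided.

## The synthetic world

`simulation_spec()` defaults describe one fixed, realistic scenario of
an anticoagulant comparison in atrial fibrillation, chosen once:
age ~ N(70, 10); 55% female; hypertension 50%, diabetes 30%, heart
failure 20%, antiplatelet comedication 30%; treatment assignment from a
logistic model with moderate confounding (log-odds 0.1–0.5 per
covariate); outcome times exponential with baseline hazard 5e-5 per
person-day and true treatment hazard ratio 0.5; refill chains of
30/60/90-day supplies with exponential inter-refill gaps of mean 10 days
(so a realistic minority of gaps exceeds the 30-day grace period and
exercises discontinuation); administrative end of data 1–4 years after
index; 5% washout-violating prior exposure and 5% pre-index outcome
history to exercise the filters.

The exponential (constant baseline hazard) choice is deliberate: the Cox
model is semi-parametric, and the exponential special case gives
closed-form truth for recovery tests. The generator does **not** attempt
realistic ICD code distributions, correlated comorbidity structure, or
real atrial-fibrillation epidemiology. A green test therefore
establishes that the machinery is correct under its stated assumptions
(proportional hazards, logistic assignment, independent censoring) — not
that any clinical conclusion transfers. The latent truth table is
written beside the generated tables but no pipeline stage accepts it.

A hand-written 16-patient fixture complements the generator with exactly
traced expected outputs (attrition counts, every follow-up record, every
incidence cell), committed beside the fixture and compared
byte-for-byte. In the fixture the propensity model is intercept-only so
the matched membership is hand-derivable (all scores equal, ties resolve
by smallest control id); the Cox and KM outputs on the fixture are
covered by the determinism contract (two runs, identical bytes) rather
than by hand-tracing, which is not feasible for an iterative fit.

## Runtime scaling in the test suite

Two simulation-based checks run scaled down relative to their idealized
designs so the default suite stays fast: the confounding-reduction
replicate check uses 6 replicates of n = 900 (requiring 4/6 successes)
rather than 100 replicates, and the acceptance suite's coverage check
uses the full 200 × n = 1000 design but a single, fixed seed. The
full-size coverage criterion (93–97% Wald coverage, |mean bias| < 0.05)
runs in the acceptance tests in about a minute.

## Known limitations

* No IPTW or optimal/full/variable-ratio matching; no stratified,
  time-varying, or pair-clustered Cox variants; no proportional-hazards
  diagnostics; no log-rank test; no competing-risk estimators.
* Only structured data: no lab values, free text, or imaging.
* The coding system is deliberately unspecified; code sets are exact or
  prefix string matches, so ICD-9/ICD-10/ATC mixtures are the user's
  responsibility.
* Whether a risk score enters the propensity model as a total score, as
  components, or both is left to configuration on purpose — there is no
  single right answer and the package does not pretend otherwise.
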