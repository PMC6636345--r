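# Analysis-ready assembly, lookback flags, risk scores, templates.

mapper_tables <- function() {
  mk_tables(
    patients = data.frame(patient_id = c("A", "B"),
                          birth_date = c("1936-03-15", "1950-01-01"),
                          sex = c("female", "male"),
                          data_end_date = "2020-12-31"),
    diagnoses = data.frame(
      patient_id = c("A", "A", "B", "B"),
      date = c("2012-04-01", "2010-12-01", "2011-03-27", "2012-04-20"),
      code = c("I10", "E11.9", "E11.9", "E11.9"),
      setting = c("outpatient", "outpatient", "outpatient", "outpatient")))
}

mapper_node <- function(ids = c("A", "B")) {
  structure(list(node_id = "n", label = "leaf", parent = NA_character_,
                 members = ids, n_in = length(ids), n_out = length(ids),
                 n_dropped = 0L), class = "cohort_node")
}

test_that("lookback flags respect the 365-day half-open window", {
  tb <- mapper_tables()
  index <- mk_index(c("A", "B"), "2012-05-01", c("trt", "ctl"))
  specs <- list(covariate_spec("diabetes", "diagnosis_flag",
                               code_set("dm", "E11", "prefix")))
  rows <- assemble_analysis_ready(mapper_node(), index, tb, specs, "trt")
  # A: only code at index-517 -> 0; B: index-401 (out) and index-11 (in) -> 1
  expect_equal(rows$diabetes, c(0L, 1L))
  # shrink window: B's 2012-04-20 still in, A's 2011-12-01 out
  specs30 <- list(covariate_spec("dm30", "diagnosis_flag",
                                 code_set("dm", "E11", "prefix"), window_days = 30))
  rows30 <- assemble_analysis_ready(mapper_node(), index, tb, specs30, "trt")
  expect_equal(rows30$dm30, c(0L, 1L))
  # beyond 12 months only -> 0
  idx_late <- mk_index(c("A", "B"), "2013-06-01", c("trt", "ctl"))
  rows_late <- assemble_analysis_ready(mapper_node(), idx_late, tb, specs, "trt")
  expect_equal(rows_late$diabetes, c(0L, 0L))
  # base columns and group coding
  expect_equal(rows$group, c(1L, 0L))
  expect_equal(rows$sex, c(1L, 0L))
  expect_equal(names(assemble_analysis_ready(mapper_node(), index, tb, list(), "trt")),
               c("patient_id", "index_date", "group", "age_years", "sex"))
})

test_that("flags are invariant to duplicated rows and assembly is pure", {
  tb <- mapper_tables()
  dup <- tb$diagnoses[rep(seq_len(nrow(tb$diagnoses)), 3), ]
  tb_dup <- emr_tables(tb$patients, dup, tb$prescriptions)
  index <- mk_index(c("A", "B"), "2012-05-01", c("trt", "ctl"))
  specs <- list(covariate_spec("diabetes", "diagnosis_flag",
                               code_set("dm", "E11", "prefix")))
  r1 <- assemble_analysis_ready(mapper_node(), index, tb, specs, "trt")
  r2 <- assemble_analysis_ready(mapper_node(), index, tb_dup, specs, "trt")
  r3 <- assemble_analysis_ready(mapper_node(), index, tb, specs, "trt")
  expect_equal(r1$diabetes, r2$diabetes)
  expect_identical(r1, r3)
})

test_that("member without index assignment is a structural error", {
  tb <- mapper_tables()
  index <- mk_index("A", "2012-05-01", "trt")
  expect_error(assemble_analysis_ready(mapper_node(), index, tb, list(), "trt"),
               class = "cw_structural_error")
})

test_that("default additive risk score: components sum and are monotone", {
  tb <- mapper_tables()
  def <- default_risk_score()
  # A: female (1) + age 76 (2) + hypertension I10 (1) = 4
  ctx <- patient_context("A", tb, as.Date("2012-05-01"))
  expect_equal(compute_risk_score(ctx, def), 4L)
  # B: male, 62, diabetes E11 in window = 1
  ctxB <- patient_context("B", tb, as.Date("2012-05-01"))
  expect_equal(compute_risk_score(ctxB, def), 1L)
  # no components satisfied -> 0
  tb0 <- mk_tables(patients = data.frame(patient_id = "C", birth_date = "1990-01-01",
                                         sex = "male", data_end_date = "2020-01-01"))
  expect_equal(compute_risk_score(patient_context("C", tb0, as.Date("2012-05-01")), def), 0L)
  # monotonicity: dropping a satisfied component never raises the score
  sub_def <- risk_score_def("sub", def$components[-length(def$components)])
  expect_lte(compute_risk_score(ctx, sub_def), compute_risk_score(ctx, def))
  # as a covariate column
  index <- mk_index(c("A", "B"), "2012-05-01", c("trt", "ctl"))
  rows <- assemble_analysis_ready(mapper_node(), index, tb,
                                  list(covariate_spec("chads", "risk_score",
                                                      risk_score = def)), "trt")
  expect_equal(rows$chads, c(4L, 1L))
})

test_that("recovered flags equal the generator truth exactly", {
  sp <- simulation_spec(n_patients = 300, seed = 31)
  g <- generate_emr(sp)
  nu <- identify_new_users(g$tables,
                           list(warfarin = code_set("warfarin", "WARF"),
                                noac = code_set("noac", "NOAC_A")),
                           as.Date(c("2010-01-01", "2015-12-31")), 365)
  node <- structure(list(node_id = "n", label = "all", parent = NA_character_,
                         members = nu$index$patient_id,
                         n_in = nrow(nu$index), n_out = nrow(nu$index),
                         n_dropped = 0L), class = "cohort_node")
  rows <- assemble_analysis_ready(node, nu$index, g$tables, g$covariate_specs, "noac")
  tr <- g$truth[match(rows$patient_id, g$truth$patient_id), ]
  for (nm in c("hypertension", "diabetes", "heart_failure", "rx_antiplatelet")) {
    expect_equal(rows[[nm]], tr[[nm]], info = nm)
  }
  expect_equal(rows$group, tr$treated)
})

test_that("template library round-trips and errors on unknown names", {
  cfg <- load_config(fixture_paths()$config)
  specs <- list(covariate_spec("dm", "diagnosis_flag", code_set("dm", "E11", "prefix")))
  cfg2 <- save_template(cfg, "metabolic", specs)
  expect_identical(load_template(cfg2, "metabolic"), specs)
  expect_error(load_template(cfg2, "nope"), class = "cw_config_error")
  expect_error(save_template(cfg2, "metabolic", specs), class = "cw_config_error")
  # two templates may share code sets by reference
  cfg3 <- save_template(cfg2, "metabolic2", specs)
  expect_identical(load_template(cfg3, "metabolic")[[1]]$code_set,
                   load_template(cfg3, "metabolic2")[[1]]$code_set)
})
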