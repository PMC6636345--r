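# New-user identification, criteria, incident subcohorts, attrition tree.

two_arm_sets <- list(a = code_set("a", "DRUG_A"), b = code_set("b", "DRUG_B"))
win <- as.Date(c("2010-01-01", "2015-12-31"))

test_that("new-user washout, inclusion, and dual-exposure rules", {
  tb <- mk_tables(
    patients = data.frame(patient_id = c("PRIOR", "NEW", "DUAL"),
                          birth_date = "1950-01-01", sex = "male",
                          data_end_date = "2020-12-31"),
    prescriptions = data.frame(
      patient_id = c("PRIOR", "PRIOR", "NEW", "DUAL", "DUAL"),
      drug_code = c("DRUG_A", "DRUG_A", "DRUG_A", "DRUG_A", "DRUG_B"),
      start_date = c("2009-06-01", "2010-03-01", "2012-05-01",
                     "2012-07-01", "2012-07-01"),
      days_supplied = 30L))
  nu <- identify_new_users(tb, two_arm_sets, win, washout_days = 365)
  expect_equal(nu$index$patient_id, "NEW")
  expect_equal(nu$index$index_date, as.Date("2012-05-01"))
  expect_equal(nu$index$index_group, "a")
  att <- attrition_report(nu$nodes)
  expect_equal(att$n_out, c(3L, 3L, 2L, 1L))
  # with washout = Inf the all-history rule gives the same exclusion here
  nu2 <- identify_new_users(tb, two_arm_sets, win, washout_days = Inf)
  expect_equal(nu2$index$patient_id, "NEW")
})

test_that("age boundary is inclusive and windows are half-open", {
  tb <- mk_tables(
    patients = data.frame(patient_id = c("X20", "X19"),
                          birth_date = c("1992-05-01", "1992-05-02"),
                          sex = "female", data_end_date = "2020-12-31"),
    diagnoses = data.frame(patient_id = c("X20", "X19"),
                           date = "2012-05-01", code = "C50.1",
                           setting = "inpatient"))
  index <- mk_index(c("X20", "X19"), "2012-05-01")
  root <- structure(list(node_id = "r", label = "root", parent = NA_character_,
                         members = c("X19", "X20"), n_in = 2L, n_out = 2L,
                         n_dropped = 0L), class = "cohort_node")
  aged <- apply_criterion(root, criterion("age20", "age_at_least", min_age = 20),
                          tb, index)
  expect_equal(aged$members, "X20")  # exactly 20 retained, 19 dropped

  # cancer ON the index date is outside [-365, 0): both retained
  canc <- apply_criterion(root,
                          criterion("cancer", "exclude_diagnosis",
                                    code_set("cancer", "C", "prefix"),
                                    window = c(-365, 0)),
                          tb, index)
  expect_equal(canc$members, c("X19", "X20"))

  # require on an empty node is vacuous
  empty <- structure(list(node_id = "e", label = "empty", parent = NA_character_,
                          members = character(), n_in = 0L, n_out = 0L,
                          n_dropped = 0L), class = "cohort_node")
  ch <- apply_criterion(empty,
                        criterion("c", "require_diagnosis",
                                  code_set("cancer", "C", "prefix")),
                        tb, index)
  expect_equal(ch$n_in, 0L)
  expect_equal(ch$n_out, 0L)
})

test_that("incident subcohorts exclude on the pre-index window only", {
  tb <- mk_tables(
    patients = data.frame(patient_id = c("PRE", "ON", "NONE"),
                          birth_date = "1950-01-01", sex = "male",
                          data_end_date = "2020-12-31"),
    diagnoses = data.frame(patient_id = c("PRE", "ON"),
                           date = c("2012-01-22", "2012-05-01"),
                           code = c("G45.9", "I63.0"),
                           setting = "inpatient"))
  index <- mk_index(c("PRE", "ON", "NONE"), "2012-05-01")
  root <- structure(list(node_id = "r", label = "root", parent = NA_character_,
                         members = c("NONE", "ON", "PRE"), n_in = 3L, n_out = 3L,
                         n_dropped = 0L), class = "cohort_node")
  sub <- build_incident_subcohort(root, code_set("stroke_tia", c("I63", "G45"), "prefix"),
                                  365, tb, index)
  # TIA 100 days pre-index drops PRE; a stroke code ON the index date is
  # not "before the index date" and is follow-up's business
  expect_equal(sub$members, c("NONE", "ON"))
  # nobody with pre-index outcomes -> subcohort equals parent
  sub2 <- build_incident_subcohort(root, code_set("ich", "I61", "prefix"),
                                   365, tb, index)
  expect_equal(sub2$members, root$members)
})

test_that("attrition report telescopes and guards structure", {
  fx <- worked_fixture()
  cfg <- load_config(fx$config_path)
  nu <- identify_new_users(fx$tables, cfg$exposure_sets, cfg$study_window,
                           cfg$washout_days)
  tree <- nu$nodes
  node <- tree[[length(tree)]]
  for (cr in cfg$criteria) {
    node <- apply_criterion(node, cr, fx$tables, nu$index)
    tree <- c(tree, list(node))
  }
  att <- attrition_report(tree)
  expect_equal(att$n_out, att$n_in - att$n_dropped)
  expect_equal(att$n_in[-1], att$n_out[-nrow(att)])      # chain telescopes
  expect_equal(sum(att$n_dropped), att$n_in[1] - att$n_out[nrow(att)])
  # monotone membership down the chain
  for (i in seq_along(tree)[-1]) {
    expect_true(all(tree[[i]]$members %in% tree[[i - 1]]$members))
  }
  # every member appears in the patients table
  expect_true(all(unlist(lapply(tree, `[[`, "members")) %in%
                    fx$tables$patients$patient_id))
  # single node tree
  expect_equal(attrition_report(tree[1])$n_dropped, 0L)
  # broken parent pointer
  orphan <- tree[[2]]; orphan$parent <- "deadbeef"
  expect_error(attrition_report(list(tree[[1]], orphan)),
               class = "cw_structural_error")
})

test_that("exclusion criteria commute on leaf membership", {
  fx <- worked_fixture()
  cfg <- load_config(fx$config_path)
  nu <- identify_new_users(fx$tables, cfg$exposure_sets, cfg$study_window,
                           cfg$washout_days)
  base <- nu$nodes[[length(nu$nodes)]]
  c1 <- criterion("no cancer", "exclude_diagnosis",
                  code_set("cancer", "C", "prefix"), window = c(-365, 0))
  c2 <- criterion("no prior stroke", "exclude_diagnosis",
                  code_set("stroke", c("I63", "G45"), "prefix"), window = c(-365, 0))
  ab <- apply_criterion(apply_criterion(base, c1, fx$tables, nu$index),
                        c2, fx$tables, nu$index)
  ba <- apply_criterion(apply_criterion(base, c2, fx$tables, nu$index),
                        c1, fx$tables, nu$index)
  expect_equal(ab$members, ba$members)
})
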