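test_that("at zero noise the pipeline reproduces the intended truth exactly", {
  spec <- population_spec(n = 500, seed = 81, response_noise = 0,
                          contamination_prob = 0, missing_prob = 0)
  sim <- simulate_respondents(spec)
  scores <- score_respondents(sim$respondents)
  # realized converted scores equal the lattice targets exactly
  for (k in constitutions()) {
    expect_identical(scores[[k]], sim$truth[[paste0("target_", k)]])
  }
  cls <- classify_constitutions(scores)
  expect_identical(as.character(cls$group),
                   as.character(sim$truth$intended_group))
  expect_identical(cls$primary, sim$truth$intended_primary)
})

test_that("identical spec and seed give byte-identical cohorts", {
  spec <- population_spec(n = 200, seed = 82)
  a <- simulate_respondents(spec)
  b <- simulate_respondents(spec)
  expect_identical(a$respondents, b$respondents)
  expect_identical(a$truth, b$truth)
  c <- simulate_respondents(population_spec(n = 200, seed = 83))
  expect_false(identical(a$respondents, c$respondents))
})

test_that("degenerate mixtures produce the promised cohorts", {
  # everyone balanced
  all_bal <- population_spec(
    n = 100, seed = 84, response_noise = 0, contamination_prob = 0,
    missing_prob = 0, no_classification_prob = 0,
    class_mix = c(balanced = 1,
                  setNames(rep(0, 8), constitutions(unbalanced_only = TRUE)),
                  tendency_only = 0)
  )
  cohort <- qc_cascade(simulate_respondents(all_bal)$respondents)$cohort
  expect_equal(nrow(cohort), 100)
  expect_true(all(cohort$group == "balanced"))
  # pure contamination: everyone excluded for middle responses
  cont <- simulate_respondents(population_spec(n = 50, seed = 85,
                                               contamination_prob = 1))
  qc <- qc_cascade(cont$respondents)
  expect_true(all(qc$ledger$disposition == "excluded_middle_response"))
  # pure missingness
  miss <- simulate_respondents(population_spec(n = 50, seed = 86,
                                               missing_prob = 1))
  qc <- qc_cascade(miss$respondents)
  expect_true(all(qc$ledger$disposition == "excluded_missing"))
})

test_that("contaminated respondents spuriously accumulate unbalanced constitutions", {
  cont <- simulate_respondents(population_spec(n = 40, seed = 87,
                                               contamination_prob = 1))
  scores <- score_respondents(cont$respondents)
  cls <- classify_constitutions(scores)
  # mostly-3 responders sit near 50 on every scale: many constitutions fire
  expect_gte(median(cls$n_constitutions), 6)
})

test_that("unattainable target bands are rejected", {
  expect_error(ccmq:::.lattice_raws(5, 98, 99), "no attainable score")
  expect_error(population_spec(n = 0), "n must be")
  expect_error(population_spec(class_mix = c(balanced = 1)), "class_mix")
  expect_error(population_spec(response_noise = 1.5), "probabilities")
})

test_that("misclassification under noise concentrates near the thresholds", {
  spec <- population_spec(n = 3000, seed = 88, response_noise = 0.25,
                          contamination_prob = 0, missing_prob = 0)
  sim <- simulate_respondents(spec)
  cls <- classify_constitutions(score_respondents(sim$respondents))
  ok <- as.character(cls$group) == as.character(sim$truth$intended_group) &
    (is.na(cls$primary) == is.na(sim$truth$intended_primary)) &
    (is.na(cls$primary) | cls$primary == sim$truth$intended_primary)
  # distance from each respondent's targets to the nearest decision threshold
  unbal <- constitutions(unbalanced_only = TRUE)
  tu <- as.matrix(sim$truth[paste0("target_", unbal)])
  d_unbal <- apply(pmin(abs(tu - 30), abs(tu - 40)), 1, min)
  d_bal <- abs(sim$truth$target_balanced - 60)
  dist <- pmin(d_unbal, d_bal)
  expect_gt(mean(!ok), 0.01)  # the noise level genuinely perturbs
  expect_lt(mean(dist[!ok]), mean(dist[ok]))
})

test_that("a stronger co-occurrence boost raises the coexistence entry", {
  lo <- population_spec(n = 5000, seed = 89,
                        cooccurrence_boosts = c("qi_stagnation:qi_deficiency" = 0))
  hi <- population_spec(n = 5000, seed = 89,
                        cooccurrence_boosts = c("qi_stagnation:qi_deficiency" = 2.5))
  entry <- function(spec) {
    cohort <- qc_cascade(simulate_respondents(spec)$respondents)$cohort
    m <- coexistence_to_matrix(coexistence_matrix(cohort))
    m["qi_stagnation", "qi_deficiency"]
  }
  expect_gt(entry(hi), entry(lo))
})

test_that("covariate effects push constitution propensities in the set direction", {
  sim <- simulate_respondents(population_spec(n = 12000, seed = 90))
  cohort <- qc_cascade(sim$respondents)$cohort
  prev <- prevalence_table(cohort, by = "bmi_group")
  pd <- prev[prev$classification == "phlegm_dampness", ]
  expect_gt(pd$prevalence[pd$subgroup == "obese"],
            pd$prevalence[pd$subgroup == "normal"])
  yang <- prev[prev$classification == "yang_deficiency", ]
  expect_lt(yang$prevalence[yang$subgroup == "obese"],
            yang$prevalence[yang$subgroup == "normal"])
})

test_that("the fixture suite writes its manifest and fixtures behave as declared", {
  dir <- withr::local_tempdir()
  manifest <- make_fixture_suite(dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  boundary <- readr::read_csv(file.path(dir, "boundary_scores.csv"),
                              show_col_types = FALSE)
  cls <- classify_constitutions(boundary)
  got <- setNames(as.character(cls$group), cls$participant_id)
  expect_equal(got[["boundary_tendency"]], "tendency_only")
  expect_equal(got[["boundary_constitution"]], "unbalanced_constitution")
  expect_equal(got[["boundary_balanced"]], "balanced")
  expect_equal(got[["boundary_none"]], "no_classification")
  ties <- classify_constitutions(
    readr::read_csv(file.path(dir, "tie_scores.csv"), show_col_types = FALSE)
  )
  expect_true(all(ties$tie))
  cont <- read_respondents(file.path(dir, "contamination_respondents.csv"))
  expect_true(all(qc_cascade(cont)$ledger$disposition ==
                    "excluded_middle_response"))
  pr_cohort <- readr::read_csv(file.path(dir, "pr_cohort.csv"),
                               show_col_types = FALSE)
  fit <- fit_prevalence_ratio(
    dplyr::mutate(pr_cohort, exposure = factor(exposure,
                                               levels = c("unexposed", "exposed"))),
    "y", "exposure", adjust = c("age_decade_c", "sex")
  )
  expect_equal(tidy(fit)$pr[2], 1.5, tolerance = 0.35)
})
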