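test_that("composite percentages use the within-primary denominator", {
  # 10 primary-qi_deficiency, 4 composite -> 40% within primary, regardless
  # of the cohort-level denominator (50 respondents in total)
  cohort <- make_classified_cohort(
    n_balanced = 30, n_tendency_only = 10,
    primaries = list(qi_deficiency = c(10, 4, 0))
  )
  cs <- composite_summary(cohort)
  row <- cs[cs$primary == "qi_deficiency", ]
  expect_equal(row$pct_with_composite, 40)
  expect_equal(row$prevalence, 100 * 10 / 50)
  # the two denominators genuinely differ here
  expect_false(isTRUE(all.equal(row$pct_with_composite, row$prevalence)))
  # totals row equals column sums
  expect_equal(cs$n_primary[cs$primary == "all_unbalanced"],
               sum(cs$n_primary[cs$primary != "all_unbalanced"]))
})

test_that("a cohort of single-constitution respondents has zero composite", {
  cohort <- make_classified_cohort(
    n_balanced = 5, n_tendency_only = 5,
    primaries = list(qi_deficiency = c(8, 0, 0), damp_heat = c(2, 0, 0))
  )
  cs <- composite_summary(cohort)
  expect_true(all(cs$pct_with_composite == 0))
})

test_that("an empty unbalanced group yields an all-zero table with a warning", {
  cohort <- make_classified_cohort(n_balanced = 5, n_tendency_only = 2,
                                   primaries = list())
  expect_warning(cs <- composite_summary(cohort), "all-zero")
  expect_true(all(cs$n_primary == 0))
})

test_that("coexistence entries are within-primary percentages, asymmetric", {
  # 4 primary qi_stagnation, all also qi_deficiency; 10 primary
  # qi_deficiency, 2 also qi_stagnation
  qs <- dplyr::bind_rows(purrr::map(1:4, function(i) {
    r <- classify_constitutions(
      make_scores(paste0("qs", i), qi_stagnation = 60, qi_deficiency = 45)
    )
    r
  }))
  qd_both <- dplyr::bind_rows(purrr::map(1:2, function(i) {
    classify_constitutions(
      make_scores(paste0("qdb", i), qi_deficiency = 60, qi_stagnation = 45)
    )
  }))
  qd_only <- dplyr::bind_rows(purrr::map(1:8, function(i) {
    classify_constitutions(make_scores(paste0("qdo", i), qi_deficiency = 60))
  }))
  cohort <- dplyr::bind_rows(qs, qd_both, qd_only)
  cx <- coexistence_matrix(cohort)
  m <- coexistence_to_matrix(cx)
  expect_equal(m["qi_stagnation", "qi_deficiency"], 100)
  expect_equal(m["qi_deficiency", "qi_stagnation"], 20)
  expect_true(all(is.na(diag(m))))
  # rows with no primaries are missing, not zero
  expect_true(all(is.na(m["damp_heat", setdiff(colnames(m), "damp_heat")])))
  # consistency: composite count for primary A matches the union behind row A
  cs <- composite_summary(cohort)
  expect_equal(cs$n_with_composite[cs$primary == "qi_stagnation"], 4)
  expect_equal(cs$n_with_composite[cs$primary == "qi_deficiency"], 2)
  expect_equal(sum(cx$n_both[cx$primary == "qi_stagnation"]), 4)
})

test_that("chord export emits one edge per coexisting pair with the max flagged", {
  cohort <- dplyr::bind_rows(
    purrr::map(1:10, ~ classify_constitutions(
      make_scores(paste0("a", .x),
                  qi_stagnation = 60,
                  qi_deficiency = if (.x <= 7) 45 else 10)
    )),
    purrr::map(1:10, ~ classify_constitutions(
      make_scores(paste0("b", .x),
                  qi_deficiency = 60,
                  qi_stagnation = if (.x <= 3) 45 else 10)
    ))
  )
  cx <- coexistence_matrix(cohort)
  p <- withr::local_tempfile(fileext = ".csv")
  edges <- export_chord(cx, p)
  expect_equal(nrow(edges), 1)
  expect_setequal(c(edges$source, edges$target),
                  c("qi_deficiency", "qi_stagnation"))
  expect_equal(edges$max_pct, 70)
  expect_equal(sort(c(edges$pct_source_to_target, edges$pct_target_to_source)),
               c(30, 70))
  expect_equal(nrow(readr::read_csv(p, show_col_types = FALSE)), 1)
  # no coexistence at all -> empty edge list
  lone <- classify_constitutions(make_scores("solo", damp_heat = 60))
  expect_equal(nrow(export_chord(coexistence_matrix(lone))), 0)
})

test_that("stratified coexistence compares composite proportions across strata", {
  half <- dplyr::bind_rows(
    purrr::map(1:30, ~ classify_constitutions(
      make_scores(paste0("y", .x), qi_deficiency = 60,
                  yang_deficiency = if (.x <= 20) 45 else 10)
    ))
  )
  young <- dplyr::mutate(half, age_group_young = "18-39")
  old <- dplyr::mutate(half, age_group_young = "40+",
                       participant_id = paste0("o", participant_id))
  cohort <- dplyr::bind_rows(young, old)
  st <- stratified_coexistence(cohort, "age_group_young")
  expect_equal(st$matrices[["18-39"]]$pct, st$matrices[["40+"]]$pct)
  expect_equal(st$composite_test$p_value, 1, tolerance = 1e-12)
  expect_equal(st$composite_by_stratum$pct_composite,
               c(100 * 20 / 30, 100 * 20 / 30))
})

test_that("a generator with stronger youth co-occurrence shows it in the young stratum", {
  sim <- simulate_respondents(population_spec(n = 6000, seed = 41,
                                              young_composite_logit = 1.5))
  cohort <- qc_cascade(sim$respondents)$cohort
  st <- stratified_coexistence(cohort, "age_group_young")
  expect_lt(st$composite_test$p_value, 0.05)
  expect_gt(st$composite_by_stratum$pct_composite[1],
            st$composite_by_stratum$pct_composite[2])
})
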