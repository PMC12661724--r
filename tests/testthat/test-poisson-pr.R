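test_that("the unadjusted PR equals the ratio of proportions to machine precision", {
  cohort <- tibble::tibble(
    y = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 15, 85)),
    exposure = factor(rep(c("exposed", "unexposed"), each = 100),
                      levels = c("unexposed", "exposed"))
  )
  pr <- fit_prevalence_ratio(cohort, "y", "exposure", adjust = character())
  td <- tidy(pr)
  expect_equal(td$pr[td$level == "exposed"], 2, tolerance = 1e-10)
  expect_identical(td$pr[td$level == "unexposed"], 1)
  expect_true(is.na(td$ci_low[td$level == "unexposed"]))
  expect_true(td$ci_low[td$level == "exposed"] < 2 &&
                td$ci_high[td$level == "exposed"] > 2)
})

test_that("identical outcome distributions give PR 1 with a covering CI", {
  set.seed(71)
  cohort <- tibble::tibble(
    y = rbinom(2000, 1, 0.2) == 1,
    exposure = factor(rep(c("a", "b"), 1000))
  )
  td <- tidy(fit_prevalence_ratio(cohort, "y", "exposure", adjust = character()))
  row <- td[td$level == "b", ]
  expect_equal(row$pr, 1, tolerance = 0.2)
  expect_true(row$ci_low < 1 && row$ci_high > 1)
})

test_that("separation and missing columns raise explicit errors", {
  cohort <- tibble::tibble(
    y = rep(c(TRUE, FALSE), c(100, 100)),
    exposure = factor(rep(c("all_events", "no_events"), each = 100))
  )
  expect_error(fit_prevalence_ratio(cohort, "y", "exposure", adjust = character()),
               "separation.*all_events")
  expect_error(fit_prevalence_ratio(cohort, "y", "nope", adjust = character()),
               "exposure column")
  expect_error(fit_prevalence_ratio(cohort, "y", "exposure", adjust = "age"),
               "adjustment")
})

test_that("the adjusted model recovers a built-in confounded PR", {
  cohort <- simulate_pr_cohort(30000, pr = 1.5, seed = 72)
  adj <- fit_prevalence_ratio(cohort, "y", "exposure",
                              adjust = c("age_decade_c", "sex"))
  crude <- fit_prevalence_ratio(cohort, "y", "exposure", adjust = character())
  pr_adj <- tidy(adj)$pr[2]
  pr_crude <- tidy(crude)$pr[2]
  expect_equal(pr_adj, 1.5, tolerance = 0.08)
  # confounding biases the crude ratio away from the truth
  expect_gt(abs(log(pr_crude / 1.5)), abs(log(pr_adj / 1.5)))
  g <- glance(adj)
  expect_equal(g$n, 30000)
  expect_true(g$converged)
})

test_that("marginal standardization reproduces stratified crude prevalences
           when there is nothing to adjust for", {
  cohort <- tibble::tibble(
    y = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 15, 85)),
    exposure = factor(rep(c("exposed", "unexposed"), each = 100),
                      levels = c("unexposed", "exposed"))
  )
  pr <- fit_prevalence_ratio(cohort, "y", "exposure", adjust = character())
  ms <- marginal_standardization(pr)
  expect_equal(ms$adjusted_prevalence[ms$level == "unexposed"], 15,
               tolerance = 1e-8)
  expect_equal(ms$adjusted_prevalence[ms$level == "exposed"], 30,
               tolerance = 1e-8)
  expect_equal(ms$n_capped, c(0L, 0L))
})

test_that("adjusted prevalences move toward the truth under confounding", {
  set.seed(73)
  n <- 20000
  age_c <- rnorm(n)
  exposed <- runif(n) < stats::plogis(-1 + 1.2 * age_c)
  p <- pmin(0.1 * 1.5^exposed * exp(0.5 * age_c), 0.95)
  cohort <- tibble::tibble(
    y = runif(n) < p,
    exposure = factor(ifelse(exposed, "exposed", "unexposed"),
                      levels = c("unexposed", "exposed")),
    age_c = age_c
  )
  fit <- fit_prevalence_ratio(cohort, "y", "exposure", adjust = "age_c")
  ms <- suppressWarnings(marginal_standardization(fit))
  # truth: average over the cohort of p with exposure forced to each level
  truth_unexp <- 100 * mean(pmin(0.1 * exp(0.5 * age_c), 0.95))
  truth_exp <- 100 * mean(pmin(0.1 * 1.5 * exp(0.5 * age_c), 0.95))
  crude <- 100 * tapply(cohort$y, cohort$exposure, mean)
  adj <- setNames(ms$adjusted_prevalence, ms$level)
  expect_lt(abs(adj[["exposed"]] - truth_exp),
            abs(crude[["exposed"]] - truth_exp))
  expect_lt(abs(adj[["unexposed"]] - truth_unexp),
            abs(crude[["unexposed"]] - truth_unexp))
})

test_that("out-of-range log-link predictions are truncated with a count", {
  set.seed(74)
  n <- 2000
  x <- rnorm(n)
  p <- pmin(0.7 * exp(0.4 * x), 0.99)
  cohort <- tibble::tibble(
    y = runif(n) < p,
    exposure = factor(sample(c("a", "b"), n, replace = TRUE)),
    x = x
  )
  fit <- fit_prevalence_ratio(cohort, "y", "exposure", adjust = "x")
  w <- testthat::capture_warnings(ms <- marginal_standardization(fit))
  expect_true(any(grepl("truncated", w)))
  expect_gt(sum(ms$n_capped), 0)
  expect_true(all(ms$adjusted_prevalence <= 100))
})
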