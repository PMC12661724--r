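# Prevalence estimation and hypothesis tests. Prevalence of a
# classification = its count divided by the full analytic sample (or the
# subgroup size when stratified); tendency-only and unclassified-outcome
# respondents stay in denominators. Nine constitution-wise tests are run
# at the Bonferroni-corrected alpha of 0.05/9.

#' Bonferroni-corrected significance level
#'
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of constitution-wise tests (default 9).
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 9) alpha / m

.outcome_indicator <- function(cohort, outcome) {
  # constitution keys take precedence over same-named score columns; a key
  # means "primary constitution is <key>", so tendency-only respondents
  # (whose primary is a tendency label) never count
  if (outcome %in% constitutions() && "group" %in% names(cohort)) {
    if (outcome == "balanced") return(cohort$group == "balanced")
    return(cohort$group == "unbalanced_constitution" &
             !is.na(cohort$primary) & cohort$primary == outcome)
  }
  if (outcome %in% names(cohort)) {
    v <- cohort[[outcome]]
    if (is.logical(v)) return(v)
    if (is.numeric(v) && all(v %in% c(0, 1), na.rm = TRUE)) return(v == 1)
    abort(paste0("outcome column '", outcome, "' must be logical or 0/1"))
  }
  if (outcome %in% constitutions()) {
    if (outcome == "balanced") return(cohort$group == "balanced")
    return(!is.na(cohort$primary) & cohort$primary == outcome)
  }
  abort(paste0("unknown outcome: ", outcome,
               " (not a column or constitution key)"))
}

#' Prevalence table of primary classifications
#'
#' Prevalence of each primary classification — the balanced constitution,
#' the eight unbalanced constitutions (by primary), the tendency-only
#' group, and the single/composite split of the unbalanced group — overall
#' or within each level of a grouping covariate. Denominators are the full
#' analytic sample (or subgroup size), never restricted to classified
#' respondents. Wilson 95\% confidence intervals accompany each estimate.
#'
#' @param cohort Classified analytic cohort.
#' @param by Optional name of a covariate column to stratify on.
#' @return Tibble with `classification`, `subgroup`, `numerator`,
#'   `denominator`, `prevalence` (in %), `ci_low`, `ci_high`.
#' @export
prevalence_table <- function(cohort, by = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort")
  tend_keys <- paste0("tendency_", constitutions(unbalanced_only = TRUE))
  defs <- c(
    setNames(as.list(constitutions()), constitutions()),
    setNames(as.list(tend_keys), tend_keys),
    list(
      tendency_only = "tendency_only",
      any_constitution = "any_constitution",
      unbalanced_constitution = "unbalanced_constitution",
      single_unbalanced = "single_unbalanced",
      composite_unbalanced = "composite_unbalanced"
    )
  )
  indicator <- function(data, what) {
    if (startsWith(what, "tendency_") && what != "tendency_only") {
      key <- sub("^tendency_", "", what)
      return(data$group == "tendency_only" &
               !is.na(data$primary) & data$primary == key)
    }
    switch(what,
      tendency_only = data$group == "tendency_only",
      any_constitution = data$group %in% c("balanced", "unbalanced_constitution"),
      unbalanced_constitution = data$group == "unbalanced_constitution",
      single_unbalanced = data$group == "unbalanced_constitution" & !data$composite,
      composite_unbalanced = data$group == "unbalanced_constitution" & data$composite,
      .outcome_indicator(data, what)
    )
  }
  strata <- if (is.null(by)) {
    list(overall = cohort)
  } else {
    if (!by %in% names(cohort)) abort(paste0("covariate not found: ", by))
    lv <- levels(factor(cohort[[by]]))
    setNames(
      purrr::map(lv, ~ cohort[!is.na(cohort[[by]]) & cohort[[by]] == .x, ,
                              drop = FALSE]),
      lv
    )
  }
  purrr::imap_dfr(strata, function(data, label) {
    purrr::imap_dfr(defs, function(what, name) {
      num <- sum(indicator(data, what))
      den <- nrow(data)
      ci <- if (den > 0) {
        stats::prop.test(num, den, correct = FALSE)$conf.int
      } else {
        c(NA_real_, NA_real_)
      }
      tibble(
        classification = name, subgroup = label,
        numerator = num, denominator = den,
        prevalence = 100 * num / den,
        ci_low = 100 * ci[1], ci_high = 100 * ci[2]
      )
    })
  })
}

.test_result <- function(name, statistic, df, p, alpha, m) {
  a <- bonferroni_alpha(alpha, m)
  tibble(
    test = name, statistic = unname(statistic), df = unname(df),
    p_value = unname(p), alpha_corrected = a, significant = p < a
  )
}

#' Chi-squared test of independence
#'
#' Pearson chi-squared (no continuity correction) on the outcome-by-factor
#' contingency table, with the significance flag applied at the
#' Bonferroni-corrected level `alpha / m`.
#'
#' @param cohort Classified analytic cohort.
#' @param outcome A logical/0-1 column name, or a constitution key (the
#'   indicator is then `primary == outcome`; for `"balanced"`, membership
#'   in the balanced group).
#' @param factor Name of a categorical covariate column.
#' @param alpha,m Family-wise level and number of tests in the family
#'   (defaults 0.05 and 9).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`,
#'   `alpha_corrected`, `significant`.
#' @export
chisq_independence <- function(cohort, outcome, factor, alpha = 0.05, m = 9) {
  y <- .outcome_indicator(cohort, outcome)
  f <- base::factor(cohort[[factor]])
  keep <- !is.na(y) & !is.na(f)
  tab <- table(y[keep], droplevels(f[keep]))
  if (ncol(tab) < 2) abort("factor must have >= 2 non-empty levels")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  .test_result("chisq_independence", ct$statistic, ct$parameter, ct$p.value,
               alpha, m)
}

#' Chi-squared test for linear trend
#'
#' Cochran-Armitage-style trend test: the 1-df chi-squared for a linear
#' trend in outcome proportion across an ordered factor, with integer
#' scores 1..k assigned to the levels (delegates to
#' [stats::prop.trend.test()]).
#'
#' @inheritParams chisq_independence
#' @param ordered_factor Name of an ordered categorical column with >= 3
#'   levels (e.g. `"age_group"`).
#' @return One-row tibble as in [chisq_independence()].
#' @export
chisq_trend <- function(cohort, outcome, ordered_factor, alpha = 0.05, m = 9) {
  y <- .outcome_indicator(cohort, outcome)
  f <- base::factor(cohort[[ordered_factor]])
  keep <- !is.na(y) & !is.na(f)
  f <- droplevels(f[keep]); y <- y[keep]
  if (nlevels(f) < 3) abort("ordered factor must have >= 3 non-empty levels")
  events <- tapply(y, f, sum)
  trials <- tapply(y, f, length)
  tt <- stats::prop.trend.test(events, trials, score = seq_len(nlevels(f)))
  .test_result("chisq_trend", tt$statistic, tt$parameter, tt$p.value, alpha, m)
}
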