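# Modified Poisson regression: a log-link Poisson GLM on a binary outcome
# with a robust (sandwich) variance estimator. The exponentiated exposure
# coefficients are adjusted prevalence ratios; averaging predicted
# probabilities with the exposure set to each level (marginal
# standardization) gives covariate-adjusted prevalences.

#' Fit a modified Poisson prevalence-ratio model
#'
#' Regresses a binary classification outcome on a categorical exposure,
#' adjusting for confounders (age group and sex by default), with a
#' Poisson log link so that exponentiated coefficients are prevalence
#' ratios rather than odds ratios. Because the Poisson likelihood is
#' misspecified for a binary outcome, standard errors come from the
#' HC0 sandwich estimator and confidence intervals are robust Wald
#' intervals.
#'
#' The model is complete-case: rows missing the outcome, exposure or any
#' adjustment covariate are dropped and the n actually used is reported by
#' [glance()]. Exposure levels in which the outcome never (or always)
#' occurs are rejected as separation.
#'
#' @param cohort Classified analytic cohort.
#' @param outcome A logical/0-1 column name or a constitution key (see
#'   [chisq_independence()]).
#' @param exposure Name of a categorical exposure column; its first factor
#'   level is the reference.
#' @param adjust Character vector of adjustment covariate columns; default
#'   `c("age_group", "sex")`. Use `character()` for an unadjusted model.
#' @return A `ccmq_pr` object with [tidy()], [glance()] and
#'   [marginal_standardization()] methods.
#' @examples
#' cohort <- tibble::tibble(
#'   y = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 70, 15, 85)),
#'   exp = factor(rep(c("a", "b"), c(100, 100)))
#' )
#' pr <- fit_prevalence_ratio(cohort, "y", "exp", adjust = character())
#' tidy(pr)  # PR for b vs a = 0.5
#' @export
fit_prevalence_ratio <- function(cohort, outcome, exposure,
                                 adjust = c("age_group", "sex")) {
  y <- .outcome_indicator(cohort, outcome)
  if (!exposure %in% names(cohort)) {
    abort(paste0("exposure column not found: ", exposure))
  }
  adjust <- setdiff(adjust, exposure)
  missing_adj <- setdiff(adjust, names(cohort))
  if (length(missing_adj) > 0) {
    abort(paste0("adjustment column(s) not found: ", toString(missing_adj)))
  }
  df <- tibble(.outcome = as.integer(y))
  df[[exposure]] <- factor(cohort[[exposure]])
  for (a in adjust) {
    v <- cohort[[a]]
    df[[a]] <- if (is.numeric(v)) v else factor(v)
  }
  complete <- stats::complete.cases(df)
  df <- df[complete, , drop = FALSE]
  df[[exposure]] <- droplevels(df[[exposure]])
  if (nlevels(df[[exposure]]) < 2) {
    abort("exposure must have >= 2 non-empty levels after complete-case filtering")
  }
  by_level <- tapply(df$.outcome, df[[exposure]], mean)
  sep <- names(by_level)[by_level %in% c(0, 1)]
  if (length(sep) > 0) {
    abort(paste0("separation: outcome is constant within exposure level(s) ",
                 toString(sep)))
  }
  fml <- as.formula(paste(
    ".outcome ~", paste(c(exposure, adjust), collapse = " + ")
  ))
  fit <- glm(fml, data = df, family = poisson(link = "log"))
  if (!fit$converged) {
    abort(paste0("modified Poisson fit did not converge for exposure ", exposure))
  }
  vc <- sandwich::vcovHC(fit, type = "HC0")
  structure(
    list(fit = fit, vcov = vc, outcome = outcome, exposure = exposure,
         adjust = adjust, data = df,
         reference = levels(df[[exposure]])[1]),
    class = "ccmq_pr"
  )
}

#' @export
print.ccmq_pr <- function(x, ...) {
  cat("Modified Poisson prevalence-ratio model\n")
  cat("  outcome:  ", x$outcome, "\n")
  cat("  exposure: ", x$exposure, " (reference: ", x$reference, ")\n", sep = "")
  cat("  adjusted for:", if (length(x$adjust)) toString(x$adjust) else "(none)", "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a prevalence-ratio model
#'
#' One row per exposure level, including the reference level with a PR of
#' exactly 1 and no interval.
#'
#' @param x A `ccmq_pr` object.
#' @param conf_level Confidence level for the robust Wald interval.
#' @param ... Unused.
#' @return Tibble with `term`, `level`, `pr`, `ci_low`, `ci_high`,
#'   `robust_se` (on the log scale), `p_value`.
#' @method tidy ccmq_pr
#' @export
tidy.ccmq_pr <- function(x, conf_level = 0.95, ...) {
  lv <- levels(x$data[[x$exposure]])
  terms <- paste0(x$exposure, lv[-1])
  est <- unname(coef(x$fit)[terms])
  se <- unname(sqrt(diag(x$vcov)[terms]))
  z <- qnorm(1 - (1 - conf_level) / 2)
  non_ref <- tibble(
    term = x$exposure, level = lv[-1],
    pr = exp(est),
    ci_low = exp(est - z * se),
    ci_high = exp(est + z * se),
    robust_se = se,
    p_value = 2 * stats::pnorm(-abs(est / se))
  )
  ref <- tibble(
    term = x$exposure, level = lv[1], pr = 1,
    ci_low = NA_real_, ci_high = NA_real_,
    robust_se = NA_real_, p_value = NA_real_
  )
  bind_rows(ref, non_ref)
}

#' @method glance ccmq_pr
#' @export
glance.ccmq_pr <- function(x, ...) {
  tibble(
    outcome = x$outcome,
    exposure = x$exposure,
    n = nrow(x$data),
    n_events = sum(x$data$.outcome),
    n_levels = nlevels(x$data[[x$exposure]]),
    converged = x$fit$converged,
    deviance = x$fit$deviance
  )
}

#' Marginally standardized (adjusted) prevalences
#'
#' For each exposure level L, sets every cohort member's exposure to L,
#' averages the model-predicted outcome probabilities, and reports the
#' mean as a percentage — the adjusted prevalence for that subgroup
#' (estimated marginal means over the observed covariate distribution).
#' The log link can predict probabilities above 1; such predictions are
#' truncated at 1 and their count reported.
#'
#' @param model A `ccmq_pr` object.
#' @return Tibble with `level`, `adjusted_prevalence` (in %), `n_capped`
#'   (predictions truncated at 1). A warning is raised if any were capped.
#' @export
marginal_standardization <- function(model) {
  stopifnot(inherits(model, "ccmq_pr"))
  lv <- levels(model$data[[model$exposure]])
  purrr::map_dfr(lv, function(l) {
    nd <- model$data
    nd[[model$exposure]] <- factor(l, levels = lv)
    p <- predict(model$fit, newdata = nd, type = "response")
    n_cap <- sum(p > 1)
    if (n_cap > 0) {
      warn(sprintf("%d predicted probabilities > 1 truncated at 1 (level %s)",
                   n_cap, l))
    }
    tibble(level = l, adjusted_prevalence = 100 * mean(pmin(p, 1)),
           n_capped = as.integer(n_cap))
  })
}
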