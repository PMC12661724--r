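# Synthetic CCMQ respondent generator with known ground truth.
#
# Design: each respondent is assigned a latent profile class (balanced, one
# of eight primary unbalanced constitutions, tendency-only, or
# no-classification) from a multinomial whose logits carry demographic
# shifts; class intercepts are calibrated by fixed-point iteration so the
# population marginals match the target mix regardless of the covariate
# effects. Each class implies a target converted score per constitution,
# drawn on the exact score lattice {100*k/(4N)}; the inverse of the
# conversion formula turns a target raw score into per-question responses
# (distributed as evenly as possible), so at zero noise the pipeline
# recovers the intended scores, statuses, group and primary exactly.
# Response noise perturbs individual responses by +/-1 with a small
# probability; low-engagement contamination (mostly-3 responders) and
# missing responses are injected last.

.demo_defaults <- function() {
  list(
    age_group_probs = c("18-29" = 0.054, "30-49" = 0.274, "50-59" = 0.258,
                        "60-69" = 0.299, "70+" = 0.116),
    sex_male_prob = 0.39,
    bmi_group_probs = c(underweight = 0.038, normal = 0.520,
                        overweight = 0.346, obese = 0.095),
    bmi_missing_prob = 0.0015,
    education_probs = c(elementary = 0.193, middle_school = 0.317,
                        high_school = 0.238, college = 0.252),
    income_probs = c("<3104" = 0.119, "3104-7760" = 0.510,
                     "7760-12416" = 0.228, "12416+" = 0.142),
    work_status_probs = c(working = 0.292, other = 0.215, retired = 0.493),
    marital_status_probs = c(married = 0.871, other = 0.073, single = 0.056),
    smoking_probs = c(never = 0.745, former = 0.072, current = 0.183),
    drinking_probs = c(never = 0.540, former = 0.020,
                       current_occasional = 0.249, current_frequent = 0.191)
  )
}

.default_class_mix <- function() {
  c(balanced = 0.223,
    qi_deficiency = 0.164, phlegm_dampness = 0.110, yang_deficiency = 0.094,
    yin_deficiency = 0.061, damp_heat = 0.046, qi_stagnation = 0.025,
    inherited_special = 0.011, blood_stasis = 0.008,
    tendency_only = 0.258)
}

.default_covariate_effects <- function() {
  tibble(
    class = c("phlegm_dampness", "phlegm_dampness", "phlegm_dampness",
              "damp_heat",
              "yang_deficiency", "yang_deficiency", "yang_deficiency",
              "yang_deficiency",
              "yin_deficiency", "yin_deficiency",
              "balanced", "balanced",
              "qi_stagnation", "inherited_special", "qi_deficiency"),
    term = c("obese", "overweight", "male",
             "male",
             "obese", "overweight", "male", "age_decade_c",
             "obese", "male",
             "obese", "age_decade_c",
             "age_decade_c", "age_decade_c", "age_decade_c"),
    shift = c(1.2, 0.6, 0.5,
              0.45,
              -1.5, -0.6, -0.6, 0.2,
              -0.7, -0.5,
              -0.9, 0.15,
              -0.35, -0.45, -0.1)
  )
}

.default_boosts <- function() {
  c("qi_stagnation:qi_deficiency" = 1.7,
    "qi_stagnation:yin_deficiency" = 1.4,
    "damp_heat:phlegm_dampness" = 1.5,
    "yang_deficiency:qi_deficiency" = 0.9,
    "blood_stasis:qi_deficiency" = 1.0,
    "blood_stasis:yin_deficiency" = 1.0,
    "inherited_special:qi_deficiency" = 0.8,
    "inherited_special:yin_deficiency" = 0.8)
}

#' Specify a synthetic CCMQ population
#'
#' Bundles every generative parameter of the synthetic cohort. The
#' defaults emulate a large urban community cohort: the class mix follows
#' the headline classification distribution of such cohorts (balanced
#' 22.3\%, Qi Deficiency 16.4\%, Phlegm Dampness 11.0\%, Yang Deficiency
#' 9.4\%, Yin Deficiency 6.1\%, Damp Heat 4.6\%, Qi Stagnation 2.5\%,
#' Inherited Special 1.1\%, Blood Stasis 0.8\%, tendency-only 25.8\%,
#' expressed as fractions of the classifiable population), with an
#' additional 5\% of unclassifiable profiles, composite and tendency
#' propensities per primary constitution, pairwise co-occurrence boosts
#' (Qi Stagnation with Qi Deficiency, Damp Heat with Phlegm Dampness, ...),
#' demographic covariate effects on the class logits (obesity raising
#' Phlegm Dampness and lowering Balanced/Yang/Yin Deficiency; age raising
#' Balanced and Yang Deficiency; sex effects), a small response-noise
#' rate, and low-engagement / missing-response contamination at the rates
#' seen in careful field work (about 0.2\% and 0.1\%).
#'
#' @param n Number of respondents.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param class_mix Named probabilities over `balanced`, the eight
#'   unbalanced constitution keys and `tendency_only`; must sum to 1.
#'   These are target proportions of the classifiable population.
#' @param no_classification_prob Fraction of profiles that meet no
#'   classification (excluded by QC).
#' @param response_noise Per-question probability of a +/-1 perturbation
#'   of the latent-implied response (clipped to 1-5).
#' @param contamination_prob Fraction of low-engagement respondents who
#'   answer "sometimes" (3) to most questions.
#' @param contamination_middle_count How many questions a contaminated
#'   respondent answers with 3 (default 52; remaining responses random).
#' @param missing_prob Fraction of respondents with 1-3 missing responses.
#' @param composite_probs Named per-primary probability of carrying at
#'   least one additional constitution.
#' @param composite_extra_prob Probability a composite respondent carries
#'   a second additional constitution.
#' @param tendency_probs Named per-primary probability of carrying
#'   unbalanced tendencies.
#' @param young_composite_logit Additive logit shift on the composite
#'   probability for respondents under 40 (younger adults carry composite
#'   constitutions more often).
#' @param cooccurrence_boosts Named log-odds increments
#'   (`"a:b" = boost`) favouring constitution `b` as a partner when the
#'   primary (or first tendency) is `a`.
#' @param covariate_effects Tibble (`class`, `term`, `shift`) of logit
#'   shifts; recognised terms are `male`, `underweight`, `overweight`,
#'   `obese` and `age_decade_c` (age centred at 50, per decade).
#' @param demographics List of demographic marginals (see defaults).
#' @return A `ccmq_population_spec` list.
#' @export
population_spec <- function(n = 10000, seed = 1,
                            class_mix = .default_class_mix(),
                            no_classification_prob = 0.050,
                            response_noise = 0.02,
                            contamination_prob = 0.00175,
                            contamination_middle_count = 52,
                            missing_prob = 0.001,
                            composite_probs = c(
                              qi_deficiency = 0.486, phlegm_dampness = 0.436,
                              yang_deficiency = 0.621, yin_deficiency = 0.528,
                              damp_heat = 0.585, qi_stagnation = 0.722,
                              inherited_special = 0.633, blood_stasis = 0.681
                            ),
                            composite_extra_prob = 0.3,
                            tendency_probs = c(
                              qi_deficiency = 0.651, phlegm_dampness = 0.622,
                              yang_deficiency = 0.691, yin_deficiency = 0.723,
                              damp_heat = 0.739, qi_stagnation = 0.769,
                              inherited_special = 0.653, blood_stasis = 0.739
                            ),
                            young_composite_logit = 0.45,
                            cooccurrence_boosts = .default_boosts(),
                            covariate_effects = .default_covariate_effects(),
                            demographics = .demo_defaults()) {
  if (n < 1) abort("n must be >= 1")
  classes <- c("balanced", constitutions(unbalanced_only = TRUE), "tendency_only")
  if (!setequal(names(class_mix), classes)) {
    abort("class_mix must name balanced, the 8 unbalanced keys and tendency_only")
  }
  if (abs(sum(class_mix) - 1) > 1e-6) abort("class_mix must sum to 1")
  probs <- c(class_mix, no_classification_prob, contamination_prob,
             missing_prob, response_noise)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must be in [0, 1]")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         class_mix = class_mix[classes],
         no_classification_prob = no_classification_prob,
         response_noise = response_noise,
         contamination_prob = contamination_prob,
         contamination_middle_count = contamination_middle_count,
         missing_prob = missing_prob,
         composite_probs = composite_probs,
         composite_extra_prob = composite_extra_prob,
         tendency_probs = tendency_probs,
         young_composite_logit = young_composite_logit,
         cooccurrence_boosts = cooccurrence_boosts,
         covariate_effects = covariate_effects,
         demographics = demographics),
    class = "ccmq_population_spec"
  )
}

# Lattice raw scores whose converted score lies in [lo, hi).
.lattice_raws <- function(n_questions, lo, hi) {
  raws <- n_questions:(5L * n_questions)
  s <- convert_score(raws, n_questions)
  out <- raws[s >= lo & s < hi]
  if (length(out) == 0) {
    abort(sprintf("no attainable score in [%g, %g) for a %d-question constitution",
                  lo, hi, n_questions))
  }
  out
}

.resample <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, replace = TRUE, prob = prob)]
}

# Score bands (on the converted scale) used for target placement. Bands
# keep latent scores clear of the decision thresholds so that, at the
# default noise rate, misclassification is rare and concentrated at the
# band edges.
.bands <- list(
  none = c(3, 23),
  tendency = c(30, 37),
  secondary = c(41, 58),
  primary = c(52, 71),
  balanced_high = c(66, 93),
  balanced_mid = c(28, 55)
)

.sample_band <- function(const, band, size = 1) {
  n_q <- .ccmq_question_counts[[const]]
  .resample(.lattice_raws(n_q, .bands[[band]][1], .bands[[band]][2]), size)
}

# Partner weights for composite / tendency co-occurrence.
.partner_weights <- function(anchor, candidates, mix, boosts) {
  w <- mix[candidates]
  if (length(boosts) > 0) {
    for (cand in candidates) {
      b <- boosts[paste0(anchor, ":", cand)]
      if (is.na(b)) b <- boosts[paste0(cand, ":", anchor)]
      if (!is.na(b)) w[cand] <- w[cand] * exp(b)
    }
  }
  w / sum(w)
}

#' Generate a synthetic respondent cohort
#'
#' Draws demographics, assigns latent profile classes (with
#' intercepts calibrated so that class marginals match
#' `spec$class_mix` despite covariate effects), places target converted
#' scores on the exact score lattice, inverts the conversion formula into
#' per-question responses, and finally injects response noise,
#' low-engagement contamination and missingness. Deterministic under
#' `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return A `ccmq_simulation` list:
#'   \describe{
#'     \item{respondents}{tibble ready for [qc_cascade()]: participant_id,
#'       57 question columns, demographics.}
#'     \item{truth}{per-respondent ground truth: latent class, intended
#'       group/primary/composite (from the target scores, pre-noise),
#'       target scores (`target_*` columns), contamination and
#'       missing-injection flags.}
#'   }
#' @export
simulate_respondents <- function(spec) {
  stopifnot(inherits(spec, "ccmq_population_spec"))
  set.seed(spec$seed)
  n <- spec$n
  schema <- ccmq_schema()
  unbal <- constitutions(unbalanced_only = TRUE)
  d <- spec$demographics

  # --- demographics -------------------------------------------------------
  age_rng <- list("18-29" = 18:29, "30-49" = 30:49, "50-59" = 50:59,
                  "60-69" = 60:69, "70+" = 70:80)
  ag <- .resample(names(d$age_group_probs), n, d$age_group_probs)
  age <- vapply(ag, function(g) .resample(age_rng[[g]], 1), integer(1))
  sex <- if_else(runif(n) < d$sex_male_prob, "male", "female")
  bmi_rng <- list(underweight = c(16, 18.5), normal = c(18.5, 24),
                  overweight = c(24, 28), obese = c(28, 35))
  bg <- .resample(names(d$bmi_group_probs), n, d$bmi_group_probs)
  bmi <- round(vapply(bg, function(g) runif(1, bmi_rng[[g]][1], bmi_rng[[g]][2]),
                      numeric(1)), 1)
  bmi[runif(n) < d$bmi_missing_prob] <- NA_real_
  demo <- tibble(
    participant_id = sprintf("S%06d", seq_len(n)),
    age = age, sex = sex, bmi = bmi,
    education = .resample(names(d$education_probs), n, d$education_probs),
    income = .resample(names(d$income_probs), n, d$income_probs),
    work_status = .resample(names(d$work_status_probs), n, d$work_status_probs),
    marital_status = .resample(names(d$marital_status_probs), n,
                               d$marital_status_probs),
    smoking = .resample(names(d$smoking_probs), n, d$smoking_probs),
    drinking = .resample(names(d$drinking_probs), n, d$drinking_probs)
  )

  # --- latent class assignment with calibrated intercepts -----------------
  classes <- c(names(spec$class_mix), "no_classification")
  target <- c(spec$class_mix * (1 - spec$no_classification_prob),
              no_classification = spec$no_classification_prob)
  terms <- tibble(
    male = as.numeric(sex == "male"),
    underweight = as.numeric(!is.na(bmi) & bmi < 18.5),
    overweight = as.numeric(!is.na(bmi) & bmi >= 24 & bmi < 28),
    obese = as.numeric(!is.na(bmi) & bmi >= 28),
    age_decade_c = (age - 50) / 10
  )
  shifts <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (i in seq_len(nrow(spec$covariate_effects))) {
    eff <- spec$covariate_effects[i, ]
    if (!eff$class %in% classes || !eff$term %in% names(terms)) {
      abort(paste0("unknown class/term in covariate_effects: ",
                   eff$class, "/", eff$term))
    }
    shifts[, eff$class] <- shifts[, eff$class] + eff$shift * terms[[eff$term]]
  }
  delta <- rep(0, length(classes))
  base_logit <- log(target)  # zero-target classes stay at -Inf
  for (it in 1:40) {
    lg <- sweep(shifts, 2, base_logit + delta, `+`)
    p <- exp(lg - apply(lg, 1, max))
    p <- p / rowSums(p)
    step <- log(target / colMeans(p))
    delta <- delta + if_else(target > 0 & is.finite(step), step, 0)
  }
  cum <- t(apply(p, 1, cumsum))
  u <- runif(n)
  class <- classes[max.col(u < cum, ties.method = "first")]

  # --- target raw scores on the exact lattice -----------------------------
  raws <- matrix(0L, n, 9, dimnames = list(NULL, constitutions()))
  for (const in unbal) raws[, const] <- .sample_band(const, "none", n)
  raws[, "balanced"] <- .sample_band("balanced", "balanced_mid", n)
  i_bal <- class == "balanced"
  if (any(i_bal)) {
    raws[i_bal, "balanced"] <- .sample_band("balanced", "balanced_high", sum(i_bal))
  }
  mix_u <- spec$class_mix[unbal]
  young <- age < 40
  for (i in which(class %in% unbal)) {
    pc <- class[i]
    raws[i, pc] <- .sample_band(pc, "primary")
    others <- setdiff(unbal, pc)
    taken <- pc
    comp_logit <- stats::qlogis(spec$composite_probs[[pc]]) +
      if (young[i]) spec$young_composite_logit else 0
    if (runif(1) < plogis(comp_logit)) {
      k <- 1L + rbinom(1, 1, spec$composite_extra_prob)
      w <- .partner_weights(pc, others, mix_u, spec$cooccurrence_boosts)
      partners <- sample(others, min(k, length(others)), prob = w)
      primary_score <- convert_score(raws[i, pc], .ccmq_question_counts[[pc]])
      for (pp in partners) {
        hi <- min(.bands$secondary[2], primary_score - 8)
        n_q <- .ccmq_question_counts[[pp]]
        raws[i, pp] <- .resample(.lattice_raws(n_q, .bands$secondary[1],
                                               max(hi, .bands$secondary[1] + 5)), 1)
      }
      taken <- c(taken, partners)
    }
    if (runif(1) < spec$tendency_probs[[pc]]) {
      free <- setdiff(unbal, taken)
      if (length(free) > 0) {
        k <- min(1L + rbinom(1, 1, 0.4), length(free))
        w <- .partner_weights(pc, free, mix_u, spec$cooccurrence_boosts)
        tends <- sample(free, k, prob = w)
        for (tt in tends) raws[i, tt] <- .sample_band(tt, "tendency")
      }
    }
  }
  for (i in which(class == "tendency_only")) {
    k <- 1L + rbinom(1, 2, 0.55)
    first <- .resample(unbal, 1, mix_u)
    tends <- first
    if (k > 1) {
      w <- .partner_weights(first, setdiff(unbal, first), mix_u,
                            spec$cooccurrence_boosts)
      tends <- c(first, sample(setdiff(unbal, first), k - 1L, prob = w))
    }
    for (tt in tends) raws[i, tt] <- .sample_band(tt, "tendency")
  }

  # --- intended classification (pre-noise ground truth) -------------------
  target_scores <- raws
  for (const in constitutions()) {
    target_scores[, const] <- convert_score(raws[, const],
                                            .ccmq_question_counts[[const]])
  }
  truth_cls <- classify_constitutions(
    dplyr::bind_cols(tibble(participant_id = demo$participant_id),
                     as_tibble(target_scores))
  )

  # --- responses: even decomposition of each raw score --------------------
  resp <- matrix(0L, n, 57, dimnames = list(NULL, schema$question_id))
  for (const in constitutions()) {
    cols <- schema$question_id[schema$constitution == const]
    n_q <- length(cols)
    base <- raws[, const] %/% n_q
    rem <- raws[, const] %% n_q
    for (j in seq_along(cols)) {
      resp[, cols[j]] <- as.integer(base + (j <= rem))
    }
  }
  # response noise: occasional +/-1 perturbation, clipped to 1..5
  if (spec$response_noise > 0) {
    u <- matrix(runif(n * 57), n, 57)
    resp <- resp - (u < spec$response_noise / 2) +
      (u > 1 - spec$response_noise / 2)
    resp <- pmin(pmax(resp, 1L), 5L)
  }
  # reverse-scored questions store the observed (pre-reversal) response
  rev_q <- schema$question_id[schema$polarity == "reverse"]
  if (length(rev_q) > 0) resp[, rev_q] <- 6L - resp[, rev_q]

  # --- contamination and missingness (last) -------------------------------
  contaminated <- runif(n) < spec$contamination_prob
  for (i in which(contaminated)) {
    mid <- sample.int(57, spec$contamination_middle_count)
    resp[i, mid] <- 3L
    resp[i, -mid] <- .resample(1:5, 57 - spec$contamination_middle_count)
  }
  missing_injected <- runif(n) < spec$missing_prob
  resp_na <- matrix(as.integer(resp), n, 57, dimnames = dimnames(resp))
  for (i in which(missing_injected)) {
    resp_na[i, sample.int(57, .resample(1:3, 1))] <- NA_integer_
  }

  respondents <- dplyr::bind_cols(
    tibble(participant_id = demo$participant_id),
    as_tibble(resp_na),
    demo[setdiff(names(demo), "participant_id")]
  )
  truth <- dplyr::bind_cols(
    tibble(
      participant_id = demo$participant_id,
      class = class,
      contaminated = contaminated,
      missing_injected = missing_injected,
      intended_group = truth_cls$group,
      intended_primary = truth_cls$primary,
      intended_composite = truth_cls$composite,
      intended_has_tendency = truth_cls$has_tendency
    ),
    as_tibble(target_scores) %>% rename_with_prefix("target_")
  )
  structure(list(respondents = respondents, truth = truth, spec = spec),
            class = "ccmq_simulation")
}

rename_with_prefix <- function(x, prefix) {
  names(x) <- paste0(prefix, names(x))
  x
}

#' @export
print.ccmq_simulation <- function(x, ...) {
  cat("Synthetic CCMQ cohort:", nrow(x$respondents), "respondents\n")
  print(count(x$truth, .data$class, sort = TRUE), n = 11)
  invisible(x)
}

#' Simulate a cohort with a known prevalence ratio
#'
#' Generates a binary exposure and a binary outcome from a log-link model
#' with a fixed conditional prevalence ratio, with optional confounding by
#' age and sex (the exposure probability depends on the confounders, so
#' the crude ratio is biased while the adjusted model recovers `pr`).
#' Used for coverage and calibration checks of [fit_prevalence_ratio()].
#'
#' @param n Number of subjects.
#' @param pr True conditional prevalence ratio of exposed vs unexposed.
#' @param baseline Outcome probability for an unexposed reference subject.
#' @param exposure_prob Marginal exposure probability (before
#'   confounding shifts).
#' @param confounded If `TRUE`, exposure depends on age and sex.
#' @param seed Optional seed.
#' @return Tibble with `y` (logical outcome), `exposure` (factor,
#'   reference `"unexposed"`), `age_decade_c`, `sex`.
#' @export
simulate_pr_cohort <- function(n, pr = 1.5, baseline = 0.08,
                               exposure_prob = 0.3, confounded = TRUE,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  age_c <- rnorm(n)
  male <- runif(n) < 0.4
  e_logit <- stats::qlogis(exposure_prob) +
    if (confounded) 0.5 * age_c + 0.3 * male else 0
  exposed <- runif(n) < plogis(e_logit)
  p <- baseline * pr^exposed * exp(0.15 * age_c + 0.1 * male)
  if (any(p >= 1)) abort("outcome probability >= 1; lower baseline or pr")
  tibble(
    y = runif(n) < p,
    exposure = factor(if_else(exposed, "exposed", "unexposed"),
                      levels = c("unexposed", "exposed")),
    age_decade_c = age_c,
    sex = if_else(male, "male", "female")
  )
}

#' Write a deterministic fixture suite
#'
#' Emits small canned inputs exercising every pipeline stage: an exact
#' boundary score table (scores at 30, 40 and 60), a tie-case score
#' table, a pure-contamination cohort, a missing-response cohort, and a
#' confounded cohort with a built-in prevalence ratio, together with a
#' JSON manifest of the expectations each fixture encodes.
#'
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unbal <- constitutions(unbalanced_only = TRUE)
  base_scores <- function(id) {
    s <- tibble(participant_id = id, balanced = 50)
    s[unbal] <- as.list(rep(10, 8))
    s
  }
  b1 <- base_scores("boundary_tendency");  b1$qi_deficiency <- 30
  b2 <- base_scores("boundary_constitution"); b2$qi_deficiency <- 40
  b3 <- base_scores("boundary_balanced"); b3$balanced <- 60
  b4 <- base_scores("boundary_none"); b4$balanced <- 59.9
  boundary <- bind_rows(b1, b2, b3, b4)
  readr::write_csv(boundary, file.path(out_dir, "boundary_scores.csv"))

  t1 <- base_scores("tie_constitution")
  t1$qi_deficiency <- 45; t1$yin_deficiency <- 45
  t2 <- base_scores("tie_tendency")
  t2$blood_stasis <- 35; t2$qi_stagnation <- 35
  readr::write_csv(bind_rows(t1, t2), file.path(out_dir, "tie_scores.csv"))

  spec_cont <- population_spec(n = 20, seed = 101, contamination_prob = 1,
                               missing_prob = 0, response_noise = 0)
  write_respondents(simulate_respondents(spec_cont)$respondents,
                    file.path(out_dir, "contamination_respondents.csv"))
  spec_miss <- population_spec(n = 20, seed = 102, contamination_prob = 0,
                               missing_prob = 1, response_noise = 0)
  write_respondents(simulate_respondents(spec_miss)$respondents,
                    file.path(out_dir, "missing_respondents.csv"))
  pr_truth <- 1.5
  readr::write_csv(simulate_pr_cohort(4000, pr = pr_truth, seed = 103),
                   file.path(out_dir, "pr_cohort.csv"))

  manifest <- list(
    boundary_scores = list(
      boundary_tendency = "qi_deficiency exactly 30 -> tendency_only",
      boundary_constitution = "qi_deficiency exactly 40 -> unbalanced_constitution",
      boundary_balanced = "balanced exactly 60, all unbalanced < 30 -> balanced",
      boundary_none = "balanced 59.9, all unbalanced < 30 -> no_classification"
    ),
    tie_scores = list(
      tie_constitution = "qi_deficiency and yin_deficiency both 45; primary qi_deficiency, tie flag",
      tie_tendency = "blood_stasis and qi_stagnation both 35; primary qi_stagnation, tie flag"
    ),
    contamination_respondents = list(
      expectation = "all respondents excluded_middle_response at threshold 50"
    ),
    missing_respondents = list(
      expectation = "all respondents excluded_missing"
    ),
    pr_cohort = list(true_pr = pr_truth, outcome = "y",
                     exposure = "exposure",
                     adjust = c("age_decade_c", "sex"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
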