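# ZZYXH/T157-2009 decision rules applied to converted-score profiles:
#   * unbalanced constitution: score >= 40
#   * unbalanced tendency:     30 <= score < 40
#   * balanced constitution:   Balanced >= 60 AND all eight unbalanced < 30
#   * no classification:       Balanced < 60 AND all eight unbalanced < 30
# Respondents are then grouped (balanced / unbalanced_constitution /
# tendency_only / no_classification) and, where multiple constitutions or
# tendencies co-occur, the one with the highest score is the primary
# classification. Thresholds compare unrounded scores.

#' Classify score profiles into constitutions, tendencies and groups
#'
#' Applies the decision rules above to each row of a score table. The
#' four groups partition the respondents:
#' \describe{
#'   \item{balanced}{Balanced score >= 60 and every unbalanced score < 30.}
#'   \item{unbalanced_constitution}{at least one unbalanced score >= 40;
#'     the highest-scoring such constitution is the primary.}
#'   \item{tendency_only}{no constitution of any kind but at least one
#'     unbalanced score in \code{[30, 40)}; the highest-scoring tendency is
#'     the primary.}
#'   \item{no_classification}{Balanced < 60 and all unbalanced < 30.}
#' }
#' When two or more candidates share the maximal score the tie is broken by
#' a fixed priority order (descending typical community prevalence:
#' Qi Deficiency, Phlegm Dampness, Yang Deficiency, Yin Deficiency,
#' Damp Heat, Qi Stagnation, Inherited Special, Blood Stasis) and the
#' `tie` flag is set so the choice can be audited.
#'
#' @param scores Tibble from [score_respondents()]: `participant_id` plus
#'   one numeric column in `[0, 100]` per constitution key.
#' @return A tibble with one row per respondent: `participant_id`, `group`,
#'   `primary` (constitution key, `"balanced"`, or `NA` for
#'   no-classification), `n_constitutions` (count of unbalanced
#'   constitutions), `composite` (>= 2 unbalanced constitutions),
#'   `has_tendency`, `tie`, and a `status_*` column per unbalanced
#'   constitution with values `none` / `tendency` / `constitution`.
#' @examples
#' s <- tibble::tibble(participant_id = "p1", balanced = 65,
#'   qi_deficiency = 10, yin_deficiency = 10, yang_deficiency = 10,
#'   phlegm_dampness = 10, damp_heat = 10, blood_stasis = 10,
#'   qi_stagnation = 10, inherited_special = 10)
#' classify_constitutions(s)$group  # "balanced"
#' @export
classify_constitutions <- function(scores) {
  scores <- as_tibble(scores)
  unbal <- constitutions(unbalanced_only = TRUE)
  need <- c("participant_id", "balanced", unbal)
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols) > 0) {
    abort(paste0("score table missing columns: ", toString(missing_cols)))
  }
  sc <- as.matrix(scores[c("balanced", unbal)])
  if (anyNA(sc) || any(sc < 0) || any(sc > 100)) {
    abort("all nine scores must be present and in [0, 100]")
  }
  th <- .ccmq_thresholds
  u <- sc[, unbal, drop = FALSE]
  is_const <- u >= th[["constitution"]]
  is_tend <- u >= th[["tendency"]] & u < th[["constitution"]]
  all_below <- rowSums(u >= th[["tendency"]]) == 0
  is_balanced <- sc[, "balanced"] >= th[["balanced"]] & all_below

  n_const <- rowSums(is_const)
  has_tend <- rowSums(is_tend) > 0
  group <- case_when(
    n_const >= 1 ~ "unbalanced_constitution",
    is_balanced ~ "balanced",
    has_tend ~ "tendency_only",
    TRUE ~ "no_classification"
  )

  # Primary: highest score among the candidate set; ties broken by the
  # fixed priority order with the tie flag raised.
  prio <- match(unbal, .ccmq_tie_priority)
  pick_primary <- function(cand_mask, score_row) {
    idx <- which(cand_mask)
    if (length(idx) == 0) return(c(NA_integer_, 0L))
    s <- score_row[idx]
    top <- idx[s == max(s)]
    tie <- length(top) > 1L
    winner <- top[order(prio[top])][1L]
    c(winner, as.integer(tie))
  }
  n_row <- nrow(sc)
  primary <- character(n_row)
  tie <- logical(n_row)
  for (i in seq_len(n_row)) {
    g <- group[i]
    if (g == "balanced") {
      primary[i] <- "balanced"; tie[i] <- FALSE
    } else if (g == "no_classification") {
      primary[i] <- NA_character_; tie[i] <- FALSE
    } else {
      mask <- if (g == "unbalanced_constitution") is_const[i, ] else is_tend[i, ]
      res <- pick_primary(mask, u[i, ])
      primary[i] <- unbal[res[1L]]
      tie[i] <- res[2L] == 1L
    }
  }

  status <- matrix("none", n_row, length(unbal), dimnames = list(NULL, unbal))
  status[is_tend] <- "tendency"
  status[is_const] <- "constitution"
  status_tbl <- as_tibble(status)
  names(status_tbl) <- paste0("status_", unbal)

  dplyr::bind_cols(
    tibble(
      participant_id = as.character(scores$participant_id),
      group = factor(group, levels = c(
        "balanced", "unbalanced_constitution", "tendency_only",
        "no_classification"
      )),
      primary = primary,
      n_constitutions = as.integer(n_const),
      composite = n_const >= 2L,
      has_tendency = has_tend,
      tie = tie
    ),
    status_tbl
  )
}

#' Count middle ("sometimes") responses
#'
#' The number of answered questions equal to 3, the middle of the
#' five-point scale. Missing responses do not count. Used by the QC cascade
#' to flag low-engagement respondents.
#'
#' @param data Respondent tibble.
#' @param schema Questionnaire schema.
#' @return Tibble with `participant_id` and `n_middle` (0-57).
#' @export
count_middle_responses <- function(data, schema = ccmq_schema()) {
  data <- validate_respondents(data, schema)
  resp <- as.matrix(data[schema$question_id])
  tibble(
    participant_id = data$participant_id,
    n_middle = as.integer(rowSums(resp == 3L, na.rm = TRUE))
  )
}

#' Quality-control exclusion cascade
#'
#' Applies the study exclusions in order, each respondent receiving exactly
#' one disposition:
#' \enumerate{
#'   \item `excluded_missing` — any of the 57 responses missing (scoring
#'     requires complete responses);
#'   \item `excluded_middle_response` — middle response ("sometimes", 3)
#'     chosen for at least `middle_threshold` questions, a low-engagement
#'     pattern that inflates all nine scores toward 50 and spuriously
#'     produces many coexisting constitutions;
#'   \item `excluded_no_classification` — scored but Balanced < 60 with all
#'     unbalanced scores < 30, so no constitution or tendency applies;
#'   \item `included` — everyone else, forming the analytic cohort.
#' }
#'
#' @param data Respondent tibble.
#' @param schema Questionnaire schema.
#' @param middle_threshold Middle-response exclusion threshold: default 50
#'   (88\% of 57 questions); 29 (>= 50\%) is the stringent sensitivity
#'   setting; `Inf` disables the exclusion.
#' @param allergy Allergy-item aggregation, passed to
#'   [score_respondents()].
#' @return A list of class `ccmq_qc`:
#'   \describe{
#'     \item{cohort}{included respondents joined with their nine scores,
#'       classification and derived covariates — the analytic cohort.}
#'     \item{ledger}{one row per input respondent: `participant_id`,
#'       `disposition`, `n_middle`.}
#'   }
#' @examples
#' spec <- population_spec(n = 200, seed = 1)
#' qc <- qc_cascade(simulate_respondents(spec)$respondents)
#' table(qc$ledger$disposition)
#' @export
qc_cascade <- function(data, schema = ccmq_schema(), middle_threshold = 50,
                       allergy = c("questions", "max_item")) {
  allergy <- match.arg(allergy)
  data <- validate_respondents(data, schema)
  resp <- as.matrix(data[schema$question_id])
  n_middle <- as.integer(rowSums(resp == 3L, na.rm = TRUE))
  disposition <- rep("included", nrow(data))
  disposition[n_middle >= middle_threshold] <- "excluded_middle_response"
  disposition[rowSums(is.na(resp)) > 0] <- "excluded_missing"

  keep <- disposition == "included"
  scored <- if (any(keep)) {
    score_respondents(data[keep, , drop = FALSE], schema, allergy = allergy)
  } else {
    NULL
  }
  if (!is.null(scored) && nrow(scored) > 0) {
    cls <- classify_constitutions(scored)
    no_class <- cls$participant_id[cls$group == "no_classification"]
    disposition[data$participant_id %in% no_class] <- "excluded_no_classification"
    keep_ids <- cls$participant_id[cls$group != "no_classification"]
    cohort <- data[data$participant_id %in% keep_ids, , drop = FALSE]
    cohort <- left_join(cohort, scored, by = "participant_id")
    cohort <- left_join(cohort, cls, by = "participant_id")
    if ("age" %in% names(cohort)) cohort <- derive_covariates(cohort)
  } else {
    cohort <- data[0, , drop = FALSE]
  }

  ledger <- tibble(
    participant_id = data$participant_id,
    disposition = factor(disposition, levels = c(
      "included", "excluded_missing", "excluded_middle_response",
      "excluded_no_classification"
    )),
    n_middle = n_middle
  )
  structure(list(cohort = as_tibble(cohort), ledger = ledger),
            class = "ccmq_qc")
}

#' @export
print.ccmq_qc <- function(x, ...) {
  counts <- table(x$ledger$disposition)
  cat("CCMQ QC cascade:", sum(counts), "respondents\n")
  for (d in names(counts)) cat(sprintf("  %-28s %d\n", d, counts[[d]]))
  invisible(x)
}

#' @method glance ccmq_qc
#' @export
glance.ccmq_qc <- function(x, ...) {
  counts <- table(x$ledger$disposition)
  tibble(
    n_input = nrow(x$ledger),
    n_included = counts[["included"]],
    n_excluded_missing = counts[["excluded_missing"]],
    n_excluded_middle_response = counts[["excluded_middle_response"]],
    n_excluded_no_classification = counts[["excluded_no_classification"]]
  )
}
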