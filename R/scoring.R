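# Converted-score computation. For each constitution the raw score is the
# sum of its questions' effective responses (after polarity handling), and
# the converted score rescales it to 0-100:
#   converted = ((raw - N) / (4 * N)) * 100
# where N is that constitution's question count. Scores are never rounded
# internally: the 30/40/60 classification thresholds compare against the
# exact lattice values 100*k/(4N).

#' Polarity-adjusted effective response
#'
#' A direct question contributes its response value; a reverse-scored
#' question contributes `6 - value`, so 1 and 5 swap and the midpoint 3 is
#' fixed.
#'
#' @param value Integer responses in 1-5.
#' @param polarity `"direct"` or `"reverse"`, recycled against `value`.
#' @return Integer vector of effective responses in 1-5.
#' @examples
#' effective_response(1:5, "reverse")
#' @export
effective_response <- function(value, polarity = "direct") {
  if (any(!is.na(value) & !(value %in% 1:5))) {
    abort("responses must be integers in 1-5")
  }
  if (!all(polarity %in% c("direct", "reverse"))) {
    abort("polarity must be 'direct' or 'reverse'")
  }
  as.integer(if_else(rep_len(polarity, length(value)) == "reverse",
                     6L - as.integer(value), as.integer(value)))
}

#' Convert a raw constitution score to the 0-100 scale
#'
#' Applies `((raw - N) / (4 * N)) * 100`, the linear map sending the
#' all-ones floor `raw = N` to 0 and the all-fives ceiling `raw = 5 N` to
#' 100. Vectorized over `raw` and `n`.
#'
#' @param raw Raw score: sum of the constitution's effective responses.
#' @param n Number of questions contributing (N).
#' @return Converted score(s) in `[0, 100]`, unrounded.
#' @examples
#' convert_score(13, 5)  # 40
#' convert_score(21, 7)  # 50
#' @export
convert_score <- function(raw, n) {
  if (any(n < 1)) abort("n must be >= 1")
  bad <- !is.na(raw) & (raw < n | raw > 5 * n)
  if (any(bad)) {
    abort(sprintf("raw score %s outside [N, 5N] = [%s, %s]",
                  format(raw[bad][1]), format(n[bad][1]), format(5 * n[bad][1])))
  }
  (raw - n) / (4 * n) * 100
}

#' Score respondents on the nine constitutions
#'
#' Computes the nine converted scores for every respondent with complete
#' responses. Respondents missing any of the 57 responses cannot be scored
#' — by default they are dropped with a warning (the QC cascade accounts
#' for them explicitly); set `on_incomplete = "error"` to fail instead.
#'
#' The allergy item of Inherited Special is administered as four questions.
#' By default all four enter the sum directly with N = 6, matching the
#' question-level scoring rule. `allergy = "max_item"` instead collapses
#' the four questions to their maximum as a single item value with N = 3,
#' an alternative item-level aggregation.
#'
#' @param data Respondent tibble (see [read_respondents()]).
#' @param schema Questionnaire schema.
#' @param allergy `"questions"` (default) or `"max_item"`.
#' @param on_incomplete `"drop"` (default, with warning) or `"error"`.
#' @return A tibble with `participant_id` and one numeric column per
#'   constitution key, each in `[0, 100]`.
#' @examples
#' sch <- ccmq_schema()
#' resp <- tibble::tibble(participant_id = "p1")
#' resp[sch$question_id] <- as.list(rep(3L, 57))
#' score_respondents(resp, sch)  # all nine scores 50
#' @export
score_respondents <- function(data, schema = ccmq_schema(),
                              allergy = c("questions", "max_item"),
                              on_incomplete = c("drop", "error")) {
  allergy <- match.arg(allergy)
  on_incomplete <- match.arg(on_incomplete)
  validate_schema(schema)
  data <- validate_respondents(data, schema)

  resp <- as.matrix(data[schema$question_id])
  incomplete <- rowSums(is.na(resp)) > 0
  if (any(incomplete)) {
    msg <- sprintf("%d respondent(s) with incomplete responses", sum(incomplete))
    if (on_incomplete == "error") abort(paste0(msg, "; classification requires all 57"))
    warn(paste0(msg, " dropped before scoring"))
    data <- data[!incomplete, , drop = FALSE]
    resp <- resp[!incomplete, , drop = FALSE]
  }

  eff <- resp
  rev_cols <- which(schema$polarity == "reverse")
  if (length(rev_cols) > 0) eff[, rev_cols] <- 6L - eff[, rev_cols]

  scores <- matrix(NA_real_, nrow(eff), length(constitutions()),
                   dimnames = list(NULL, constitutions()))
  item_counts <- table(schema$item_id)
  allergy_item <- names(item_counts)[item_counts == 4L]
  for (const in constitutions()) {
    cols <- which(schema$constitution == const)
    if (const == "inherited_special" && allergy == "max_item") {
      a_cols <- cols[schema$item_id[cols] == allergy_item]
      s_cols <- setdiff(cols, a_cols)
      raw <- rowSums(eff[, s_cols, drop = FALSE]) +
        apply(eff[, a_cols, drop = FALSE], 1, max)
      n_q <- length(s_cols) + 1L
    } else {
      raw <- rowSums(eff[, cols, drop = FALSE])
      n_q <- length(cols)
    }
    scores[, const] <- convert_score(raw, n_q)
  }

  dplyr::bind_cols(
    tibble(participant_id = data$participant_id),
    as_tibble(scores)
  )
}
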