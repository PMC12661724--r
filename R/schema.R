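# Questionnaire schema: the 57 questions, their constitution assignment,
# item grouping (the allergy item is administered as 4 questions), and
# per-question polarity. The schema is data, not code: it can be read from
# and written to JSON, and a bundled default honours the published
# per-constitution question counts.

#' Default CCMQ questionnaire schema
#'
#' Builds the bundled structural schema of the 2016 CCMQ: 57 five-point
#' Likert questions mapped to the nine constitutions (Balanced 7,
#' Qi Deficiency 6, Yin Deficiency 6, Yang Deficiency 7, Phlegm Dampness 5,
#' Damp Heat 6, Blood Stasis 7, Qi Stagnation 7, Inherited Special 6),
#' grouped into 54 items because the allergy-related item of the Inherited
#' Special constitution is administered as four separate questions.
#' Question wording is deliberately not part of the schema.
#'
#' Polarity defaults to `direct` for every question (a response of 5
#' contributes 5 to the raw score). The published instrument reverse-scores
#' some questions; set `reverse` to the IDs of those questions if your data
#' follow the original coding rather than pre-reversed responses.
#'
#' @param reverse Character vector of question IDs to flag as
#'   reverse-scored (effective response is `6 - value`). Default none.
#' @param version Version tag stored on the schema.
#' @return A `ccmq_schema`: a tibble with one row per question and columns
#'   `question_id`, `item_id`, `constitution`, `polarity`, plus a `version`
#'   attribute.
#' @examples
#' sch <- ccmq_schema()
#' nrow(sch)                     # 57 questions
#' dplyr::n_distinct(sch$item_id) # 54 items
#' @export
ccmq_schema <- function(reverse = character(), version = "ccmq-2016-default") {
  counts <- .ccmq_question_counts
  constitution <- rep(names(counts), counts)
  question_id <- sprintf("Q%02d", seq_len(sum(counts)))
  # One item per question except the allergy item: the last four Inherited
  # Special questions share a single item.
  item <- integer(length(question_id))
  item_counter <- 0L
  allergy_rows <- which(constitution == "inherited_special")
  allergy_rows <- utils::tail(allergy_rows, 4L)
  for (i in seq_along(question_id)) {
    if (i %in% allergy_rows) {
      if (i == allergy_rows[1L]) item_counter <- item_counter + 1L
      item[i] <- item_counter
    } else {
      item_counter <- item_counter + 1L
      item[i] <- item_counter
    }
  }
  schema <- tibble(
    question_id = question_id,
    item_id = sprintf("I%02d", item),
    constitution = constitution,
    polarity = if_else(question_id %in% reverse, "reverse", "direct")
  )
  bad <- setdiff(reverse, question_id)
  if (length(bad) > 0) {
    abort(paste0("unknown question IDs in `reverse`: ", toString(bad)))
  }
  new_ccmq_schema(schema, version = version)
}

new_ccmq_schema <- function(x, version) {
  x <- as_tibble(x)
  attr(x, "version") <- version
  class(x) <- c("ccmq_schema", class(x))
  validate_schema(x)
}

#' Validate a questionnaire schema
#'
#' Checks the structural invariants of a CCMQ schema: exactly 57 questions,
#' the published per-constitution counts, 54 distinct items with exactly
#' one 4-question item (the allergy item, inside Inherited Special), every
#' question assigned to exactly one known constitution, and a valid
#' polarity flag on each question.
#'
#' @param schema A schema tibble (see [ccmq_schema()]).
#' @return The schema, invisibly unchanged, if valid; otherwise an error
#'   naming the violated invariant.
#' @export
validate_schema <- function(schema) {
  req <- c("question_id", "item_id", "constitution", "polarity")
  missing_cols <- setdiff(req, names(schema))
  if (length(missing_cols) > 0) {
    abort(paste0("schema missing columns: ", toString(missing_cols)))
  }
  if (nrow(schema) != 57L) {
    abort(sprintf("question count != 57 (got %d)", nrow(schema)))
  }
  if (anyDuplicated(schema$question_id)) {
    abort("duplicate question_id in schema")
  }
  unknown <- setdiff(schema$constitution, constitutions())
  if (length(unknown) > 0) {
    abort(paste0("unknown constitution(s): ", toString(unknown)))
  }
  got <- table(factor(schema$constitution, levels = constitutions()))
  want <- .ccmq_question_counts[constitutions()]
  off <- names(want)[as.integer(got) != as.integer(want)]
  if (length(off) > 0) {
    abort(paste0(
      "per-constitution question counts violated for: ", toString(off),
      " (expected ", toString(sprintf("%s=%d", off, want[off])), ")"
    ))
  }
  items <- table(schema$item_id)
  if (length(items) != 54L) {
    abort(sprintf("item count != 54 (got %d)", length(items)))
  }
  multi <- items[items > 1L]
  if (length(multi) != 1L || multi[[1L]] != 4L) {
    abort("exactly one item must map to 4 questions (the allergy item)")
  }
  allergy_const <- unique(schema$constitution[schema$item_id == names(multi)])
  if (!identical(allergy_const, "inherited_special")) {
    abort("the 4-question allergy item must lie within Inherited Special")
  }
  if (!all(schema$polarity %in% c("direct", "reverse"))) {
    abort("polarity must be 'direct' or 'reverse'")
  }
  invisible(schema)
}

#' Read or write a schema as JSON
#'
#' The on-disk form is a JSON object with a `version` string and a
#' `questions` array of `{question_id, item_id, constitution, polarity}`
#' records. `read_schema()` validates all structural invariants before
#' returning.
#'
#' @param path Path to a schema JSON file.
#' @return `read_schema()` returns a validated `ccmq_schema`;
#'   `write_schema()` returns `path` invisibly.
#' @examples
#' p <- tempfile(fileext = ".json")
#' write_schema(ccmq_schema(), p)
#' sch <- read_schema(p)
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("schema file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$questions)) abort("schema JSON must contain a 'questions' array")
  q <- as_tibble(raw$questions)
  if (is.null(q$polarity)) q$polarity <- "direct"
  new_ccmq_schema(q, version = raw$version %||% "unversioned")
}

#' @rdname read_schema
#' @param schema A validated schema tibble.
#' @export
write_schema <- function(schema, path) {
  validate_schema(schema)
  jsonlite::write_json(
    list(
      version = attr(schema, "version") %||% "unversioned",
      questions = as.data.frame(schema[c(
        "question_id", "item_id", "constitution", "polarity"
      )])
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
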