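# Respondent-level I/O. The on-disk dialect is UTF-8 CSV with a header row:
# participant_id, the 57 question columns named by schema question_id, and
# any demographic columns. Missing cells stay missing at read time; the QC
# cascade, not the reader, decides exclusions.

#' Read a respondent CSV
#'
#' Reads one row per participant. The header must contain `participant_id`
#' and all 57 question IDs of `schema`; demographic columns (`age`, `sex`,
#' `bmi`, ...) are carried through unchanged. Likert cells must be integers
#' in 1-5 or blank; out-of-range values are rejected with the offending row
#' and column named. Blank responses are preserved as `NA` — missingness is
#' legal at read time and handled by [qc_cascade()].
#'
#' @param path Path to a CSV file.
#' @param schema Questionnaire schema, default [ccmq_schema()].
#' @return A tibble with one row per respondent.
#' @export
read_respondents <- function(path, schema = ccmq_schema()) {
  validate_schema(schema)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_respondents(data, schema)
}

#' Validate a respondent table against a schema
#'
#' Structural checks shared by [read_respondents()] and in-memory
#' pipelines: required columns present, participant IDs unique, every
#' present Likert response in 1-5.
#'
#' @param data Respondent tibble.
#' @param schema Questionnaire schema.
#' @return The data, as a tibble with integer question columns.
#' @export
validate_respondents <- function(data, schema = ccmq_schema()) {
  data <- as_tibble(data)
  if (!"participant_id" %in% names(data)) {
    abort("respondent data must contain a 'participant_id' column")
  }
  missing_q <- setdiff(schema$question_id, names(data))
  if (length(missing_q) > 0) {
    abort(paste0("missing question columns: ", toString(head(missing_q, 5)),
                 if (length(missing_q) > 5) " ..."))
  }
  if (anyDuplicated(data$participant_id)) {
    dup <- data$participant_id[duplicated(data$participant_id)][1]
    abort(paste0("duplicate participant_id: ", dup))
  }
  data$participant_id <- as.character(data$participant_id)
  for (q in schema$question_id) {
    v <- data[[q]]
    if (!is.numeric(v)) {
      suppressWarnings(v_num <- as.numeric(v))
      if (any(!is.na(v) & is.na(v_num))) {
        bad <- which(!is.na(v) & is.na(v_num))[1]
        abort(sprintf("non-numeric response in column %s, row %d: '%s'",
                      q, bad, v[bad]))
      }
      v <- v_num
    }
    ok <- is.na(v) | (v %in% 1:5)
    if (!all(ok)) {
      bad <- which(!ok)[1]
      abort(sprintf(
        "response out of range 1-5 in column %s, row %d (participant %s): %s",
        q, bad, data$participant_id[bad], format(v[bad])
      ))
    }
    data[[q]] <- as.integer(v)
  }
  data
}

#' Write a respondent CSV
#'
#' Inverse of [read_respondents()]: a write-then-read round trip reproduces
#' the records exactly.
#'
#' @param data Respondent tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_respondents <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(path)
}

#' Derive analysis covariates
#'
#' Adds the grouped covariates used by the prevalence and composite
#' analyses:
#' \describe{
#'   \item{age_group}{five levels: 18-29, 30-49, 50-59, 60-69, 70+}
#'   \item{age_group_young}{two levels, 18-39 vs 40+, used for the
#'     age-stratified composite analysis}
#'   \item{bmi_group}{Working Group on Obesity in China cutoffs:
#'     underweight (< 18.5), normal (18.5-23.9), overweight (24.0-27.9),
#'     obese (>= 28 kg/m^2). The printed decimal ranges are read as
#'     half-open intervals \code{[18.5, 24)} and \code{[24, 28)} so the
#'     binning is exhaustive on positive BMI.}
#' }
#' Respondents with missing BMI get a missing `bmi_group`. Ages outside
#' the 18-80 cohort definition are kept but trigger a warning.
#'
#' @param data Respondent tibble with an `age` column and optionally `bmi`.
#' @return The tibble with `age_group`, `age_group_young` and (if `bmi`
#'   present) `bmi_group` factor columns added.
#' @examples
#' derive_covariates(tibble::tibble(age = c(25, 39, 70), bmi = c(17, 23.9, 28)))
#' @export
derive_covariates <- function(data) {
  data <- as_tibble(data)
  if (!"age" %in% names(data)) abort("derive_covariates() requires an 'age' column")
  out_of_range <- !is.na(data$age) & (data$age < 18 | data$age > 80)
  if (any(out_of_range)) {
    warn(sprintf("%d respondent(s) outside the 18-80 age range (kept)",
                 sum(out_of_range)))
  }
  age_levels <- c("18-29", "30-49", "50-59", "60-69", "70+")
  data$age_group <- cut(
    data$age, breaks = c(-Inf, 30, 50, 60, 70, Inf), right = FALSE,
    labels = age_levels
  )
  data$age_group[!is.na(data$age) & data$age < 18] <- NA
  data$age_group_young <- factor(
    if_else(data$age < 40, "18-39", "40+"),
    levels = c("18-39", "40+")
  )
  data$age_group_young[!is.na(data$age) & data$age < 18] <- NA
  if ("bmi" %in% names(data)) {
    data$bmi_group <- cut(
      as.numeric(data$bmi), breaks = c(0, 18.5, 24, 28, Inf), right = FALSE,
      labels = c("underweight", "normal", "overweight", "obese")
    )
  }
  data
}
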