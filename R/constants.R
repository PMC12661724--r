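# Shared constants: constitution keys, labels, question counts, thresholds.

#' The nine TCM body constitutions
#'
#' Returns the canonical constitution keys used throughout the package, in
#' schema order. `balanced` is the single balanced constitution; the other
#' eight are the unbalanced constitutions.
#'
#' @param unbalanced_only If `TRUE`, drop `balanced` and return the eight
#'   unbalanced constitution keys.
#' @return Character vector of constitution keys (snake_case).
#' @examples
#' constitutions()
#' constitutions(unbalanced_only = TRUE)
#' @export
constitutions <- function(unbalanced_only = FALSE) {
  keys <- names(.ccmq_question_counts)
  if (unbalanced_only) keys[keys != "balanced"] else keys
}

# Per-constitution question counts of the 2016 CCMQ (57 questions total).
.ccmq_question_counts <- c(
  balanced          = 7L,
  qi_deficiency     = 6L,
  yin_deficiency    = 6L,
  yang_deficiency   = 7L,
  phlegm_dampness   = 5L,
  damp_heat         = 6L,
  blood_stasis      = 7L,
  qi_stagnation     = 7L,
  inherited_special = 6L
)

# Display labels for tables and plots.
.ccmq_labels <- c(
  balanced          = "Balanced",
  qi_deficiency     = "Qi Deficiency",
  yin_deficiency    = "Yin Deficiency",
  yang_deficiency   = "Yang Deficiency",
  phlegm_dampness   = "Phlegm Dampness",
  damp_heat         = "Damp Heat",
  blood_stasis      = "Blood Stasis",
  qi_stagnation     = "Qi Stagnation",
  inherited_special = "Inherited Special"
)

# Tie-break priority for the primary classification when two candidates
# share the maximal score: descending overall prevalence in large
# community cohorts. The tie flag is always emitted so analysts can audit.
.ccmq_tie_priority <- c(
  "qi_deficiency", "phlegm_dampness", "yang_deficiency", "yin_deficiency",
  "damp_heat", "qi_stagnation", "inherited_special", "blood_stasis"
)

# ZZYXH/T157-2009 score thresholds on the 0-100 converted scale.
.ccmq_thresholds <- c(tendency = 30, constitution = 40, balanced = 60)

#' Constitution display labels
#'
#' @param keys Constitution keys as returned by [constitutions()].
#' @return Character vector of human-readable labels.
#' @examples
#' constitution_label("qi_deficiency")
#' @export
constitution_label <- function(keys) {
  unname(.ccmq_labels[keys])
}
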