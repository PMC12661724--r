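# Coexistence of unbalanced constitutions: the composite/tendency summary
# by primary constitution, the asymmetric 8x8 coexistence matrix behind the
# chord diagram, and its stratified variant. "Composite" always means >= 2
# constitutions at full threshold (score >= 40); tendencies are reported in
# their own column, never folded into the composite flag.

#' Composite-constitution summary by primary constitution
#'
#' For the unbalanced-constitution group, one row per primary constitution
#' plus an `all_unbalanced` totals row: how many respondents have that
#' primary, its prevalence in the full analytic cohort, and the
#' proportions (within the primary) who also have other constitutions
#' (composite) or one or more unbalanced tendencies.
#'
#' Percentages are unrounded; round at presentation (the conventional
#' table shows 1 decimal).
#'
#' @param cohort Classified analytic cohort (from [qc_cascade()], or any
#'   tibble with `group`, `primary`, `composite`, `has_tendency`).
#' @param denominator Denominator for the prevalence column; defaults to
#'   `nrow(cohort)`, the full analytic sample.
#' @return Tibble with columns `primary`, `n_primary`, `prevalence`,
#'   `n_with_composite`, `pct_with_composite`, `n_with_tendency`,
#'   `pct_with_tendency`.
#' @export
composite_summary <- function(cohort, denominator = nrow(cohort)) {
  unbal <- cohort[cohort$group == "unbalanced_constitution", , drop = FALSE]
  if (nrow(unbal) == 0) {
    warn("no respondents in the unbalanced-constitution group; all-zero table")
  }
  keys <- constitutions(unbalanced_only = TRUE)
  per <- purrr::map_dfr(keys, function(k) {
    sub <- unbal[unbal$primary == k, , drop = FALSE]
    tibble(
      primary = k,
      n_primary = nrow(sub),
      n_with_composite = sum(sub$composite),
      n_with_tendency = sum(sub$has_tendency)
    )
  })
  per <- arrange(per, dplyr::desc(.data$n_primary))
  total <- tibble(
    primary = "all_unbalanced",
    n_primary = nrow(unbal),
    n_with_composite = sum(unbal$composite),
    n_with_tendency = sum(unbal$has_tendency)
  )
  out <- bind_rows(total, per)
  mutate(
    out,
    prevalence = 100 * .data$n_primary / denominator,
    pct_with_composite = if_else(.data$n_primary > 0,
                                 100 * .data$n_with_composite / .data$n_primary, 0),
    pct_with_tendency = if_else(.data$n_primary > 0,
                                100 * .data$n_with_tendency / .data$n_primary, 0)
  ) %>%
    select("primary", "n_primary", "prevalence", "n_with_composite",
           "pct_with_composite", "n_with_tendency", "pct_with_tendency")
}

#' Coexistence matrix of unbalanced constitutions
#'
#' For each ordered pair (A, B) of distinct unbalanced constitutions,
#' the percentage of respondents with primary constitution A who also have
#' constitution B at full threshold (score >= 40). The matrix is
#' asymmetric because the two directions use different denominators
#' (primary-A vs primary-B respondents). Rows whose primary has zero
#' respondents are missing, not zero.
#'
#' @param cohort Classified analytic cohort.
#' @return A `ccmq_coexistence` tibble in long form: `primary`,
#'   `coexisting`, `n_primary`, `n_both`, `pct`. Use
#'   [coexistence_to_matrix()] for the 8x8 wide form and [export_chord()]
#'   for chord-diagram edges.
#' @export
coexistence_matrix <- function(cohort) {
  unbal <- cohort[cohort$group == "unbalanced_constitution", , drop = FALSE]
  keys <- constitutions(unbalanced_only = TRUE)
  grid <- tidyr::expand_grid(primary = keys, coexisting = keys) %>%
    filter(.data$primary != .data$coexisting)
  out <- purrr::pmap_dfr(grid, function(primary, coexisting) {
    sub <- unbal[unbal$primary == primary, , drop = FALSE]
    n_p <- nrow(sub)
    n_b <- sum(sub[[paste0("status_", coexisting)]] == "constitution")
    tibble(
      primary = primary, coexisting = coexisting,
      n_primary = n_p, n_both = n_b,
      pct = if (n_p > 0) 100 * n_b / n_p else NA_real_
    )
  })
  class(out) <- c("ccmq_coexistence", class(out))
  out
}

#' Widen a coexistence table to an 8x8 matrix
#'
#' @param coex Long coexistence tibble from [coexistence_matrix()].
#' @return Numeric 8x8 matrix, rows = primary constitution, columns =
#'   coexisting constitution, `NA` diagonal.
#' @export
coexistence_to_matrix <- function(coex) {
  keys <- constitutions(unbalanced_only = TRUE)
  m <- matrix(NA_real_, 8, 8, dimnames = list(keys, keys))
  m[cbind(coex$primary, coex$coexisting)] <- coex$pct
  m
}

#' Stratified coexistence analysis
#'
#' Computes one coexistence table per stratum level and compares the
#' composite-constitution proportion across strata with a chi-squared
#' independence test (among unbalanced-constitution respondents).
#'
#' @param cohort Classified analytic cohort.
#' @param stratum Name of a factor column, e.g. `"age_group_young"`.
#' @return A list with `matrices` (named list of `ccmq_coexistence`
#'   tibbles), `composite_by_stratum` (per-level n and composite
#'   percentage) and `composite_test` (a one-row test tibble).
#' @export
stratified_coexistence <- function(cohort, stratum = "age_group_young") {
  if (!stratum %in% names(cohort)) {
    abort(paste0("stratum column not found: ", stratum))
  }
  lv <- levels(factor(cohort[[stratum]]))
  matrices <- setNames(
    purrr::map(lv, ~ coexistence_matrix(cohort[!is.na(cohort[[stratum]]) &
                                                  cohort[[stratum]] == .x, ,
                                                drop = FALSE])),
    lv
  )
  unbal <- cohort[cohort$group == "unbalanced_constitution" &
                    !is.na(cohort[[stratum]]), , drop = FALSE]
  comp <- unbal %>%
    group_by(stratum_level = factor(.data[[stratum]])) %>%
    summarise(n_unbalanced = n(),
              n_composite = sum(.data$composite),
              pct_composite = 100 * mean(.data$composite),
              .groups = "drop")
  test <- chisq_independence(unbal, outcome = "composite", factor = stratum)
  list(matrices = matrices, composite_by_stratum = comp,
       composite_test = test)
}

#' Export chord-diagram edges
#'
#' Serializes a coexistence table as one row per unordered constitution
#' pair with both directed percentages and their maximum (chord colouring
#' conventionally uses the higher of the two). Pairs with no coexistence
#' in either direction are omitted.
#'
#' @param coex Long coexistence tibble from [coexistence_matrix()].
#' @param path Optional CSV output path.
#' @return Tibble with `source`, `target`, `pct_source_to_target`,
#'   `pct_target_to_source`, `max_pct`; written to `path` if given.
#' @export
export_chord <- function(coex, path = NULL) {
  keys <- constitutions(unbalanced_only = TRUE)
  pairs <- utils::combn(keys, 2)
  m <- coexistence_to_matrix(coex)
  edges <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tibble(
      source = a, target = b,
      pct_source_to_target = m[a, b],
      pct_target_to_source = m[b, a],
      max_pct = suppressWarnings(
        max(c(m[a, b], m[b, a]), na.rm = TRUE)
      )
    )
  })
  edges$max_pct[!is.finite(edges$max_pct)] <- NA_real_
  edges <- filter(edges, !is.na(.data$max_pct), .data$max_pct > 0)
  if (!is.null(path)) readr::write_csv(edges, path)
  edges
}

#' Heatmap of the coexistence matrix
#'
#' @param object A `ccmq_coexistence` tibble.
#' @param ... Unused.
#' @return A ggplot: primary constitution on the y axis, coexisting
#'   constitution on the x axis, tile fill = percentage coexisting.
#' @method autoplot ccmq_coexistence
#' @export
autoplot.ccmq_coexistence <- function(object, ...) {
  keys <- constitutions(unbalanced_only = TRUE)
  df <- mutate(
    as_tibble(object),
    primary = factor(constitution_label(.data$primary),
                     levels = constitution_label(rev(keys))),
    coexisting = factor(constitution_label(.data$coexisting),
                        levels = constitution_label(keys))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$coexisting, .data$primary,
                                   fill = .data$pct)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% coexisting", na.value = "grey90") +
    ggplot2::labs(x = "Coexisting constitution", y = "Primary constitution") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
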