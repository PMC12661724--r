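# Fixture builders used across the suite.

# A score tibble with every unbalanced score low and a balanced score of 50,
# overridden by ... (constitution = score pairs).
make_scores <- function(id = "p1", ...) {
  s <- tibble::tibble(participant_id = id, balanced = 50)
  for (k in constitutions(unbalanced_only = TRUE)) s[[k]] <- 10
  over <- list(...)
  for (k in names(over)) s[[k]] <- over[[k]]
  s
}

# A complete respondent row answering `value` everywhere, with overrides
# given as a named vector question_id -> response.
make_respondent <- function(id = "p1", value = 3L, overrides = NULL,
                            schema = ccmq_schema(), age = 45, sex = "female",
                            bmi = 22) {
  r <- tibble::tibble(participant_id = id, age = age, sex = sex, bmi = bmi)
  r[schema$question_id] <- as.list(rep(as.integer(value), 57))
  for (q in names(overrides)) r[[q]] <- as.integer(overrides[[q]])
  r
}

# A classified-cohort tibble built directly from group/primary counts, for
# table arithmetic. `primaries` is a named list: key -> c(n, n_composite,
# n_tendency).
make_classified_cohort <- function(n_balanced, n_tendency_only, primaries,
                                   n_no_class = 0) {
  rows <- list()
  add <- function(group, primary, composite, has_tendency, n) {
    if (n > 0) {
      rows[[length(rows) + 1]] <<- tibble::tibble(
        group = group, primary = primary,
        composite = composite, has_tendency = has_tendency,
        n = n
      )
    }
  }
  add("balanced", "balanced", FALSE, FALSE, n_balanced)
  add("tendency_only", "qi_deficiency", FALSE, TRUE, n_tendency_only)
  for (k in names(primaries)) {
    v <- primaries[[k]]  # c(n_primary, n_composite, n_tendency)
    n_both <- 0  # composite & tendency overlap: allocate maximally disjoint
    n_comp_only <- v[2]
    n_tend_only <- v[3]
    overlap <- max(0, v[2] + v[3] - v[1])
    n_comp_only <- v[2] - overlap
    n_tend_only <- v[3] - overlap
    add("unbalanced_constitution", k, TRUE, TRUE, overlap)
    add("unbalanced_constitution", k, TRUE, FALSE, n_comp_only)
    add("unbalanced_constitution", k, FALSE, TRUE, n_tend_only)
    add("unbalanced_constitution", k, FALSE, FALSE,
        v[1] - overlap - n_comp_only - n_tend_only)
  }
  add("no_classification", NA_character_, FALSE, FALSE, n_no_class)
  df <- dplyr::bind_rows(rows)
  out <- df[rep(seq_len(nrow(df)), df$n), setdiff(names(df), "n")]
  out$participant_id <- sprintf("c%05d", seq_len(nrow(out)))
  out$group <- factor(out$group, levels = c(
    "balanced", "unbalanced_constitution", "tendency_only", "no_classification"
  ))
  tibble::as_tibble(out)
}

# The printed-count cohort of the published cross-sectional analysis
# (N = 8,665): per-primary counts with composite / tendency counts.
printed_count_cohort <- function() {
  make_classified_cohort(
    n_balanced = 1931, n_tendency_only = 2234,
    primaries = list(
      qi_deficiency     = c(1425, 692, 927),
      phlegm_dampness   = c(957, 417, 595),
      yang_deficiency   = c(813, 505, 562),
      yin_deficiency    = c(527, 278, 381),
      damp_heat         = c(395, 231, 292),
      qi_stagnation     = c(216, 156, 166),
      inherited_special = c(98, 62, 64),
      blood_stasis      = c(69, 47, 51)
    )
  )
}

# Random score profiles drawn from a boundary-spanning lattice of values.
boundary_grid_profiles <- function(n, seed) {
  set.seed(seed)
  vals <- c(0, 29, 29.9, 30, 39, 39.9, 40, 59, 60, 100)
  keys <- constitutions()
  m <- matrix(sample(vals, n * 9, replace = TRUE), n, 9,
              dimnames = list(NULL, keys))
  dplyr::bind_cols(
    tibble::tibble(participant_id = sprintf("g%06d", seq_len(n))),
    tibble::as_tibble(m)
  )
}
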