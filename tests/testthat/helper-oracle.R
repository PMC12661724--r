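# Independent oracles, written directly from the rule statements and kept
# free of any package internals.

# Linear interpolation between (raw = N -> 0) and (raw = 5N -> 100).
oracle_convert <- function(raw, n) {
  stats::approx(x = c(n, 5 * n), y = c(0, 100), xout = raw)$y
}

# Brute-force rule interpreter over one named score vector:
#  rule 1: unbalanced score >= 40            -> that constitution
#  rule 2: unbalanced score in [30, 40)      -> tendency toward it
#  rule 3: balanced >= 60 and all eight < 30 -> balanced constitution
#  rule 4: balanced < 60 and all eight < 30  -> no classification
# Primary = highest-scoring member of the relevant candidate set; ties by
# the documented priority order.
oracle_classify <- function(scores) {
  priority <- c("qi_deficiency", "phlegm_dampness", "yang_deficiency",
                "yin_deficiency", "damp_heat", "qi_stagnation",
                "inherited_special", "blood_stasis")
  unbal <- setdiff(names(scores), "balanced")
  consts <- character(0)
  tends <- character(0)
  for (k in unbal) {
    if (scores[[k]] >= 40) {
      consts <- c(consts, k)
    } else if (scores[[k]] >= 30) {
      tends <- c(tends, k)
    }
  }
  pick <- function(cands) {
    best <- -Inf
    for (k in cands) best <- max(best, scores[[k]])
    top <- cands[vapply(cands, function(k) scores[[k]] == best, logical(1))]
    list(primary = top[order(match(top, priority))][1], tie = length(top) > 1)
  }
  if (length(consts) > 0) {
    p <- pick(consts)
    list(group = "unbalanced_constitution", primary = p$primary, tie = p$tie,
         constitutions = consts, tendencies = tends)
  } else if (scores[["balanced"]] >= 60 && length(tends) == 0) {
    list(group = "balanced", primary = "balanced", tie = FALSE,
         constitutions = character(0), tendencies = character(0))
  } else if (length(tends) > 0) {
    p <- pick(tends)
    list(group = "tendency_only", primary = p$primary, tie = p$tie,
         constitutions = character(0), tendencies = tends)
  } else {
    list(group = "no_classification", primary = NA_character_, tie = FALSE,
         constitutions = character(0), tendencies = character(0))
  }
}

# Score-regression formulation of the 1-df chi-squared trend statistic:
# T = [sum_i s_i (r_i - n_i R/N)]^2 / [p(1-p) (sum_i s_i^2 n_i - (sum_i s_i n_i)^2 / N)]
oracle_trend_stat <- function(events, trials, scores = seq_along(events)) {
  R <- sum(events); N <- sum(trials); p <- R / N
  num <- sum(scores * (events - trials * p))^2
  den <- p * (1 - p) * (sum(scores^2 * trials) - sum(scores * trials)^2 / N)
  num / den
}
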