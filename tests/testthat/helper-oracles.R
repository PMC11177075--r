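# Independent oracles and record builders shared across tests.

# O(n^2) pairwise AUROC: fraction of (positive, negative) pairs ranked
# correctly, with half-credit for ties. Deliberately brute-force.
brute_force_auroc <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg, function(p, q) {
    (p > q) + 0.5 * (p == q)
  })
  mean(cmp)
}

# Clopper-Pearson interval by bisection on the binomial tail
# probabilities, independent of the beta-quantile implementation.
cp_ci_bisect <- function(k, n, level = 0.95) {
  alpha <- 1 - level
  low <- if (k == 0) 0 else {
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  high <- if (k == n) 1 else {
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  }
  c(low, high)
}

# A single eligible-by-default Utstein-style record, overridable field
# by field to construct targeted fixtures.
make_record <- function(record_id = "r1", age = 60L, cause = "internal",
                        witnessed = TRUE, no_flow_time = 3,
                        first_rhythm = "asystole", pad_performed = FALSE,
                        prehospital_rosc = FALSE,
                        resuscitation_attempted = TRUE, region = "other",
                        year = 2008L, cpc = 5L) {
  tibble::tibble(
    record_id = record_id, age = age, cause = cause, witnessed = witnessed,
    no_flow_time = no_flow_time, first_rhythm = first_rhythm,
    pad_performed = pad_performed, prehospital_rosc = prehospital_rosc,
    resuscitation_attempted = resuscitation_attempted, region = region,
    year = year, cpc = cpc
  )
}

# Random non-degenerate stratum table (both classes occupied).
random_stratum_table <- function(max_n = 60) {
  repeat {
    n <- sample(0:max_n, 4, replace = TRUE)
    pos <- vapply(n, function(m) if (m == 0) 0L else sample(0:m, 1),
                  integer(1))
    if (sum(pos) > 0 && sum(n) - sum(pos) > 0) {
      return(stratum_table(n, pos))
    }
  }
}

# Per-score expansion of a stratum table into scores of each class.
table_scores <- function(tab) {
  st <- tab$strata
  list(pos = rep(st$score, st$pos),
       neg = rep(st$score, st$n - st$pos))
}
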