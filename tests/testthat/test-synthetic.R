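test_that("configuration validation rejects infeasible inputs before sampling", {
  ok <- function(...) synthetic_config(100, c(0.5, 0.3, 0.15, 0.05),
                                       p_cpc12 = c(0.01, 0.02, 0.05, 0.1), ...)
  expect_s3_class(ok(), "synthetic_config")
  expect_error(synthetic_config(100, c(0.5, 0.5, 0.5, 0.5),
                                p_cpc12 = rep(0.1, 4)), "summing to 1")
  expect_error(ok(p_cpc34 = c(0.99, 0.99, 0.99, 0.99)), "p_cpc12 \\+ p_cpc34")
  expect_error(ok(contamination = list(kanto = -0.1)), "contamination")
  expect_error(ok(contamination = list(bad_type = 0.1)), "unknown contamination")
  expect_error(ok(years = 2010:2011), "guideline analysis period")
  expect_error(ok(component_style = list(one_weights = c(0, 0, 0))),
               "one_weights")
  expect_error(ok(component_style = list(witnessed_rate_b0 = 1.4)),
               "probabilities")
})

test_that("generation is reproducible from the seed and ids embed it", {
  cfg <- synthetic_config_group("g2005", n_records = 300)
  a <- generate_cohort(cfg, seed = 5)
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a, b)
  c_ <- generate_cohort(cfg, seed = 6)
  expect_false(any(a$record_id %in% c_$record_id))

  empty <- generate_cohort(synthetic_config_group("g2005", n_records = 0))
  expect_equal(nrow(empty), 0)
})

test_that("records realize their drawn stratum: score equals the intended pattern", {
  cfg <- synthetic_config_group(
    "g2010", n_records = 3000,
    contamination = list(external_cause = 0.05, prehospital_rosc = 0.05))
  coh <- generate_cohort(cfg, seed = 13)
  eligible <- apply_selection_filters(coh)
  scored <- compute_abc_score(eligible)
  expect_true(all(scored$abc_total %in% 0:3))
  # bystander-positive records are witnessed with no-flow <= 5
  expect_true(all(scored$witnessed[scored$b == 1]))
  expect_true(all(scored$no_flow_time[scored$b == 1] <= 5))
  # cardiogram points come from VT/VF or PAD only
  expect_true(all(scored$first_rhythm[scored$c == 1] %in% c("VT", "VF") |
                    scored$pad_performed[scored$c == 1]))
  # years stay inside the configured guideline period
  expect_true(all(eligible$year %in% 2012:2014))
})

test_that("the selection funnel tallies match the generator's bookkeeping exactly", {
  rates <- list(under_18 = 0.03, external_cause = 0.06,
                missing_fields = 0.04, prehospital_rosc = 0.05,
                kanto = 0.03, transition_year = 0.02)
  cfg <- synthetic_config_group("g2005", n_records = 8000,
                                contamination = rates)
  coh <- generate_cohort(cfg, seed = 17)
  log <- exclusion_log(apply_selection_filters(coh))
  fate <- table(coh$intended_fate)
  mapping <- c(under_18 = "not_attempted_or_under_18",
               external_cause = "external_cause",
               missing_fields = "score_not_computable",
               prehospital_rosc = "prehospital_rosc",
               kanto = "kanto_region",
               transition_year = "transition_year")
  for (f in names(mapping)) {
    expect_equal(log$n_excluded[log$step == mapping[[f]]],
                 unname(fate[f]), ignore_attr = TRUE, label = f)
  }
  expect_equal(attr(log, "n_retained"), unname(fate["eligible"]),
               ignore_attr = TRUE)
  # realized eligible fraction is binomially consistent with 1 - sum(rates)
  p_elig <- 1 - sum(unlist(rates))
  bounds <- qbinom(c(0.005, 0.995), 8000, p_elig)
  expect_gte(unname(fate["eligible"]), bounds[1])
  expect_lte(unname(fate["eligible"]), bounds[2])
})

test_that("per-score outcome rates are recovered within 99% binomial bounds at n = 1e5", {
  cfg <- synthetic_config_group("g2005", n_records = 1e5)
  coh <- generate_cohort(cfg, seed = 1)
  tab <- build_stratum_table(compute_abc_score(apply_selection_filters(coh)))
  for (s in 0:3) {
    n_s <- tab$strata$n[s + 1]
    k_s <- tab$strata$pos[s + 1]
    bounds <- qbinom(c(0.005, 0.995), n_s, cfg$p_cpc12[s + 1])
    expect_gte(k_s, bounds[1])
    expect_lte(k_s, bounds[2])
  }
})

test_that("the empirical score distribution converges to the configured one", {
  cfg <- synthetic_config_group("g2015")
  kolmogorov <- vapply(c(1e3, 1e4, 1e5), function(n) {
    coh <- generate_cohort(synthetic_config_group("g2015", n_records = n),
                           seed = 1)
    scored <- compute_abc_score(apply_selection_filters(coh))
    emp_cdf <- cumsum(tabulate(scored$abc_total + 1L, 4L)) / nrow(scored)
    max(abs(emp_cdf - cumsum(cfg$score_distribution)))
  }, numeric(1))
  # 99% Kolmogorov band at each size, and decay across two decades
  expect_true(all(kolmogorov <= 1.63 / sqrt(c(1e3, 1e4, 1e5))))
  expect_lt(kolmogorov[3], kolmogorov[1])
})

test_that("the closed-form AUROC oracle matches degenerate cases and Monte Carlo", {
  flat <- synthetic_config(10, rep(0.25, 4), p_cpc12 = rep(0.3, 4))
  expect_equal(expected_auroc(flat), 0.5)
  split <- synthetic_config(10, c(0.5, 0, 0, 0.5), p_cpc12 = c(0, 0, 0, 1))
  expect_equal(expected_auroc(split), 1)
  expect_error(expected_auroc(synthetic_config(10, rep(0.25, 4),
                                               p_cpc12 = rep(0, 4))),
               "zero expected favourable")

  cfg <- synthetic_config_group("g2005", n_records = 1e6)
  coh <- generate_cohort(cfg, seed = 1)
  tab <- build_stratum_table(compute_abc_score(apply_selection_filters(coh)))
  expect_equal(roc_from_strata(tab)$auroc, expected_auroc(cfg),
               tolerance = 0.005 / expected_auroc(cfg))
})

test_that("configurations survive a YAML round trip", {
  cfg <- synthetic_config_group("g2010", n_records = 123, seed = 99)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_synthetic_config(cfg, f)
  back <- read_synthetic_config(f)
  expect_equal(back$score_distribution, cfg$score_distribution)
  expect_equal(back$p_cpc12, cfg$p_cpc12)
  expect_equal(back$component_style, cfg$component_style)
  expect_equal(back$n_records, 123L)
  expect_equal(back$seed, 99L)
})
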