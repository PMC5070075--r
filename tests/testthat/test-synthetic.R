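test_that("count distributions are calibrated to their target means", {
  d <- count_dist(3.2, 1.8, 1, 9)
  expect_equal(sum(d$support * d$prob), 3.2, tolerance = 1e-8)
  d2 <- count_dist(7.9, 2.9, 3, 17)
  expect_equal(sum(d2$support * d2$prob), 7.9, tolerance = 1e-8)

  # degenerate spec always returns its point
  dd <- count_dist(3, 0, 3, 3)
  expect_identical(sample_count(dd, 5), rep(3L, 5L))

  # infeasible specs are config errors
  expect_error(count_dist(0.5, 1, 1, 9), "outside bounds")
  expect_error(count_dist(3, 1, 9, 1), "out of order")

  # large-sample mean recovery within 2% of the target
  set.seed(61)
  draws <- sample_count(d, 1e5)
  expect_lt(abs(mean(draws) - 3.2) / 3.2, 0.02)
  expect_true(all(draws >= 1 & draws <= 9))
})

test_that("endpoint distributions carry their point mass and mean", {
  ft <- endpoint_dist(3.56, 0.71, 1, 4, mass_at = 4, mass_p = 0.67)
  expect_equal(ft$prob[ft$support == 4], 0.67 +
                 (1 - 0.67) * 0)  # remainder excludes the mass point
  expect_equal(sum(ft$support * ft$prob), 3.56, tolerance = 1e-8)
  et <- endpoint_dist(-2.5, 2.08, -4, 2, mass_at = -4, mass_p = 0.54)
  expect_equal(et$prob[et$support == -4], 0.54)
  expect_equal(sum(et$support * et$prob), -2.5, tolerance = 1e-8)
  # a mass that makes the mean unreachable is rejected
  expect_error(endpoint_dist(3.9, 0.5, 1, 4, mass_at = 4, mass_p = 0.5),
               "incompatible")
})

test_that("conditioned draws respect their bounds", {
  d <- count_dist(1.76, 0.81, -2, 3)
  set.seed(62)
  expect_true(all(sample_count(d, 200, upper = 0) <= 0))
  expect_true(all(sample_count(d, 200, lower = 2) >= 2))
  # empty restriction clamps to the nearest feasible point
  expect_identical(sample_count(d, 3, upper = -5), rep(-2L, 3L))
})

test_that("every generated case is valid and three-phase conforming", {
  cfg <- generator_config(n_cases = 1, seed = 63)
  for (i in 1:60) {
    set.seed(1000 + i)
    x <- generate_case(cfg)
    expect_true(is_valid(validate_dpm(x)))
    expect_true(segment(x)$conforming)
  }
})

test_that("generated trajectories are monotone towards the outcome", {
  cfg <- generator_config(n_cases = 1, seed = 64)
  for (i in 1:30) {
    set.seed(2000 + i)
    x <- generate_case(cfg)
    oo <- option_outcomes(x)
    for (j in seq_len(nrow(oo))) {
      lv <- trajectory(x, oo$option_id[j])$level
      if (oo$outcome[j] == "FINAL") expect_true(all(diff(lv) >= 0))
      if (oo$outcome[j] == "EXCLUDED") expect_true(all(diff(lv) <= 0))
    }
    # exactly one final diagnosis per generated case
    expect_identical(sum(oo$outcome == "FINAL"), 1L)
  }
})

test_that("generation is deterministic and order-independent", {
  cfg <- generator_config(n_cases = 6, seed = 65)
  set.seed(99); a <- generate_case(cfg)
  set.seed(99); b <- generate_case(cfg)
  expect_identical(a, b)

  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_identical(coh1$cases, coh2$cases)

  # per-case substreams: case i is the same regardless of cohort size
  # (before the cohort-level covariate pass, which depends on all cases)
  cfg3 <- generator_config(n_cases = 3, seed = 65)
  coh3 <- generate_cohort(cfg3)
  strip_cov <- function(x) {
    x$metadata$experience_months <- NA_integer_
    x$metadata$similarity <- NA_integer_
    x
  }
  expect_identical(lapply(coh3$cases, strip_cov),
                   lapply(coh1$cases[1:3], strip_cov))
})

test_that("an empty cohort is permitted", {
  coh <- generate_cohort(generator_config(n_cases = 0, seed = 66))
  expect_identical(length(coh$cases), 0L)
  expect_identical(coh$provenance$n_cases, 0L)
})

test_that("infeasible joint probabilities are config errors", {
  expect_error(generator_config(p_final_in_phase1 = 0.01),
               "infeasible")
  expect_error(generator_config(p_phase2_addition = 0.001),
               "infeasible")
})

test_that("cohort moments approach the configured values (n = 1200)", {
  cfg <- generator_config(n_cases = 1200, seed = 67)
  cs <- case_summaries(generate_cohort(cfg))
  s <- cohort_summary(cs)
  m <- function(metric) s$metrics$mean[s$metrics$metric == metric]
  se3 <- function(sd) 3 * sd / sqrt(nrow(cs))
  expect_lt(abs(m("n_options") - 3.2), se3(1.8))
  expect_lt(abs(m("n_cues") - 7.9), se3(2.9))
  expect_lt(abs(s$proportions[["final_in_phase1"]] - 0.87),
            3 * sqrt(0.87 * 0.13 / nrow(cs)))
  expect_lt(abs(s$proportions[["phase2_additions"]] - 0.45),
            3 * sqrt(0.45 * 0.55 / nrow(cs)))
  # rank matching hits the experience ~ verification-cues correlation
  expect_lt(abs(cor(cs$experience_months, cs$phase2_cues) + 0.35), 0.05)
  # and similarity ~ final confidence on the rank scale
  sel <- cs$case_experience == "yes"
  fconf <- cs$final_terminal_sum[sel] / pmax(cs$n_final_rated[sel], 1)
  expect_lt(abs(cor(cs$similarity[sel], fconf, method = "spearman") - 0.31),
            0.05)
  # experience marginal is untouched by the reordering
  expect_true(all(cs$experience_months >= 23 & cs$experience_months <= 69))
})
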