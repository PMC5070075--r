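test_that("fig1 case summary reflects the worked example", {
  f <- fig1_case()
  s <- case_summary(f)
  expect_identical(s$n_options, 3L)
  expect_identical(s$n_cues, 18L)
  expect_true(s$final_in_phase1)
  expect_identical(s$n_final, 1L)
  expect_identical(s$n_excluded, 2L)
  # "Viral Gastroenteritis" started at quite probable (+2)
  vg <- f$options$option_id[f$options$text == "Viral Gastroenteritis"]
  expect_identical(initial_confidence(f, vg), 2L)
  # and the % final-in-phase1 of a fig1-only cohort is 1
  cs <- cohort_summary(s)
  expect_identical(cs$proportions[["final_in_phase1"]], 1)
})

test_that("confidence trajectories move towards the option's fate", {
  f <- fig1_case()
  vg <- f$options$option_id[f$options$text == "Viral Gastroenteritis"]
  lung <- f$options$option_id[f$options$text == "Lung infection"]
  expect_gt(net_change(f, vg), 0)
  expect_lt(net_change(f, lung), 0)
  expect_identical(net_change(minimal_case(), "o1"), 0L)
  tr <- trajectory(f, vg)
  expect_true(all(diff(tr$order_index) > 0))
})

test_that("cohort summary does hand arithmetic correctly", {
  set.seed(41)
  cfg <- generator_config(n_cases = 2, seed = 41)
  # force two comparable summaries by editing the metric column directly
  cs <- case_summaries(generate_cohort(cfg))
  cs$n_options <- c(2L, 4L)
  s <- cohort_summary(cs)
  m <- s$metrics[s$metrics$metric == "n_options", ]
  expect_equal(m$mean, 3)
  expect_equal(m$sd, sqrt(2))
  expect_identical(c(m$min, m$max), c(2L, 4L))

  # identical cases -> SD 0 everywhere
  s2 <- cohort_summary(rbind(cs[1, ], cs[1, ]))
  expect_true(all(s2$metrics$sd == 0))

  # proportions are invariant to case order
  s3 <- cohort_summary(cs[2:1, ])
  expect_identical(s3$proportions, s$proportions)

  expect_error(cohort_summary(cs[0, ]), "at least one case")
})

test_that("added-option means are reported under both readings", {
  set.seed(42)
  cfg <- generator_config(n_cases = 40, seed = 42)
  cs <- case_summaries(generate_cohort(cfg))
  s <- cohort_summary(cs)
  all_mean <- s$confidence[["added_options_mean_all"]]
  cond_mean <- s$confidence[["added_options_mean_conditional"]]
  expect_equal(all_mean, mean(cs$phase2_options_added))
  expect_gte(cond_mean, 1)  # conditional on >= 1 addition
  expect_gte(cond_mean, all_mean)
})

test_that("group comparison returns means, SDs and Cohen's d", {
  set.seed(43)
  cfg <- generator_config(n_cases = 30, seed = 43)
  cs <- case_summaries(generate_cohort(cfg))

  # identical groups -> d = 0
  half <- nrow(cs) %/% 2
  cs$time_pressure <- rep(c("yes", "no"), length.out = nrow(cs))
  cs$n_cues <- rep(cs$n_cues[seq_len(half)], length.out = nrow(cs))
  cs$n_cues[cs$time_pressure == "no"] <- cs$n_cues[cs$time_pressure == "yes"]
  g <- compare_groups(cs, "time_pressure", metrics = "n_cues")
  expect_equal(g$d, 0)

  # constructed groups with means 1 and 2, common SD 1 -> d = 1
  es <- cohens_d(2, 1, 10, 1, 1, 10)
  expect_equal(es$d, 1)

  # unknown-flag cases are dropped
  cs$stress <- c("unknown", rep(c("yes", "no"), length.out = nrow(cs) - 1))
  g2 <- compare_groups(cs, "stress", metrics = "n_options")
  expect_identical(g2$n_yes + g2$n_no, nrow(cs) - 1L)
})

test_that("summary export writes readable CSV", {
  set.seed(44)
  cfg <- generator_config(n_cases = 3, seed = 44)
  cs <- case_summaries(generate_cohort(cfg))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_summary_csv(cohort_summary(cs), tmp)
  tab <- read.csv(tmp)
  expect_true("n_options" %in% tab$metric)
  expect_true("prop_final_in_phase1" %in% tab$metric)
})
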