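test_that("concordance rate is the proportion of agreeing diagnoses", {
  p <- rater_pairs(letters[1:3], c(4, 3, 2), c(4, 3, 2), c(TRUE, TRUE, TRUE))
  expect_equal(concordance_rate(p), 1)
  p$concordant <- c(FALSE, FALSE, FALSE)
  expect_equal(concordance_rate(p), 0)
  # 51 agreeing cases out of 55
  p55 <- rater_pairs(sprintf("c%02d", 1:55), rep(4, 55), rep(3, 55),
                     c(rep(TRUE, 51), rep(FALSE, 4)))
  expect_equal(round(concordance_rate(p55), 3), 0.927)
  expect_error(concordance_rate(p55[0, ]), "at least one")
})

test_that("confidence agreement enumerates matches and discrepancies", {
  # hand enumeration: (resident, expert) = (4,3), (4,4), (2,4)
  p <- rater_pairs(c("a", "b", "c"),
                   resident_level = c(4, 4, 2),
                   expert_level = c(3, 4, 4),
                   concordant = TRUE)
  agg <- confidence_agreement(p)
  expect_equal(agg[["perfect_match_pct"]], 100 / 3)
  expect_equal(agg[["within_one_pct"]], 100 / 3)
  expect_equal(agg[["larger_pct"]], 100 / 3)
  expect_equal(agg[["max_discrepancy"]], 2)
  expect_equal(agg[["expert_underconfident_pct"]], 100 / 3)
  expect_equal(agg[["expert_overconfident_pct"]], 100 / 3)

  # identical rating lists match perfectly
  q <- rater_pairs("x", 3, 3, TRUE)
  aq <- confidence_agreement(q)
  expect_equal(aq[["perfect_match_pct"]], 100)
  expect_equal(aq[["max_discrepancy"]], 0)

  # a two-step gap is not "within one"
  r <- rater_pairs("y", 4, 2, TRUE)
  expect_equal(confidence_agreement(r)[["within_one_pct"]], 0)
})

test_that("agreement percentages always partition the cases", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(3:40, 1)
    p <- rater_pairs(seq_len(n), sample(-4:4, n, TRUE), sample(-4:4, n, TRUE),
                     TRUE)
    agg <- confidence_agreement(p)
    expect_equal(agg[["perfect_match_pct"]] + agg[["within_one_pct"]] +
                   agg[["larger_pct"]], 100)
  }
})

test_that("Cohen's d from pooled SD reproduces textbook cases", {
  # group summaries with n = 51 per group give a medium effect
  es <- cohens_d(3.5, 0.7, 51, 3.1, 0.8, 51)
  expect_equal(round(es$d, 2), 0.53)
  expect_true(es$ci_low <= es$d && es$d <= es$ci_high)

  expect_equal(cohens_d(2, 1, 10, 2, 1, 10)$d, 0)
  expect_equal(cohens_d(1, 1, 10, 0, 1, 10)$d, 1)
  expect_error(cohens_d(1, 0, 10, 0, 0, 10), "zero pooled SD")
  expect_equal(cohens_d(1, 0, 10, 1, 0, 10)$d, 0)
})

test_that("Cohen's d is antisymmetric in its two groups", {
  set.seed(52)
  for (i in 1:20) {
    m <- runif(2, -5, 5); s <- runif(2, 0.2, 3); n <- sample(5:50, 2, TRUE)
    a <- cohens_d(m[1], s[1], n[1], m[2], s[2], n[2])
    b <- cohens_d(m[2], s[2], n[2], m[1], s[1], n[1])
    expect_equal(a$d, -b$d)
  }
  # and the data interface agrees with the summary interface
  x <- rnorm(20, 1); y <- rnorm(25)
  expect_equal(cohens_d_data(x, y)$d,
               cohens_d(mean(x), sd(x), 20, mean(y), sd(y), 25)$d)
})

test_that("Pearson test reproduces the t transformation and cor.test", {
  res <- pearson_test(r = -0.35, n = 55)
  expect_equal(round(res$p, 3), 0.009)
  expect_equal(pearson_test(r = 0, n = 30)$p, 1)
  expect_warning(out <- pearson_test(r = 1, n = 10), "degenerates")
  expect_equal(out$p, 0)

  # raw-data overload agrees with the standard test
  set.seed(53)
  x <- rnorm(20); y <- x + rnorm(20)
  mine <- pearson_test(x = x, y = y)
  ref <- cor.test(x, y)
  expect_equal(mine$coefficient, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value)
})

test_that("p-values fall with |r| and with n", {
  ps_r <- vapply(seq(0.1, 0.9, by = 0.1),
                 function(r) pearson_test(r = r, n = 20)$p, numeric(1))
  expect_true(all(diff(ps_r) < 0))
  ps_n <- vapply(c(5, 10, 20, 40, 80),
                 function(n) pearson_test(r = 0.3, n = n)$p, numeric(1))
  expect_true(all(diff(ps_n) < 0))
})

test_that("correlation p-values agree with exhaustive permutation nulls", {
  # frozen oracle values from full enumeration (8! and 7! permutations)
  x8 <- c(1.2, 3.4, 2.2, 5.0, 4.1, 6.3, 5.5, 7.8)
  y8 <- c(2.0, 1.5, 3.8, 3.2, 6.0, 4.9, 7.1, 6.4)
  expect_equal(perm_test_p(x8, y8, "pearson"), 0.0656994, tolerance = 1e-6)
  expect_lt(abs(pearson_test(x = x8, y = y8)$p - 0.0656994), 0.05)

  x7 <- c(10, 25, 17, 30, 22, 41, 35)
  y7 <- c(3, 1, 4, 2, 6, 5, 7)
  expect_equal(perm_test_p(x7, y7, "spearman"), 0.5559524, tolerance = 1e-6)
  expect_lt(abs(spearman_test(x7, y7)$p - 0.5559524), 0.05)
})

test_that("Spearman coefficient handles monotone, reversed and tied data", {
  x <- c(1, 2, 3, 4, 5)
  expect_warning(up <- spearman_test(x, x^3), "degenerates")
  expect_equal(up$coefficient, 1)
  expect_warning(dn <- spearman_test(x, -x), "degenerates")
  expect_equal(dn$coefficient, -1)
  expect_error(spearman_test(x, rep(2, 5)), "constant")
  # mid-ranks for ties agree with cor(..., method = "spearman")
  y <- c(2, 2, 3, 1, 3)
  expect_equal(spearman_test(x, y)$coefficient,
               cor(x, y, method = "spearman"))
})

test_that("rater pairs round-trip through their CSV interface", {
  p <- rater_pairs(c("a", "b"), c(4, 2), c(3, 2), c(TRUE, FALSE))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write.csv(data.frame(case_id = p$case_id,
                       resident_level = p$resident_level,
                       expert_level = p$expert_level,
                       concordant = ifelse(p$concordant, "true", "false")),
            tmp, row.names = FALSE)
  q <- read_rater_pairs(tmp)
  expect_equal(q$resident_level, p$resident_level)
  expect_equal(q$concordant, p$concordant)
  expect_error(rater_pairs("a", 5, 0, TRUE), "9-point")
})

test_that("simulated expert re-ratings have the configured structure", {
  set.seed(54)
  coh <- generate_cohort(generator_config(n_cases = 120, seed = 54))
  pairs <- generate_rater_pairs(coh)
  expect_identical(nrow(pairs), 120L)
  expect_true(all(abs(pairs$expert_level) <= 4))
  agg <- confidence_agreement(pairs)
  # under- should clearly dominate over-confidence under the default mix
  expect_gt(agg[["expert_underconfident_pct"]],
            agg[["expert_overconfident_pct"]])
})
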