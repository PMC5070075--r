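test_that("confidence scale is a bijection with fixed verbal anchors", {
  labs <- confidence_labels()
  expect_length(labs, 9L)
  expect_identical(label_for(4), "practically certain")
  expect_identical(label_for(0), "possible")
  expect_identical(label_for(-4), "practically impossible")
  for (v in -4:4) expect_identical(level_for(label_for(v)), v)
  expect_error(label_for(5), "integer in")
  expect_error(label_for(1.5), "integer in")
  expect_error(level_for("certainly"), "unknown confidence label")
})

test_that("the packaged worked example validates cleanly with 46 units", {
  rep <- validate_dpm(fig1_case())
  expect_true(is_valid(rep))
  expect_identical(rep$n_units, 46L)
  expect_identical(nrow(rep$warnings), 0L)
})

test_that("the minimal four-unit case is valid and counted correctly", {
  x <- minimal_case()
  expect_true(is_valid(validate_dpm(x)))
  expect_identical(unit_counts(x),
                   c(CUE = 1L, OPTION = 1L, CONFIDENCE = 1L, FINAL = 1L,
                     total = 4L))
})

test_that("validator reports constructed structural violations as data", {
  x <- minimal_case()

  dup <- x$units
  dup$order_index[1] <- 3L  # duplicate index 3, gap at 1
  rep <- validate_dpm(dpm(dup, x$cues, x$options, x$metadata))
  expect_false(is_valid(rep))
  expect_true("numbering not consecutive" %in% rep$violations$rule)

  no_final <- x$units[x$units$kind != "FINAL", ]
  rep <- validate_dpm(dpm(no_final, x$cues, x$options, x$metadata))
  expect_false(is_valid(rep))
  expect_true("final count" %in% rep$violations$rule)

  # swapping OPTION and its CONFIDENCE creates a forward reference
  rep <- validate_dpm(swap_indices(x, 2L, 3L))
  expect_false(is_valid(rep))
  expect_true("forward reference" %in% rep$violations$rule)

  # swapping FINAL away from the last slot
  rep <- validate_dpm(swap_indices(x, 3L, 4L))
  expect_false(is_valid(rep))
  expect_true("final not last" %in% rep$violations$rule)

  expect_error(validate_dpm(list(units = 1)), "not a dpm")
})

test_that("metadata constraints: similarity requires case experience", {
  x <- minimal_case()
  md <- x$metadata
  md$similarity <- 3L  # but case_experience is "unknown"
  rep <- validate_dpm(dpm(x$units, x$cues, x$options, md))
  expect_false(is_valid(rep))
  expect_true("metadata" %in% rep$violations$rule)
})

test_that("unit counts conserve: total = cues + options + ratings + 1", {
  set.seed(11)
  cfg <- generator_config(n_cases = 1, seed = 11)
  for (i in 1:20) {
    x <- generate_case(cfg)
    k <- unit_counts(x)
    expect_identical(k[["total"]],
                     k[["CUE"]] + k[["OPTION"]] + k[["CONFIDENCE"]] + 1L)
    expect_identical(k[["total"]], max(x$units$order_index))
  }
})

test_that("terminal and initial confidence pick the right rating", {
  f <- fig1_case()
  # "Lung infection" ends with the exclusion rating at unit 45
  lung <- f$options$option_id[f$options$text == "Lung infection"]
  tr <- trajectory(f, lung)
  expect_identical(tr$order_index[nrow(tr)], 45L)
  expect_identical(terminal_confidence(f, lung), tr$level[nrow(tr)])
  expect_true(tr$is_exclusion[nrow(tr)])

  x <- minimal_case()
  expect_identical(terminal_confidence(x, "o1"), 1L)
  expect_identical(initial_confidence(x, "o1"), 1L)
  expect_error(terminal_confidence(x, "nope"), "unknown option_id")

  # never-rated option
  u <- rbind(x$units[x$units$order_index < 4, ],
             unit_row(4, "OPTION", "o2"),
             unit_row(5, "FINAL", oref = "o1"))
  opts <- rbind(x$options, data.frame(option_id = "o2", text = "extra"))
  y <- dpm(u, x$cues, opts, x$metadata)
  expect_identical(terminal_confidence(y, "o2"), NA_integer_)
  expect_identical(classify_outcome(y, "o2"), "UNDETERMINED")
  # unrated options warn, never fail validation
  rep <- validate_dpm(y)
  expect_true(is_valid(rep))
  expect_true("unrated option" %in% rep$warnings$rule)
})

test_that("outcome classification partitions the options of a case", {
  f <- fig1_case()
  oo <- option_outcomes(f)
  expect_identical(oo$outcome[oo$text == "Viral Gastroenteritis"], "FINAL")
  expect_identical(oo$outcome[oo$text == "Vascular problem"], "EXCLUDED")
  expect_identical(oo$outcome[oo$text == "Lung infection"], "EXCLUDED")
  expect_true(all(oo$outcome %in% c("FINAL", "EXCLUDED", "UNDETERMINED")))

  # an option both final and exclusion-flagged is inconsistent
  x <- minimal_case()
  u <- x$units
  u$is_exclusion[u$kind == "CONFIDENCE"] <- TRUE
  bad <- dpm(u, x$cues, x$options, x$metadata)
  expect_error(classify_outcome(bad, "o1"), "both")
  expect_false(is_valid(validate_dpm(bad)))
})
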