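#' Summarise one case
#'
#' Reduces a case to the metrics used in cohort-level description: unit
#' and phase composition counts, option outcomes with their initial and
#' terminal confidence ratings, whether the final diagnosis emerged during
#' option generation, and the contextual metadata. Sums (rather than
#' per-case means) of the confidence endpoints are kept so that cohorts
#' can pool over options, not cases.
#'
#' @param x A valid `dpm`.
#' @return A one-row tibble with columns including `n_units`, `n_cues`,
#'   `n_options`, `n_confidence`, the six [phase_composition()] counts,
#'   `conforming`, `final_in_phase1`, `n_final`, `n_excluded`,
#'   `n_undetermined`, `final_terminal_sum`, `final_top` (finals rated
#'   +4), `excluded_terminal_sum`, `excluded_bottom` (exclusions rated
#'   -4), `initial_sum`/`n_initial` (phase-1 options with a rating) and
#'   the metadata fields.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' s <- case_summary(fig1)
#' s$n_options          # 3
#' s$final_in_phase1    # TRUE
#' @export
case_summary <- function(x) {
  part <- segment(x)  # validates
  comp <- phase_composition(x, part)
  counts <- unit_counts(x)
  oo <- option_outcomes(x)

  u <- x$units
  opt_intro <- stats::setNames(u$order_index[u$kind == "OPTION"],
                               u$ref_id[u$kind == "OPTION"])
  fin_ids <- final_option_ids(x)
  final_in_phase1 <- length(fin_ids) > 0L &&
    any(opt_intro[fin_ids] <= part$phase1_end)

  fin <- oo[oo$outcome == "FINAL", , drop = FALSE]
  exc <- oo[oo$outcome == "EXCLUDED", , drop = FALSE]
  p1_opts <- names(opt_intro)[opt_intro <= part$phase1_end]
  init_p1 <- oo$initial[oo$option_id %in% p1_opts & !is.na(oo$initial)]

  md <- x$metadata
  tibble::tibble(
    case_id = md$case_id,
    n_units = counts[["total"]],
    n_cues = counts[["CUE"]],
    n_options = counts[["OPTION"]],
    n_confidence = counts[["CONFIDENCE"]],
    phase1_cues = comp[["phase1_cues"]],
    phase1_options = comp[["phase1_options"]],
    phase1_confidence = comp[["phase1_confidence"]],
    phase2_cues = comp[["phase2_cues"]],
    phase2_options_added = comp[["phase2_options_added"]],
    phase2_confidence = comp[["phase2_confidence"]],
    conforming = part$conforming,
    final_in_phase1 = final_in_phase1,
    n_final = nrow(fin),
    n_excluded = nrow(exc),
    n_undetermined = sum(oo$outcome == "UNDETERMINED"),
    final_terminal_sum = sum(fin$terminal, na.rm = TRUE),
    n_final_rated = sum(!is.na(fin$terminal)),
    final_top = sum(fin$terminal == 4L, na.rm = TRUE),
    excluded_terminal_sum = sum(exc$terminal, na.rm = TRUE),
    n_excluded_rated = sum(!is.na(exc$terminal)),
    excluded_bottom = sum(exc$terminal == -4L, na.rm = TRUE),
    initial_sum = sum(init_p1),
    n_initial = length(init_p1),
    time_pressure = md$time_pressure,
    stress = md$stress,
    case_experience = md$case_experience,
    similarity = md$similarity,
    experience_months = md$experience_months
  )
}

#' Summarise many cases at once
#'
#' @param cases A list of `dpm` objects (e.g. a generated cohort).
#' @return A tibble with one [case_summary()] row per case.
#' @export
case_summaries <- function(cases) {
  if (inherits(cases, "dpm_cohort")) cases <- cases$cases
  stopifnot(is.list(cases), length(cases) > 0L)
  do.call(rbind, lapply(cases, case_summary))
}

#' Cohort descriptive statistics
#'
#' Aggregates per-case summaries into the descriptive statistics used to
#' characterise a cohort of diagnostic episodes: mean, sample standard
#' deviation (n-1 denominator) and range for each count metric, and the
#' proportions and pooled confidence endpoints computed over their
#' applicable subsets — the share of final diagnoses rated +4 is taken
#' over final diagnoses, the share of exclusions rated -4 over excluded
#' options, and so on.
#'
#' The mean number of options added during verification is reported under
#' both readings: over all cases (`added_options_mean_all`) and over the
#' cases with at least one addition (`added_options_mean_conditional`).
#'
#' @param cases A tibble of case summaries ([case_summaries()]), or a list
#'   of `dpm` objects.
#' @return An object of class `dpm_cohort_summary`: list with `n_cases`,
#'   `metrics` (tibble: metric, mean, sd, min, max), `proportions` (named
#'   vector in `[0, 1]`: `phase2_additions`, `final_in_phase1`,
#'   `final_rated_top`, `excluded_rated_bottom`), and `confidence` (named
#'   vector: pooled means `final_terminal_mean`, `excluded_terminal_mean`,
#'   `initial_mean`, plus `added_options_mean_all` and
#'   `added_options_mean_conditional`).
#' @export
cohort_summary <- function(cases) {
  if (is.list(cases) && !is.data.frame(cases)) cases <- case_summaries(cases)
  if (!is.data.frame(cases) || nrow(cases) == 0L) {
    stop("cohort_summary() needs at least one case", call. = FALSE)
  }
  cs <- cases
  n <- nrow(cs)

  metric_cols <- c("n_options", "n_cues", "n_units", "n_confidence",
                   "phase1_options", "phase1_cues", "phase2_cues",
                   "phase2_options_added")
  metrics <- do.call(rbind, lapply(metric_cols, function(m) {
    v <- cs[[m]]
    tibble::tibble(metric = m, mean = mean(v),
                   sd = if (n > 1L) stats::sd(v) else NA_real_,
                   min = min(v), max = max(v))
  }))

  n_final_rated <- sum(cs$n_final_rated)
  n_excl_rated <- sum(cs$n_excluded_rated)
  proportions <- c(
    phase2_additions = mean(cs$phase2_options_added > 0L),
    final_in_phase1 = mean(cs$final_in_phase1),
    final_rated_top = if (n_final_rated > 0L)
      sum(cs$final_top) / n_final_rated else NA_real_,
    excluded_rated_bottom = if (n_excl_rated > 0L)
      sum(cs$excluded_bottom) / n_excl_rated else NA_real_
  )

  with_add <- cs$phase2_options_added[cs$phase2_options_added > 0L]
  confidence <- c(
    final_terminal_mean = if (n_final_rated > 0L)
      sum(cs$final_terminal_sum) / n_final_rated else NA_real_,
    excluded_terminal_mean = if (n_excl_rated > 0L)
      sum(cs$excluded_terminal_sum) / n_excl_rated else NA_real_,
    initial_mean = if (sum(cs$n_initial) > 0L)
      sum(cs$initial_sum) / sum(cs$n_initial) else NA_real_,
    added_options_mean_all = mean(cs$phase2_options_added),
    added_options_mean_conditional = if (length(with_add) > 0L)
      mean(with_add) else NA_real_
  )

  structure(list(n_cases = n, metrics = metrics, proportions = proportions,
                 confidence = confidence),
            class = "dpm_cohort_summary")
}

#' @export
print.dpm_cohort_summary <- function(x, ...) {
  cat(sprintf("<dpm_cohort_summary> %d cases\n", x$n_cases))
  for (i in seq_len(nrow(x$metrics))) {
    m <- x$metrics[i, ]
    cat(sprintf("  %-22s M = %.2f (SD = %.2f; %g-%g)\n",
                m$metric, m$mean, m$sd, m$min, m$max))
  }
  p <- x$proportions
  cat(sprintf("  final in phase 1: %.1f%%; finals rated +4: %.1f%%; exclusions rated -4: %.1f%%\n",
              100 * p[["final_in_phase1"]], 100 * p[["final_rated_top"]],
              100 * p[["excluded_rated_bottom"]]))
  cat(sprintf("  terminal confidence: finals %.2f, excluded %.2f\n",
              x$confidence[["final_terminal_mean"]],
              x$confidence[["excluded_terminal_mean"]]))
  invisible(x)
}

#' Compare cohort metrics between contextual groups
#'
#' Splits a cohort by a yes/no contextual flag (time pressure, stress,
#' case experience), drops cases with an unknown level, and reports group
#' means, sample standard deviations and the standardized mean difference
#' (Cohen's d, yes minus no) for each requested metric. Groups with fewer
#' than two cases have no defined SD; the row is kept with `sd = NA` and
#' no effect size.
#'
#' @param cases A tibble of case summaries or list of `dpm` objects.
#' @param flag One of `"time_pressure"`, `"stress"`, `"case_experience"`.
#' @param metrics Summary columns to compare.
#' @return A tibble with one row per metric: group means/SDs/sizes and
#'   `d` with its 95% CI (NA when undefined).
#' @export
compare_groups <- function(cases, flag = c("time_pressure", "stress",
                                           "case_experience"),
                           metrics = c("n_cues", "n_options")) {
  if (is.list(cases) && !is.data.frame(cases)) cases <- case_summaries(cases)
  flag <- match.arg(flag)
  g <- cases[[flag]]
  keep <- g %in% c("yes", "no")
  cs <- cases[keep, , drop = FALSE]
  g <- g[keep]
  if (!any(g == "yes") || !any(g == "no")) {
    stop("compare_groups() needs at least one case per level of ", flag,
         call. = FALSE)
  }
  do.call(rbind, lapply(metrics, function(m) {
    v1 <- cs[[m]][g == "yes"]
    v2 <- cs[[m]][g == "no"]
    s1 <- if (length(v1) > 1L) stats::sd(v1) else NA_real_
    s2 <- if (length(v2) > 1L) stats::sd(v2) else NA_real_
    es <- if (!is.na(s1) && !is.na(s2)) {
      tryCatch(cohens_d(mean(v1), s1, length(v1), mean(v2), s2, length(v2)),
               error = function(e) NULL)
    } else NULL
    tibble::tibble(
      metric = m, flag = flag,
      n_yes = length(v1), mean_yes = mean(v1), sd_yes = s1,
      n_no = length(v2), mean_no = mean(v2), sd_no = s2,
      d = if (is.null(es)) NA_real_ else es$d,
      ci_low = if (is.null(es)) NA_real_ else es$ci_low,
      ci_high = if (is.null(es)) NA_real_ else es$ci_high
    )
  }))
}

#' Export summaries as CSV
#'
#' @param x A case-summary tibble or `dpm_cohort_summary`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  if (inherits(x, "dpm_cohort_summary")) {
    extras <- tibble::tibble(
      metric = c(paste0("prop_", names(x$proportions)),
                 names(x$confidence)),
      mean = c(unname(x$proportions), unname(x$confidence)),
      sd = NA_real_, min = NA_real_, max = NA_real_)
    x <- rbind(x$metrics, extras)
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
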