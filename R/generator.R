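#' Generate one synthetic diagnostic episode
#'
#' Draws a complete, structurally valid case from a
#' [generator_config()]: a generation phase in which 1-4 cues lead to the
#' first suspected diagnoses (each rated once per generation-phase cue,
#' cells sharing the option's initial level), a verification phase in
#' which further cues arrive one at a time — each followed by a confidence
#' rating for one of the mentioned options in rotation, with occasional
#' new options inserted after a cue — and a closing block in which every
#' non-final option receives its exclusion-flagged terminal rating before
#' the final determination. Confidence trajectories interpolate linearly
#' in scale steps between the drawn initial and terminal levels, so final
#' diagnoses rise monotonically and excluded options fall monotonically.
#'
#' Uses the current RNG stream; seed it (or use [generate_cohort()], which
#' derives per-case substreams from the config seed) for reproducibility.
#'
#' @param config A [generator_config()].
#' @param case_id Identifier for the generated case.
#' @return A valid, three-phase-conforming `dpm`.
#' @export
generate_case <- function(config, case_id = "case") {
  stopifnot(inherits(config, "dpm_generator_config"))

  n_opt <- sample_count(config$options_total)
  cap <- config$phase1_options$max

  ## joint draw of final-in-phase-1 (F) and any-addition (A); see
  ## generator_config() for how the conditional laws are derived
  if (n_opt == 1L) {
    fin_p1 <- TRUE; add <- FALSE
  } else {
    fin_p1 <- stats::runif(1) < config$.f_final
    add <- if (!fin_p1 || n_opt > cap) TRUE
           else stats::runif(1) < config$.a2_addition
  }
  n_p1o <- if (add) {
    sample_count(config$phase1_options, upper = min(cap, n_opt - 1L))
  } else n_opt
  n_added <- n_opt - n_p1o

  n_cue <- sample_count(config$cues_total)
  n_p1c <- sample_count(config$phase1_cues,
                        upper = min(config$phase1_cues$max, n_cue - 1L))
  n_p2c <- n_cue - n_p1c

  final_opt <- if (fin_p1) sample.int(n_p1o, 1L)
               else n_p1o + sample.int(n_added, 1L)

  ## confidence endpoints: terminals first (their marginals are the
  ## calibration surface), initials conditioned to keep trajectories
  ## monotone in the required direction
  terminal <- integer(n_opt)
  initial <- integer(n_opt)
  for (i in seq_len(n_opt)) {
    if (i == final_opt) {
      terminal[i] <- sample_count(config$final_terminal)
      initial[i] <- sample_count(config$initial_confidence,
                                 upper = terminal[i])
    } else {
      terminal[i] <- sample_count(config$excluded_terminal)
      initial[i] <- sample_count(config$initial_confidence,
                                 lower = terminal[i])
    }
  }

  cue_ids <- sprintf("c%02d", seq_len(n_cue))
  opt_ids <- sprintf("o%d", seq_len(n_opt))
  sources <- c(rep("MHT", n_p1c),
               sample(names(config$cue_source_probs), n_p2c, replace = TRUE,
                      prob = config$cue_source_probs))

  ## insertion cue (position within phase 2) of each added option:
  ## additions tend to emerge in the earlier half of verification
  add_pos <- if (n_added > 0L) {
    sort(sample.int(max(1L, n_p2c %/% 2L), n_added, replace = TRUE))
  } else integer(0)

  n_units <- n_cue + n_opt + n_p1o * n_p1c + n_added + n_p2c + n_opt + 1L
  kind <- character(n_units); ref_id <- rep(NA_character_, n_units)
  option_ref <- rep(NA_character_, n_units)
  cue_ref <- rep(NA_character_, n_units)
  level <- rep(NA_integer_, n_units)
  is_excl <- rep(NA, n_units)
  pos <- 0L
  emit <- function(k, ref = NA, oref = NA, cref = NA, lv = NA, ex = NA) {
    pos <<- pos + 1L
    kind[pos] <<- k; ref_id[pos] <<- ref; option_ref[pos] <<- oref
    cue_ref[pos] <<- cref; level[pos] <<- lv; is_excl[pos] <<- ex
  }

  ## interior rating slots: verification cue j rates option rr_assign[j],
  ## rotating over the options mentioned by then
  mention_cue <- integer(n_opt)               # 0 = mentioned in phase 1
  if (n_added > 0L) mention_cue[n_p1o + seq_len(n_added)] <- add_pos
  rr_assign <- integer(n_p2c)
  rr <- 0L
  for (j in seq_len(n_p2c)) {
    avail <- which(mention_cue <= j)
    rr <- rr %% length(avail) + 1L
    rr_assign[j] <- avail[rr]
  }
  interior <- lapply(seq_len(n_opt), function(i) {
    m <- sum(rr_assign == i)
    vals <- round(seq(initial[i], terminal[i], length.out = m + 2L))
    as.integer(vals[seq_len(m) + 1L])
  })

  ## phase 1: cues, then each option with one rating cell per phase-1 cue
  for (j in seq_len(n_p1c)) emit("CUE", ref = cue_ids[j])
  for (i in seq_len(n_p1o)) {
    emit("OPTION", ref = opt_ids[i])
    for (j in seq_len(n_p1c)) {
      emit("CONFIDENCE", oref = opt_ids[i], cref = cue_ids[j],
           lv = initial[i], ex = FALSE)
    }
  }

  ## phase 2: cue -> (insertions) -> one interior rating
  taken <- integer(n_opt)
  for (j in seq_len(n_p2c)) {
    cid <- cue_ids[n_p1c + j]
    emit("CUE", ref = cid)
    for (k in which(mention_cue == j)) {
      emit("OPTION", ref = opt_ids[k])
      emit("CONFIDENCE", oref = opt_ids[k], cref = cid,
           lv = initial[k], ex = FALSE)
    }
    i <- rr_assign[j]
    taken[i] <- taken[i] + 1L
    emit("CONFIDENCE", oref = opt_ids[i], cref = cid,
         lv = interior[[i]][taken[i]], ex = FALSE)
  }

  ## closing block: terminal ratings (exclusions first), then FINAL
  last_cue <- cue_ids[n_cue]
  for (i in setdiff(seq_len(n_opt), final_opt)) {
    emit("CONFIDENCE", oref = opt_ids[i], cref = last_cue,
         lv = terminal[i], ex = TRUE)
  }
  emit("CONFIDENCE", oref = opt_ids[final_opt], cref = last_cue,
       lv = terminal[final_opt], ex = FALSE)
  emit("FINAL", oref = opt_ids[final_opt])

  units <- tibble::tibble(
    order_index = seq_len(n_units), kind = kind, ref_id = ref_id,
    option_ref = option_ref, cue_ref = cue_ref, level = level,
    is_exclusion = is_excl)
  cues <- tibble::tibble(cue_id = cue_ids,
                         text = paste("cue", seq_len(n_cue)),
                         source = sources)
  options <- tibble::tibble(option_id = opt_ids,
                            text = paste("option", seq_len(n_opt)))

  exp_yes <- stats::runif(1) < config$p_case_experience
  metadata <- case_metadata(
    case_id = case_id,
    resident_id = "synthetic",
    patient_age = sample(18:83, 1L),
    patient_sex = sample(c("female", "male"), 1L, prob = c(0.51, 0.49)),
    time_pressure = if (stats::runif(1) < config$p_time_pressure) "yes" else "no",
    stress = if (stats::runif(1) < config$p_stress) "yes" else "no",
    case_experience = if (exp_yes) "yes" else "no",
    similarity = if (exp_yes) sample_count(config$similarity) else NA_integer_,
    experience_months = sample_count(config$experience_months)
  )
  dpm(units, cues, options, metadata)
}

## cheap accessors for cohort-level covariate induction (generated cases
## are conforming by construction)
phase2_cue_count <- function(x) {
  u <- x$units
  first_opt <- min(u$order_index[u$kind == "OPTION"])
  sum(u$kind == "CUE" & u$order_index > first_opt)
}

final_terminal_level <- function(x) {
  ids <- final_option_ids(x)
  terminal_confidence(x, ids[1L])
}

case_substream <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483647)
}

#' Generate a reproducible synthetic cohort
#'
#' Generates `config$n_cases` cases, each from its own RNG substream
#' derived from the config seed by counter (so cohorts are reproducible
#' and case `i` does not depend on how many cases precede it), then
#' induces the configured covariate correlations by rank matching: the
#' drawn experience values are reassigned across cases against the
#' verification-phase cue counts (Iman-Conover-style reordering followed
#' by greedy pair swaps) to approach the target Pearson correlation, and
#' similarity ratings are likewise matched to final confidence on the
#' target Spearman correlation. Rank matching only permutes values, so
#' the calibrated marginals are untouched.
#'
#' @param config A [generator_config()].
#' @return An object of class `dpm_cohort`: list with `cases` (list of
#'   `dpm`) and `provenance` (config, seed, generator version).
#' @examples
#' coh <- generate_cohort(generator_config(n_cases = 5, seed = 42))
#' length(coh$cases)  # 5
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "dpm_generator_config"))
  n <- config$n_cases
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(case_substream(config$seed, i))
    cases[[i]] <- generate_case(config, case_id = sprintf("case%04d", i))
  }

  if (n >= 3L) {
    set.seed(case_substream(config$seed, 0L))
    ## experience ~ phase-2 cues (Pearson target)
    p2c <- vapply(cases, phase2_cue_count, integer(1))
    exper <- vapply(cases, function(x) x$metadata$experience_months, integer(1))
    exper <- induce_correlation(exper, p2c, config$r_experience_cues,
                                method = "pearson")
    for (i in seq_len(n)) cases[[i]]$metadata$experience_months <- exper[i]

    ## similarity ~ final confidence (Spearman target, experienced cases)
    has_sim <- vapply(cases, function(x) !is.na(x$metadata$similarity),
                      logical(1))
    if (sum(has_sim) >= 3L) {
      fconf <- vapply(cases[has_sim], final_terminal_level, integer(1))
      sims <- vapply(cases[has_sim], function(x) x$metadata$similarity,
                     integer(1))
      sims <- induce_correlation(sims, fconf,
                                 config$rs_similarity_confidence,
                                 method = "spearman")
      idx <- which(has_sim)
      for (k in seq_along(idx)) cases[[idx[k]]]$metadata$similarity <- sims[k]
    }
  }

  structure(list(
    cases = cases,
    provenance = list(seed = config$seed, n_cases = n, config = config,
                      generator = paste("dpmtrace",
                                        as.character(utils::packageVersion("dpmtrace"))))
  ), class = "dpm_cohort")
}

#' @export
print.dpm_cohort <- function(x, ...) {
  cat(sprintf("<dpm_cohort> %d synthetic cases (seed %d)\n",
              length(x$cases), x$provenance$seed))
  invisible(x)
}

## Reassign the values of `v` across positions so that cor(v, target_x)
## approaches rho: normal-score rank matching, then greedy random swaps.
## Permutation only -- the marginal distribution of v is preserved.
induce_correlation <- function(v, x, rho, method = c("pearson", "spearman"),
                               tol = 0.005, max_iter = 4000L) {
  method <- match.arg(method)
  n <- length(v)
  if (stats::sd(v) == 0 || stats::sd(x) == 0) return(v)  # nothing to induce
  rx <- rank(x, ties.method = "average")
  zx <- stats::qnorm((rx - 0.375) / (n + 0.25))
  latent <- rho * zx + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n)
  v_sorted <- sort(v)
  out <- v_sorted[rank(latent, ties.method = "first")]

  score <- function(vv) {
    if (method == "pearson") stats::cor(vv, x)
    else stats::cor(rank(vv), rank(x))
  }
  cur <- score(out)
  if (is.na(cur)) return(out)
  for (iter in seq_len(max_iter)) {
    if (abs(cur - rho) <= tol) break
    ij <- sample.int(n, 2L)
    cand <- out
    cand[ij] <- cand[rev(ij)]
    new <- score(cand)
    if (!is.na(new) && abs(new - rho) < abs(cur - rho)) {
      out <- cand
      cur <- new
    }
  }
  out
}

#' Simulate expert re-ratings for a cohort
#'
#' Produces rater pairs for concordance analyses: the resident rating is
#' each case's terminal confidence in its final diagnosis; the expert
#' rating differs by a draw from a discrepancy distribution over scale
#' steps (negative steps = expert underconfident), clamped to the scale;
#' the concordance flag is Bernoulli. Defaults reflect an expert who
#' matches exactly in a third of cases, is within one step in about half,
#' and is more often under- than overconfident.
#'
#' @param cohort A `dpm_cohort` (or list of `dpm`).
#' @param p_concordant Probability that the expert diagnosis agrees.
#' @param discrepancy_probs Named probabilities of expert-minus-resident
#'   differences in scale steps (names "-2" ... "2").
#' @return A `dpm_rater_pairs` tibble. Uses the current RNG stream.
#' @export
generate_rater_pairs <- function(cohort, p_concordant = 0.927,
                                 discrepancy_probs = c(`-2` = 0.09,
                                                       `-1` = 0.38,
                                                       `0` = 0.333,
                                                       `1` = 0.17,
                                                       `2` = 0.027)) {
  cases <- if (inherits(cohort, "dpm_cohort")) cohort$cases else cohort
  n <- length(cases)
  res <- vapply(cases, final_terminal_level, integer(1))
  steps <- as.integer(names(discrepancy_probs))
  delta <- sample(steps, n, replace = TRUE,
                  prob = discrepancy_probs / sum(discrepancy_probs))
  expert <- pmax(-4L, pmin(4L, res + delta))
  rater_pairs(
    case_id = vapply(cases, function(x) x$metadata$case_id, character(1)),
    resident_level = res,
    expert_level = expert,
    concordant = stats::runif(n) < p_concordant)
}
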