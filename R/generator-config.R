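## Calibrated integer count distributions
##
## Cohort statistics are reported only as mean / SD / range, so count
## marginals are modelled as discretized truncated normals: integer k in
## [min, max] gets weight pnorm(k+0.5, mu, sigma) - pnorm(k-0.5, mu,
## sigma), renormalized. Truncation shifts the mean away from mu, so the
## location parameter is re-solved (uniroot) until the pmf expectation
## matches the target mean; the sd parameter is left at its nominal value.
## Endpoint distributions additionally carry a point mass (e.g. 67% of
## final diagnoses rated +4) imposed first, with the truncated-normal
## remainder re-calibrated so the overall mean still hits the target.

#' Specify a calibrated integer count distribution
#'
#' @param mean Target mean after discretization and truncation.
#' @param sd Nominal standard deviation (scale of the underlying normal;
#'   `0` gives a point mass, in which case `mean` must be an integer).
#' @param min,max Inclusive integer bounds.
#' @return An object of class `dpm_count_dist` with the calibrated
#'   `support` and `prob` vectors (pmf expectation equals `mean` up to
#'   root-finding tolerance).
#' @examples
#' d <- count_dist(3.2, 1.8, 1, 9)
#' sum(d$support * d$prob)  # 3.2
#' @export
count_dist <- function(mean, sd, min, max) {
  min <- as.integer(min); max <- as.integer(max)
  if (min > max) stop("count_dist: bounds out of order", call. = FALSE)
  if (mean < min || mean > max) {
    stop(sprintf("count_dist: mean %.3g outside bounds [%d, %d]",
                 mean, min, max), call. = FALSE)
  }
  if (sd < 0) stop("count_dist: sd must be >= 0", call. = FALSE)
  support <- min:max
  if (sd == 0 || min == max) {
    if (mean != round(mean)) {
      stop("count_dist: degenerate distribution needs an integer mean",
           call. = FALSE)
    }
    prob <- as.numeric(support == round(mean))
  } else {
    prob <- calibrate_pmf(support, mean, sd)
  }
  structure(list(mean = mean, sd = sd, min = min, max = max,
                 support = support, prob = prob),
            class = "dpm_count_dist")
}

## weights of a discretized normal on an integer support
discretized_weights <- function(support, mu, sd) {
  w <- stats::pnorm(support + 0.5, mu, sd) - stats::pnorm(support - 0.5, mu, sd)
  if (sum(w) <= 0) {
    ## far outside the support; put all mass at the nearest end
    w <- as.numeric(support == support[which.min(abs(support - mu))])
  }
  w / sum(w)
}

## solve for the location parameter so the pmf expectation hits `target`
calibrate_pmf <- function(support, target, sd) {
  f <- function(mu) sum(support * discretized_weights(support, mu, sd)) - target
  lo <- min(support) - 8 * sd - 1
  hi <- max(support) + 8 * sd + 1
  mu <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  discretized_weights(support, mu, sd)
}

#' @rdname count_dist
#' @param mass_at Support point carrying a fixed probability mass.
#' @param mass_p Probability of `mass_at`; the remaining `1 - mass_p` is a
#'   truncated-normal remainder over the other support points, calibrated
#'   so the overall mean equals `mean`.
#' @export
endpoint_dist <- function(mean, sd, min, max, mass_at, mass_p) {
  min <- as.integer(min); max <- as.integer(max); mass_at <- as.integer(mass_at)
  stopifnot(min <= max, mass_at >= min, mass_at <= max,
            mass_p >= 0, mass_p <= 1)
  support <- min:max
  rest <- setdiff(support, mass_at)
  rest_mean <- (mean - mass_p * mass_at) / (1 - mass_p)
  if (rest_mean < base::min(rest) || rest_mean > base::max(rest)) {
    stop(sprintf(
      "endpoint_dist: point mass %.2f at %d is incompatible with mean %.3g",
      mass_p, mass_at, mean), call. = FALSE)
  }
  rest_prob <- calibrate_pmf(rest, rest_mean, sd)
  prob <- numeric(length(support))
  prob[match(rest, support)] <- (1 - mass_p) * rest_prob
  prob[support == mass_at] <- prob[support == mass_at] + mass_p
  structure(list(mean = mean, sd = sd, min = min, max = max,
                 mass_at = mass_at, mass_p = mass_p,
                 support = support, prob = prob),
            class = "dpm_count_dist")
}

#' Draw from a calibrated count distribution
#'
#' @param dist A [count_dist()] or [endpoint_dist()].
#' @param n Number of draws.
#' @param lower,upper Optional conditioning bounds: the pmf is restricted
#'   and renormalized to `[lower, upper]`. An empty restriction falls back
#'   to the feasible support point closest to the requested range.
#' @return Integer vector of length `n`, using the current RNG stream.
#' @export
sample_count <- function(dist, n = 1L, lower = -Inf, upper = Inf) {
  stopifnot(inherits(dist, "dpm_count_dist"))
  keep <- dist$support >= lower & dist$support <= upper
  if (!any(keep)) {
    target <- if (is.finite(upper) && max(dist$support) > upper) upper else lower
    return(rep(dist$support[which.min(abs(dist$support - target))], n))
  }
  s <- dist$support[keep]
  p <- dist$prob[keep]
  if (length(s) == 1L) return(rep(s, n))
  s[sample.int(length(s), n, replace = TRUE, prob = p)]
}

#' Configuration of the synthetic cohort generator
#'
#' Bundles every distributional parameter of the generator. The defaults
#' encode the cohort statistics of the emergency-department study the
#' package's analyses are designed around: 3.2 options and 7.9 cues per
#' case, 2.3 options from 1.9 cues during generation, an 87% chance that
#' the final diagnosis emerged during generation, additions during
#' verification in 45% of cases, confidence endpoints with point masses at
#' the scale extremes (67% of finals at +4, 54% of exclusions at -4), 20%
#' time pressure and 15% stress prevalence, and physician experience of
#' 23-69 months (mean 41) negatively correlated (-0.35) with the number
#' of verification-phase cues.
#'
#' Internally the constructor also derives the joint law of
#' "final-in-phase-1" and "any-addition" from the option-count pmf, so
#' both marginal probabilities are hit exactly in expectation even though
#' the two indicators are logically coupled (a final diagnosis outside
#' phase 1 forces an addition, a single-option case forbids one).
#'
#' @param n_cases Number of cases to generate.
#' @param seed Integer seed; all cohort randomness derives from it.
#' @param options_total,cues_total,phase1_options,phase1_cues Count
#'   distributions ([count_dist()]).
#' @param initial_confidence Distribution of an option's first rating.
#' @param final_terminal,excluded_terminal Endpoint distributions
#'   ([endpoint_dist()]) of the last rating of final / excluded options.
#' @param p_final_in_phase1 Probability that the final diagnosis was
#'   mentioned during option generation.
#' @param p_phase2_addition Probability that at least one option is added
#'   during verification.
#' @param p_time_pressure,p_stress,p_case_experience Prevalence of the
#'   contextual flags.
#' @param similarity Distribution of the similarity rating (cases with
#'   experience only).
#' @param experience_months Distribution of physician experience.
#' @param r_experience_cues Target Pearson correlation between experience
#'   and verification-phase cue count.
#' @param rs_similarity_confidence Target Spearman correlation between
#'   similarity and final confidence.
#' @param cue_source_probs Source mix for verification-phase cues
#'   (generation-phase cues are always history-taking).
#' @return A list of class `dpm_generator_config`.
#' @export
generator_config <- function(
    n_cases = 55L,
    seed = 1L,
    options_total = count_dist(3.2, 1.8, 1, 9),
    cues_total = count_dist(7.9, 2.9, 3, 17),
    phase1_options = count_dist(2.3, 1.4, 1, 6),
    phase1_cues = count_dist(1.9, 0.8, 1, 4),
    initial_confidence = count_dist(1.76, 0.81, -2, 3),
    final_terminal = endpoint_dist(3.56, 0.71, 1, 4, mass_at = 4,
                                   mass_p = 0.67),
    excluded_terminal = endpoint_dist(-2.50, 2.08, -4, 2, mass_at = -4,
                                      mass_p = 0.54),
    p_final_in_phase1 = 0.87,
    p_phase2_addition = 0.45,
    p_time_pressure = 0.20,
    p_stress = 0.15,
    p_case_experience = 46 / 55,
    similarity = count_dist(4, 1.3, 1, 6),
    experience_months = count_dist(41, 11.5, 23, 69),
    r_experience_cues = -0.35,
    rs_similarity_confidence = 0.31,
    cue_source_probs = c(MHT = 0.55, PE = 0.2, ILT = 0.2, OTHER = 0.05)) {
  probs <- c(p_final_in_phase1, p_phase2_addition, p_time_pressure,
             p_stress, p_case_experience)
  if (any(probs < 0 | probs > 1)) {
    stop("generator_config: probabilities must lie in [0, 1]", call. = FALSE)
  }
  cfg <- list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    options_total = options_total, cues_total = cues_total,
    phase1_options = phase1_options, phase1_cues = phase1_cues,
    initial_confidence = initial_confidence,
    final_terminal = final_terminal, excluded_terminal = excluded_terminal,
    p_final_in_phase1 = p_final_in_phase1,
    p_phase2_addition = p_phase2_addition,
    p_time_pressure = p_time_pressure, p_stress = p_stress,
    p_case_experience = p_case_experience,
    similarity = similarity, experience_months = experience_months,
    r_experience_cues = r_experience_cues,
    rs_similarity_confidence = rs_similarity_confidence,
    cue_source_probs = cue_source_probs / sum(cue_source_probs)
  )
  cfg <- c(cfg, joint_final_addition_law(cfg))
  structure(cfg, class = "dpm_generator_config")
}

## Derive the conditional probabilities that realise both
## P(final in phase 1) and P(any phase-2 addition) exactly, given the
## structural constraints: one-option cases can have no addition (final is
## forced into phase 1); more options than the phase-1 cap forces an
## addition; a final outside phase 1 presupposes an addition.
joint_final_addition_law <- function(cfg) {
  pmf <- cfg$options_total$prob
  supp <- cfg$options_total$support
  cap <- cfg$phase1_options$max
  p_one <- sum(pmf[supp == 1L])
  p_over <- sum(pmf[supp > cap])
  p_mid <- 1 - p_one - p_over
  pF <- cfg$p_final_in_phase1
  pA <- cfg$p_phase2_addition

  f <- (pF - p_one) / (1 - p_one)           # P(final in p1 | n_options >= 2)
  if (f < 0 || f > 1) {
    stop("generator_config: p_final_in_phase1 infeasible under the option-count pmf",
         call. = FALSE)
  }
  p_add_mid <- (pA - p_over) / p_mid        # P(addition | 2 <= n <= cap)
  a2 <- (p_add_mid - (1 - f)) / f           # P(addition | final in p1, mid n)
  if (is.na(a2) || a2 < 0 || a2 > 1) {
    stop("generator_config: p_phase2_addition infeasible under the option-count pmf",
         call. = FALSE)
  }
  list(.f_final = f, .a2_addition = a2)
}
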