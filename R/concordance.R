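#' Rater pairs for concordance analysis
#'
#' One row per case: the treating physician's confidence in the final
#' diagnosis, the confidence of an independent expert re-diagnosis on the
#' same 9-point scale, and whether the two diagnoses agree. Diagnosis
#' matching itself is expert judgment and enters as data.
#'
#' @param case_id Character vector of case ids.
#' @param resident_level,expert_level Integer ratings in `[-4, 4]`.
#' @param concordant Logical: do the two final diagnoses agree?
#' @return A tibble of class `dpm_rater_pairs`.
#' @export
rater_pairs <- function(case_id, resident_level, expert_level, concordant) {
  resident_level <- as.integer(resident_level)
  expert_level <- as.integer(expert_level)
  if (any(is.na(resident_level)) || any(is.na(expert_level)) ||
      any(abs(resident_level) > 4L) || any(abs(expert_level) > 4L)) {
    stop("rater levels must be integers on the 9-point scale [-4, 4]",
         call. = FALSE)
  }
  out <- tibble::tibble(case_id = as.character(case_id),
                        resident_level = resident_level,
                        expert_level = expert_level,
                        concordant = as.logical(concordant))
  class(out) <- c("dpm_rater_pairs", class(out))
  out
}

#' Read rater pairs from CSV
#'
#' Expects columns `case_id`, `resident_level`, `expert_level`,
#' `concordant` (`true`/`false` or `TRUE`/`FALSE`).
#'
#' @param path CSV file path.
#' @return A `dpm_rater_pairs` tibble.
#' @export
read_rater_pairs <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "resident_level", "expert_level", "concordant")
  if (!all(need %in% names(tab))) {
    stop("rater-pair CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  conc <- tab$concordant
  if (is.character(conc)) conc <- tolower(conc) == "true"
  rater_pairs(tab$case_id, tab$resident_level, tab$expert_level, conc)
}

#' Proportion of concordant final diagnoses
#'
#' @param pairs A `dpm_rater_pairs` tibble (or any data frame with a
#'   logical `concordant` column).
#' @return Proportion in `[0, 1]`.
#' @examples
#' p <- rater_pairs("a", 4, 3, TRUE)
#' concordance_rate(p)  # 1
#' @export
concordance_rate <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop("concordance_rate() needs at least one rater pair", call. = FALSE)
  }
  mean(pairs$concordant)
}

#' Agreement between resident and expert confidence ratings
#'
#' Compares the two confidence ratings case by case. Discrepancy is the
#' absolute difference in scale steps; the expert is *underconfident* on a
#' case when their rating is below the resident's and *overconfident* when
#' above. Perfect matches, one-step differences and larger differences
#' partition the cases, so the first three percentages sum to 100.
#'
#' @param pairs A `dpm_rater_pairs` tibble.
#' @return Named numeric vector (percentages on the 0-100 scale except
#'   `max_discrepancy`, in scale steps): `perfect_match_pct`,
#'   `within_one_pct`, `larger_pct`, `max_discrepancy`,
#'   `expert_underconfident_pct`, `expert_overconfident_pct`.
#' @export
confidence_agreement <- function(pairs) {
  if (!is.data.frame(pairs) || nrow(pairs) == 0L) {
    stop("confidence_agreement() needs at least one rater pair",
         call. = FALSE)
  }
  diff <- pairs$expert_level - pairs$resident_level
  c(perfect_match_pct = 100 * mean(diff == 0L),
    within_one_pct = 100 * mean(abs(diff) == 1L),
    larger_pct = 100 * mean(abs(diff) > 1L),
    max_discrepancy = max(abs(diff)),
    expert_underconfident_pct = 100 * mean(diff < 0L),
    expert_overconfident_pct = 100 * mean(diff > 0L))
}

#' Cohen's d from group summaries
#'
#' Standardized mean difference using the pooled standard deviation,
#' `d = (m1 - m2) / s_p` with
#' `s_p = sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`, without
#' small-sample (Hedges) correction. The 95% confidence interval uses the
#' large-sample variance approximation
#' `SE = sqrt((n1+n2)/(n1 n2) + d^2 / (2 (n1+n2-2)))`.
#'
#' @param m1,s1,n1 Mean, sample SD and size of group 1.
#' @param m2,s2,n2 Mean, sample SD and size of group 2.
#' @return List of class `dpm_effect_size` with `d`, `ci_low`, `ci_high`.
#' @examples
#' cohens_d(3.5, 0.7, 51, 3.1, 0.8, 51)$d  # ~0.53
#' @export
cohens_d <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(s1 >= 0, s2 >= 0, n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    if (m1 != m2) {
      stop("zero pooled SD with unequal means: d is undefined",
           call. = FALSE)
    }
    d <- 0
  } else {
    d <- (m1 - m2) / sp
  }
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2 - 2)))
  z <- stats::qnorm(0.975)
  structure(list(d = d, ci_low = d - z * se, ci_high = d + z * se),
            class = "dpm_effect_size")
}

#' @rdname cohens_d
#' @param x,y Raw observations for the two groups.
#' @export
cohens_d_data <- function(x, y) {
  cohens_d(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' @export
print.dpm_effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f, 95%% CI [%.3f, %.3f]\n",
              x$d, x$ci_low, x$ci_high))
  invisible(x)
}

correlation_result <- function(coefficient, p, n, method) {
  structure(list(coefficient = coefficient, p = p, N = n, method = method),
            class = "dpm_correlation")
}

#' @export
print.dpm_correlation <- function(x, ...) {
  cat(sprintf("%s: coefficient = %.3f, p = %.4g, N = %d\n",
              x$method, x$coefficient, x$p, x$N))
  invisible(x)
}

## two-sided p for a correlation coefficient via the t transformation
t_transform_p <- function(r, n) {
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Significance test for a Pearson correlation
#'
#' Two-sided test of zero correlation using the exact-null t
#' transformation `t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of
#' freedom. Works from either a reported coefficient plus sample size, or
#' raw paired data.
#'
#' @param r Correlation coefficient (omit when giving raw data).
#' @param n Sample size (>= 3; omit when giving raw data).
#' @param x,y Raw paired observations.
#' @return A `dpm_correlation`: `coefficient`, two-sided `p`, `N`.
#'   `|r| = 1` is degenerate: `p = 0` is returned with a warning.
#' @examples
#' round(pearson_test(r = -0.35, n = 55)$p, 3)  # 0.009
#' @export
pearson_test <- function(r = NULL, n = NULL, x = NULL, y = NULL) {
  if (is.null(r)) {
    stopifnot(!is.null(x), !is.null(y), length(x) == length(y))
    n <- length(x)
    r <- stats::cor(x, y)
  }
  stopifnot(n >= 3, abs(r) <= 1 + 1e-12)
  if (abs(r) >= 1 - 1e-12) {
    r <- sign(r)
    warning("|r| = 1: p-value degenerates to 0", call. = FALSE)
    return(correlation_result(r, 0, as.integer(n), "Pearson"))
  }
  correlation_result(r, t_transform_p(r, n), as.integer(n), "Pearson")
}

#' Significance test for a Spearman rank correlation
#'
#' Computes `rs` as the Pearson correlation of mid-ranks (ties share the
#' average rank) and a two-sided p-value via the same t transformation
#' used for Pearson coefficients — an approximation to the permutation
#' null that is standard practice at moderate sample sizes.
#'
#' @param x,y Raw paired observations.
#' @return A `dpm_correlation`: `coefficient` (`rs`), two-sided `p`, `N`.
#'   Constant input vectors leave the coefficient undefined and raise an
#'   error.
#' @export
spearman_test <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    stop("rank correlation is undefined for a constant vector",
         call. = FALSE)
  }
  rs <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rs) >= 1 - 1e-12) {
    rs <- sign(rs)
    warning("|rs| = 1: p-value degenerates to 0", call. = FALSE)
    return(correlation_result(rs, 0, n, "Spearman"))
  }
  correlation_result(rs, t_transform_p(rs, n), n, "Spearman")
}
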