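#' Segment a trace into the three diagnostic phases
#'
#' Diagnostic episodes recorded as DPMs show a characteristic three-phase
#' pattern: an *option generation* phase in which a few cues lead to the
#' first suspected diagnoses, an *option verification* phase in which
#' further cues are searched and confidence ratings evolve, and the
#' *final determination*. `segment()` recovers the phase boundaries with a
#' deterministic rule: phase 3 is the FINAL unit; phase 2 begins at the
#' first CUE unit whose order index exceeds that of the first OPTION unit;
#' phase 1 is everything before it. Options mentioned during verification
#' do not reopen phase 1.
#'
#' Traces without an option before the final determination, or with no cue
#' after the first option (an empty verification phase), do not fit the
#' pattern; they are reported as non-conforming with explanatory notes
#' (`"no-option-before-final"`, `"empty-phase-2"`), never rejected.
#'
#' @param x A valid `dpm`.
#' @return An object of class `dpm_partition`: list with `phase1_end`,
#'   `phase2_end` (order indices), `conforming` (logical) and `notes`
#'   (character vector of deviations). For conforming cases
#'   `1 <= phase1_end < phase2_end < n` and units `phase2_end + 1 ... n`
#'   form the final determination.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' p <- segment(fig1)
#' c(p$phase1_end, p$phase2_end)  # 11 45
#' @export
segment <- function(x) {
  assert_valid(x)
  u <- x$units[order(x$units$order_index), , drop = FALSE]
  n <- nrow(u)
  notes <- character(0)

  opt_idx <- u$order_index[u$kind == "OPTION"]
  if (length(opt_idx) == 0L) {
    return(structure(list(phase1_end = n - 1L, phase2_end = n - 1L,
                          conforming = FALSE,
                          notes = "no-option-before-final"),
                     class = "dpm_partition"))
  }
  first_option <- min(opt_idx)
  cue_after <- u$order_index[u$kind == "CUE" & u$order_index > first_option]
  if (length(cue_after) == 0L) {
    return(structure(list(phase1_end = n - 1L, phase2_end = n - 1L,
                          conforming = FALSE, notes = "empty-phase-2"),
                     class = "dpm_partition"))
  }
  boundary <- min(cue_after)
  structure(list(phase1_end = boundary - 1L, phase2_end = n - 1L,
                 conforming = TRUE, notes = notes),
            class = "dpm_partition")
}

#' @export
print.dpm_partition <- function(x, ...) {
  cat(sprintf("<dpm_partition> phase 1: 1-%d, phase 2: %d-%d, %s\n",
              x$phase1_end, x$phase1_end + 1L, x$phase2_end,
              if (x$conforming) "conforming"
              else paste("non-conforming:", paste(x$notes, collapse = ", "))))
  invisible(x)
}

#' Per-phase unit composition
#'
#' Counts cues, options and confidence units falling into the generation
#' and verification phases of a partitioned case. For a conforming
#' partition the six counts sum to the unit total minus the FINAL unit.
#' Non-conforming partitions are accepted; counts are then restricted to
#' the phases that exist and the result carries attribute
#' `flagged = TRUE`.
#'
#' @param x A valid `dpm`.
#' @param partition Its [segment()] partition (computed if missing).
#' @return Named integer vector with elements `phase1_cues`,
#'   `phase1_options`, `phase1_confidence`, `phase2_cues`,
#'   `phase2_options_added`, `phase2_confidence`.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' phase_composition(fig1)[c("phase1_cues", "phase2_cues")]  # 3 15
#' @export
phase_composition <- function(x, partition = segment(x)) {
  stopifnot(is_dpm(x), inherits(partition, "dpm_partition"))
  u <- x$units
  p1 <- partition$phase1_end
  p2 <- partition$phase2_end
  in1 <- u$order_index <= p1
  in2 <- u$order_index > p1 & u$order_index <= p2
  out <- c(
    phase1_cues = sum(u$kind == "CUE" & in1),
    phase1_options = sum(u$kind == "OPTION" & in1),
    phase1_confidence = sum(u$kind == "CONFIDENCE" & in1),
    phase2_cues = sum(u$kind == "CUE" & in2),
    phase2_options_added = sum(u$kind == "OPTION" & in2),
    phase2_confidence = sum(u$kind == "CONFIDENCE" & in2)
  )
  if (!partition$conforming) attr(out, "flagged") <- TRUE
  out
}
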