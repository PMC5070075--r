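#' Case metadata for a decision process trace
#'
#' Contextual information recorded alongside each case: identifiers, basic
#' patient descriptors, and the three contextual flags elicited from the
#' diagnosing physician (subjective time pressure, perceived stress, and
#' prior experience with similar cases). If `case_experience` is `"yes"`,
#' the perceived similarity of the case may be rated on a 6-point scale
#' from 1 (not similar) to 6 (very similar).
#'
#' @param case_id,resident_id Opaque identifier strings.
#' @param patient_age Optional age in years.
#' @param patient_sex Optional sex string.
#' @param time_pressure,stress,case_experience One of `"yes"`, `"no"`,
#'   `"unknown"`.
#' @param similarity Optional integer 1-6; only meaningful (and only valid)
#'   when `case_experience == "yes"`.
#' @param experience_months Optional months of postgraduate experience of
#'   the diagnosing physician.
#'
#' @return A list of class `dpm_metadata`.
#' @export
case_metadata <- function(case_id = "case",
                          resident_id = NA_character_,
                          patient_age = NA_integer_,
                          patient_sex = NA_character_,
                          time_pressure = "unknown",
                          stress = "unknown",
                          case_experience = "unknown",
                          similarity = NA_integer_,
                          experience_months = NA_integer_) {
  md <- list(
    case_id = as.character(case_id),
    resident_id = as.character(resident_id),
    patient_age = as.integer(patient_age),
    patient_sex = as.character(patient_sex),
    time_pressure = match.arg(time_pressure, c("yes", "no", "unknown")),
    stress = match.arg(stress, c("yes", "no", "unknown")),
    case_experience = match.arg(case_experience, c("yes", "no", "unknown")),
    similarity = as.integer(similarity),
    experience_months = as.integer(experience_months)
  )
  structure(md, class = "dpm_metadata")
}

metadata_fields <- function() {
  c("case_id", "resident_id", "patient_age", "patient_sex",
    "time_pressure", "stress", "case_experience", "similarity",
    "experience_months")
}

unit_kinds <- function() c("CUE", "OPTION", "CONFIDENCE", "FINAL")
cue_sources <- function() c("MHT", "PE", "ILT", "LITERATURE", "OTHER")

#' Construct a Decision Process Matrix (DPM)
#'
#' A DPM is the complete record of one diagnostic episode: the cues
#' (condensed information units) that were searched, the options (suspected
#' diagnoses) that were entertained, the confidence ratings given to
#' options over time, and the final determination — every occurrence
#' stamped with a consecutive order index starting at 1.
#'
#' The unit table has one row per numbered occurrence with columns:
#' \describe{
#'   \item{order_index}{1-based consecutive position.}
#'   \item{kind}{`"CUE"`, `"OPTION"`, `"CONFIDENCE"` or `"FINAL"`.}
#'   \item{ref_id}{For CUE/OPTION units, the id of the cue/option being
#'     introduced.}
#'   \item{option_ref}{For CONFIDENCE units, the rated option; for the
#'     FINAL unit, one or more option ids joined with `";"` (several ids
#'     encode differential diagnoses).}
#'   \item{cue_ref}{Optionally, for CONFIDENCE units, the cue the rating
#'     responds to.}
#'   \item{level}{For CONFIDENCE units, the integer rating in `[-4, 4]`.}
#'   \item{is_exclusion}{For CONFIDENCE units, whether this rating rules
#'     the option out.}
#' }
#'
#' Construction canonicalises (column types, unit order) but performs only
#' cheap structural checks; use [validate_dpm()] for the full invariant
#' audit.
#'
#' @param units Data frame of numbered units (see Details).
#' @param cues Data frame with columns `cue_id`, `text`, `source`.
#' @param options Data frame with columns `option_id`, `text`.
#' @param metadata A [case_metadata()] object (or list of its fields).
#'
#' @return An object of class `dpm`.
#' @seealso [validate_dpm()], [read_dpm_json()], [segment()]
#' @export
dpm <- function(units, cues, options, metadata = case_metadata()) {
  if (!is.data.frame(units) || !is.data.frame(cues) || !is.data.frame(options)) {
    stop("units, cues and options must be data frames", call. = FALSE)
  }
  if (!inherits(metadata, "dpm_metadata")) {
    metadata <- do.call(case_metadata, metadata[intersect(names(metadata),
                                                          metadata_fields())])
  }
  units <- canonical_units(units)
  cues <- tibble::tibble(
    cue_id = as.character(cues$cue_id),
    text = as.character(cues$text),
    source = as.character(cues$source)
  )
  options <- tibble::tibble(
    option_id = as.character(options$option_id),
    text = as.character(options$text)
  )
  structure(list(metadata = metadata, units = units,
                 cues = cues, options = options),
            class = "dpm")
}

unit_columns <- function() {
  c("order_index", "kind", "ref_id", "option_ref", "cue_ref",
    "level", "is_exclusion")
}

canonical_units <- function(units) {
  need <- c("order_index", "kind")
  if (!all(need %in% names(units))) {
    stop("unit table must have at least order_index and kind columns",
         call. = FALSE)
  }
  n <- nrow(units)
  get_chr <- function(col) {
    if (col %in% names(units)) as.character(units[[col]]) else rep(NA_character_, n)
  }
  out <- tibble::tibble(
    order_index = as.integer(units$order_index),
    kind = as.character(units$kind),
    ref_id = get_chr("ref_id"),
    option_ref = get_chr("option_ref"),
    cue_ref = get_chr("cue_ref"),
    level = if ("level" %in% names(units)) as.integer(units$level) else rep(NA_integer_, n),
    is_exclusion = if ("is_exclusion" %in% names(units)) as.logical(units$is_exclusion) else rep(NA, n)
  )
  out$is_exclusion[out$kind == "CONFIDENCE" & is.na(out$is_exclusion)] <- FALSE
  out[order(out$order_index), , drop = FALSE]
}

#' @export
print.dpm <- function(x, ...) {
  cat(sprintf("<dpm> case '%s': %d units (%d cues, %d options)\n",
              x$metadata$case_id, nrow(x$units), nrow(x$cues),
              nrow(x$options)))
  invisible(x)
}

is_dpm <- function(x) inherits(x, "dpm")

#' Option ids referenced by the final determination
#'
#' @param x A `dpm`.
#' @return Character vector of option ids named in the FINAL unit (one for
#'   a single final diagnosis, several for differential diagnoses);
#'   `character(0)` if the case has no FINAL unit.
#' @export
final_option_ids <- function(x) {
  stopifnot(is_dpm(x))
  ref <- x$units$option_ref[x$units$kind == "FINAL"]
  ref <- ref[!is.na(ref)]
  if (length(ref) == 0L) return(character(0))
  unlist(strsplit(ref, ";", fixed = TRUE), use.names = FALSE)
}

#' Count units of a case by kind
#'
#' @param x A valid `dpm`.
#' @return Named integer vector with elements `CUE`, `OPTION`,
#'   `CONFIDENCE`, `FINAL` and `total`; `total` always equals the maximal
#'   order index.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' unit_counts(fig1)["total"]  # 46
#' @export
unit_counts <- function(x) {
  stopifnot(is_dpm(x))
  k <- factor(x$units$kind, levels = unit_kinds())
  counts <- table(k)
  out <- c(as.integer(counts), total = nrow(x$units))
  names(out) <- c(unit_kinds(), "total")
  out
}

confidence_units_for <- function(x, option_id) {
  u <- x$units
  u[u$kind == "CONFIDENCE" & !is.na(u$option_ref) & u$option_ref == option_id, ,
    drop = FALSE]
}

check_option_id <- function(x, option_id) {
  if (!(option_id %in% x$options$option_id)) {
    stop("unknown option_id: ", option_id, call. = FALSE)
  }
}

#' Terminal and initial confidence of an option
#'
#' The terminal confidence of an option is the level of the last (highest
#' order index) CONFIDENCE unit targeting it — e.g. the exclusion rating
#' for a ruled-out diagnosis, or the last pre-determination rating for the
#' final diagnosis. The initial confidence is the level of its first
#' rating.
#'
#' @param x A `dpm`.
#' @param option_id Id of an option present in the case.
#' @return Integer level, or `NA_integer_` for a never-rated option.
#' @export
terminal_confidence <- function(x, option_id) {
  stopifnot(is_dpm(x))
  check_option_id(x, option_id)
  conf <- confidence_units_for(x, option_id)
  if (nrow(conf) == 0L) return(NA_integer_)
  conf$level[which.max(conf$order_index)]
}

#' @rdname terminal_confidence
#' @export
initial_confidence <- function(x, option_id) {
  stopifnot(is_dpm(x))
  check_option_id(x, option_id)
  conf <- confidence_units_for(x, option_id)
  if (nrow(conf) == 0L) return(NA_integer_)
  conf$level[which.min(conf$order_index)]
}

#' Classify the outcome of an option
#'
#' Each suspected diagnosis ends the episode in exactly one of three
#' states: `FINAL` if the final determination names it, `EXCLUDED` if an
#' exclusion-flagged confidence rating targets it, and `UNDETERMINED`
#' otherwise (mentioned but neither confirmed nor ruled out).
#'
#' @param x A `dpm`.
#' @param option_id Id of an option present in the case.
#' @return One of `"FINAL"`, `"EXCLUDED"`, `"UNDETERMINED"`. An option
#'   that is both named by the final determination and exclusion-flagged is
#'   inconsistent and raises an error.
#' @export
classify_outcome <- function(x, option_id) {
  stopifnot(is_dpm(x))
  check_option_id(x, option_id)
  is_final <- option_id %in% final_option_ids(x)
  conf <- confidence_units_for(x, option_id)
  is_excl <- any(conf$is_exclusion %in% TRUE)
  if (is_final && is_excl) {
    stop("option '", option_id,
         "' is both a final diagnosis and exclusion-flagged", call. = FALSE)
  }
  if (is_final) "FINAL" else if (is_excl) "EXCLUDED" else "UNDETERMINED"
}

#' Outcomes of all options of a case
#'
#' @param x A `dpm`.
#' @return A tibble with columns `option_id`, `text`, `outcome`,
#'   `initial`, `terminal` (initial/terminal confidence levels,
#'   `NA` if unrated).
#' @export
option_outcomes <- function(x) {
  stopifnot(is_dpm(x))
  ids <- x$options$option_id
  tibble::tibble(
    option_id = ids,
    text = x$options$text,
    outcome = vapply(ids, function(id) classify_outcome(x, id), character(1),
                     USE.NAMES = FALSE),
    initial = vapply(ids, function(id) initial_confidence(x, id), integer(1),
                     USE.NAMES = FALSE),
    terminal = vapply(ids, function(id) terminal_confidence(x, id), integer(1),
                      USE.NAMES = FALSE)
  )
}

#' Confidence trajectory of an option
#'
#' The ordered series of confidence ratings an option received over the
#' episode. For final diagnoses the trajectory typically rises towards
#' `+4`; for excluded options it falls.
#'
#' @param x A `dpm`.
#' @param option_id Id of an option present in the case.
#' @return A tibble with columns `order_index`, `level`, `is_exclusion`,
#'   strictly increasing in `order_index`; zero rows for a never-rated
#'   option.
#' @export
trajectory <- function(x, option_id) {
  stopifnot(is_dpm(x))
  check_option_id(x, option_id)
  conf <- confidence_units_for(x, option_id)
  conf <- conf[order(conf$order_index), , drop = FALSE]
  tibble::tibble(order_index = conf$order_index, level = conf$level,
                 is_exclusion = conf$is_exclusion)
}

#' Net confidence change of an option
#'
#' @param x A `dpm`.
#' @param option_id Id of a rated option.
#' @return `last - first` rating in scale steps; 0 for a single rating.
#'   Errors for a never-rated option.
#' @export
net_change <- function(x, option_id) {
  tr <- trajectory(x, option_id)
  if (nrow(tr) == 0L) {
    stop("option '", option_id, "' was never rated", call. = FALSE)
  }
  tr$level[nrow(tr)] - tr$level[1L]
}

#' Path to a packaged example case
#'
#' @param name Example name; currently `"fig1"`, the package's worked
#'   example: an 18-year-old patient with fever and abdominal pain, traced
#'   through 46 numbered units across three options
#'   ("Viral Gastroenteritis" — final, "Lung infection" and "Vascular
#'   problem" — both excluded) and 18 cues. The case skeleton (phase
#'   boundaries 11/45, option set, confidence endpoints, exclusion steps
#'   37 and 45) is fixed; interior details such as verification-phase cue
#'   texts are synthetic reconstructions, plausible for the presentation.
#' @return Path to the JSON file.
#' @export
dpm_example <- function(name = "fig1") {
  name <- match.arg(name, "fig1")
  system.file("extdata", "fig1_reconstruction.json", package = "dpmtrace",
              mustWork = TRUE)
}
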