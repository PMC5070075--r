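#' The anchored 9-point confidence scale
#'
#' Confidence in a suspected diagnosis is rated on a 9-point Likert scale
#' from -4 (*practically impossible*) to +4 (*practically certain*), with a
#' fixed verbal anchor for every step. The mapping between integer values
#' and verbal labels is bijective; labels are presentation-only and never
#' serialized (file formats store the signed integer).
#'
#' @return A named character vector of the nine verbal anchors, named by
#'   their integer value ("-4" ... "4").
#' @examples
#' confidence_labels()
#' @export
confidence_labels <- function() {
  c(`-4` = "practically impossible",
    `-3` = "improbable",
    `-2` = "doubtful",
    `-1` = "thinkable",
    `0`  = "possible",
    `1`  = "probable",
    `2`  = "quite probable",
    `3`  = "very probable",
    `4`  = "practically certain")
}

#' Convert between confidence values and verbal anchors
#'
#' @param value Integer confidence value in `[-4, 4]`.
#' @param label One of the nine fixed verbal anchors
#'   (see [confidence_labels()]).
#'
#' @return `label_for()` returns the verbal anchor for a value;
#'   `level_for()` returns the integer value for an anchor. Both are
#'   vectorised and error on out-of-range values or unknown labels.
#' @examples
#' label_for(4)            # "practically certain"
#' level_for("possible")   # 0
#' @export
label_for <- function(value) {
  if (length(value) == 0L) return(character(0))
  v <- suppressWarnings(as.integer(value))
  if (anyNA(v) || any(v != value) || any(v < -4L | v > 4L)) {
    stop("confidence value must be an integer in [-4, 4]", call. = FALSE)
  }
  unname(confidence_labels()[as.character(v)])
}

#' @rdname label_for
#' @export
level_for <- function(label) {
  if (length(label) == 0L) return(integer(0))
  lab <- confidence_labels()
  idx <- match(label, lab)
  if (anyNA(idx)) {
    stop("unknown confidence label: ",
         paste(unique(label[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  as.integer(names(lab))[idx]
}

# internal: TRUE for integer-valued scalars inside the scale
is_confidence_value <- function(x) {
  length(x) == 1L && !is.na(x) && is.numeric(x) && x == as.integer(x) &&
    x >= -4 && x <= 4
}
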