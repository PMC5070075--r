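#' Validate a Decision Process Matrix
#'
#' Audits every structural invariant of the DPM representation:
#' consecutive 1-based numbering, exactly one FINAL unit in last position,
#' backward-pointing confidence references, resolvable and unique
#' cue/option ids, in-range confidence levels, unit-count conservation and
#' metadata consistency. Violations are returned as data, never thrown:
#' a trace that breaks the rules is still inspectable.
#'
#' Unrated options ("place markers" never given a confidence rating) are
#' legal and reported as warnings, not violations.
#'
#' @param x A `dpm` object (see [dpm()]); anything else is a format error.
#' @return An object of class `dpm_validation`: a list with tibbles
#'   `violations` and `warnings` (columns `rule`, `unit_index`, `message`)
#'   and the scalar `n_units`. Use [is_valid()] to test for zero
#'   violations.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' rep <- validate_dpm(fig1)
#' is_valid(rep)            # TRUE
#' rep$n_units              # 46
#' @export
validate_dpm <- function(x) {
  if (!is_dpm(x)) {
    stop("not a dpm object: validate_dpm() expects the in-memory case type",
         call. = FALSE)
  }
  u <- x$units
  n <- nrow(u)
  viol <- list()
  warn <- list()
  add <- function(store, rule, unit_index, message) {
    store[[length(store) + 1L]] <- tibble::tibble(
      rule = rule, unit_index = as.integer(unit_index), message = message)
    store
  }

  ## numbering: exact set {1..n}
  if (n == 0L) {
    viol <- add(viol, "empty", NA, "case has no units")
  } else if (!identical(sort(u$order_index), seq_len(n))) {
    bad <- u$order_index[duplicated(u$order_index)]
    idx <- if (length(bad) > 0) bad[1L] else NA_integer_
    viol <- add(viol, "numbering not consecutive", idx,
                sprintf("order indices must form the set 1..%d", n))
  }

  ## kinds
  bad_kind <- !(u$kind %in% unit_kinds())
  for (i in which(bad_kind)) {
    viol <- add(viol, "unknown kind", u$order_index[i],
                sprintf("unit kind '%s' is not one of %s", u$kind[i],
                        paste(unit_kinds(), collapse = "/")))
  }

  ## FINAL: exactly one, maximal order index, >= 1 resolvable option ref
  finals <- which(u$kind == "FINAL")
  if (length(finals) != 1L) {
    viol <- add(viol, "final count", NA,
                sprintf("expected exactly one FINAL unit, found %d",
                        length(finals)))
  } else {
    fi <- finals[1L]
    if (n > 0L && u$order_index[fi] != max(u$order_index)) {
      viol <- add(viol, "final not last", u$order_index[fi],
                  "the FINAL unit must carry the maximal order index")
    }
    fref <- final_option_ids(x)
    if (length(fref) == 0L) {
      viol <- add(viol, "final empty", u$order_index[fi],
                  "FINAL must reference at least one option")
    } else {
      for (id in setdiff(fref, x$options$option_id)) {
        viol <- add(viol, "unresolved option ref", u$order_index[fi],
                    sprintf("FINAL references unknown option '%s'", id))
      }
    }
  }

  ## id uniqueness in the cue/option tables
  for (id in unique(x$cues$cue_id[duplicated(x$cues$cue_id)])) {
    viol <- add(viol, "duplicate cue id", NA,
                sprintf("cue_id '%s' occurs more than once", id))
  }
  for (id in unique(x$options$option_id[duplicated(x$options$option_id)])) {
    viol <- add(viol, "duplicate option id", NA,
                sprintf("option_id '%s' occurs more than once", id))
  }

  ## CUE / OPTION units must introduce known ids, once each
  for (i in which(u$kind == "CUE")) {
    if (is.na(u$ref_id[i]) || !(u$ref_id[i] %in% x$cues$cue_id)) {
      viol <- add(viol, "unresolved cue ref", u$order_index[i],
                  sprintf("CUE unit references unknown cue '%s'", u$ref_id[i]))
    }
  }
  for (i in which(u$kind == "OPTION")) {
    if (is.na(u$ref_id[i]) || !(u$ref_id[i] %in% x$options$option_id)) {
      viol <- add(viol, "unresolved option ref", u$order_index[i],
                  sprintf("OPTION unit references unknown option '%s'",
                          u$ref_id[i]))
    }
  }
  for (id in unique(u$ref_id[u$kind == "CUE"][duplicated(u$ref_id[u$kind == "CUE"])])) {
    viol <- add(viol, "cue introduced twice", NA,
                sprintf("cue '%s' is introduced by more than one CUE unit", id))
  }
  for (id in unique(u$ref_id[u$kind == "OPTION"][duplicated(u$ref_id[u$kind == "OPTION"])])) {
    viol <- add(viol, "option introduced twice", NA,
                sprintf("option '%s' is introduced by more than one OPTION unit", id))
  }

  ## CONFIDENCE units: backward refs, level range
  opt_intro <- u$order_index[u$kind == "OPTION"]
  names(opt_intro) <- u$ref_id[u$kind == "OPTION"]
  cue_intro <- u$order_index[u$kind == "CUE"]
  names(cue_intro) <- u$ref_id[u$kind == "CUE"]
  for (i in which(u$kind == "CONFIDENCE")) {
    oi <- u$order_index[i]
    oref <- u$option_ref[i]
    if (is.na(oref) || !(oref %in% names(opt_intro))) {
      viol <- add(viol, "unresolved option ref", oi,
                  sprintf("CONFIDENCE unit targets unknown option '%s'", oref))
    } else if (opt_intro[[oref]] >= oi) {
      viol <- add(viol, "forward reference", oi,
                  sprintf("CONFIDENCE at %d targets option '%s' mentioned at %d",
                          oi, oref, opt_intro[[oref]]))
    }
    cref <- u$cue_ref[i]
    if (!is.na(cref)) {
      if (!(cref %in% names(cue_intro))) {
        viol <- add(viol, "unresolved cue ref", oi,
                    sprintf("CONFIDENCE unit cites unknown cue '%s'", cref))
      } else if (cue_intro[[cref]] >= oi) {
        viol <- add(viol, "forward reference", oi,
                    sprintf("CONFIDENCE at %d cites cue '%s' recorded at %d",
                            oi, cref, cue_intro[[cref]]))
      }
    }
    lv <- u$level[i]
    if (is.na(lv) || lv < -4L || lv > 4L) {
      viol <- add(viol, "level out of range", oi,
                  "CONFIDENCE level must be an integer in [-4, 4]")
    }
  }

  ## conservation: total = #CUE + #OPTION + #CONFIDENCE + 1
  k <- table(factor(u$kind, levels = unit_kinds()))
  if (n != sum(k[c("CUE", "OPTION", "CONFIDENCE")]) + 1L ||
      k[["FINAL"]] != 1L) {
    if (length(finals) == 1L && any(bad_kind)) {
      ## already reported via unknown kind
    } else if (length(finals) == 1L) {
      viol <- add(viol, "count conservation", NA,
                  "unit total must equal #CUE + #OPTION + #CONFIDENCE + 1")
    }
  }

  ## outcome consistency: no option both FINAL and exclusion-flagged
  fref <- final_option_ids(x)
  excl <- unique(u$option_ref[u$kind == "CONFIDENCE" & u$is_exclusion %in% TRUE])
  for (id in intersect(fref, excl)) {
    viol <- add(viol, "final excluded conflict", NA,
                sprintf("option '%s' is both final and exclusion-flagged", id))
  }

  ## metadata consistency
  md <- x$metadata
  if (!is.na(md$similarity)) {
    if (!identical(md$case_experience, "yes")) {
      viol <- add(viol, "metadata", NA,
                  "similarity rating requires case_experience = 'yes'")
    }
    if (md$similarity < 1L || md$similarity > 6L) {
      viol <- add(viol, "metadata", NA, "similarity must lie in 1..6")
    }
  }

  ## warnings: unrated options, orphan cues
  rated <- unique(u$option_ref[u$kind == "CONFIDENCE"])
  for (id in setdiff(x$options$option_id, c(rated, fref))) {
    warn <- add(warn, "unrated option", NA,
                sprintf("option '%s' never received a confidence rating", id))
  }
  for (id in setdiff(x$cues$cue_id, u$ref_id[u$kind == "CUE"])) {
    warn <- add(warn, "orphan cue", NA,
                sprintf("cue '%s' is listed but never occurs as a unit", id))
  }

  empty_tbl <- tibble::tibble(rule = character(0),
                              unit_index = integer(0),
                              message = character(0))
  structure(list(
    violations = if (length(viol)) do.call(rbind, viol) else empty_tbl,
    warnings = if (length(warn)) do.call(rbind, warn) else empty_tbl,
    n_units = n
  ), class = "dpm_validation")
}

#' @rdname validate_dpm
#' @param report A `dpm_validation` report.
#' @export
is_valid <- function(report) {
  stopifnot(inherits(report, "dpm_validation"))
  nrow(report$violations) == 0L
}

#' @export
print.dpm_validation <- function(x, ...) {
  cat(sprintf("<dpm_validation> %d units, %d violation(s), %d warning(s)\n",
              x$n_units, nrow(x$violations), nrow(x$warnings)))
  if (nrow(x$violations) > 0L) {
    for (i in seq_len(nrow(x$violations))) {
      cat(sprintf("  [%s] %s\n", x$violations$rule[i], x$violations$message[i]))
    }
  }
  invisible(x)
}

## internal: stop unless the case passes validation
assert_valid <- function(x) {
  rep <- validate_dpm(x)
  if (!is_valid(rep)) {
    stop("invalid DPM: ", rep$violations$message[1L],
         sprintf(" (%d violation(s) in total)", nrow(rep$violations)),
         call. = FALSE)
  }
  invisible(x)
}
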