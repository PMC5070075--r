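## dpm-1 JSON dialect
##
## Canonical on-disk form of a case. The schema is strict: unknown fields
## are rejected (not ignored) so that fixtures stay canonical, and the
## writer emits a deterministic byte stream (fixed field order, units
## sorted by order_index, confidence levels as signed integers).

FORMAT_VERSION <- "dpm-1"

parse_error <- function(pointer, msg) {
  stop(structure(
    class = c("dpm_parse_error", "error", "condition"),
    list(message = sprintf("dpm parse error at %s: %s", pointer, msg),
         call = NULL)))
}

check_fields <- function(obj, pointer, required, optional = character(0)) {
  if (!is.list(obj)) parse_error(pointer, "expected an object")
  nm <- names(obj)
  unknown <- setdiff(nm, c(required, optional))
  if (length(unknown) > 0L) {
    parse_error(paste0(pointer, "/", unknown[1L]), "unknown field")
  }
  missing <- setdiff(required, nm)
  if (length(missing) > 0L) {
    parse_error(pointer, paste0("missing required field '", missing[1L], "'"))
  }
  invisible(obj)
}

scalar_chr <- function(x, pointer) {
  if (!(is.character(x) || is.na(x)) || length(x) != 1L) {
    parse_error(pointer, "expected a string")
  }
  as.character(x)
}

scalar_int <- function(x, pointer) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    parse_error(pointer, "expected an integer")
  }
  as.integer(x)
}

#' Read and write DPM cases as JSON
#'
#' The `dpm-1` JSON dialect is the canonical serialization of a case:
#' a versioned document with `metadata`, `cues`, `options` and `units`
#' members. Parsing is strict — unknown fields and missing required fields
#' are parse errors naming the JSON location — and `write_dpm_json()`
#' followed by `read_dpm_json()` is the identity on every field. Levels
#' are stored as signed integers; verbal anchors are presentation-only.
#'
#' @param path File path.
#' @param x A `dpm` object.
#' @return `read_dpm_json()` returns a `dpm`; `write_dpm_json()` returns
#'   `path`, invisibly.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' tmp <- tempfile(fileext = ".json")
#' write_dpm_json(fig1, tmp)
#' identical(read_dpm_json(tmp), fig1)  # TRUE
#' @export
read_dpm_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) parse_error("/", paste("invalid JSON:",
                                               conditionMessage(e))))
  dpm_from_document(doc)
}

## build a dpm from a parsed dpm-1 document (shared with config/cohort io)
dpm_from_document <- function(doc) {
  check_fields(doc, "/", c("format_version", "metadata", "cues", "options",
                           "units"))
  if (!identical(doc$format_version, FORMAT_VERSION)) {
    parse_error("/format_version",
                sprintf("unsupported version '%s' (expected '%s')",
                        doc$format_version, FORMAT_VERSION))
  }

  md <- check_fields(doc$metadata, "/metadata", "case_id",
                     setdiff(metadata_fields(), "case_id"))
  metadata <- do.call(case_metadata, md)

  cues <- parse_table(doc$cues, "/cues", c("cue_id", "text", "source"),
                      function(el, ptr) {
                        src <- scalar_chr(el$source, paste0(ptr, "/source"))
                        if (!(src %in% cue_sources())) {
                          parse_error(paste0(ptr, "/source"),
                                      paste("unknown cue source", src))
                        }
                        list(cue_id = scalar_chr(el$cue_id, ptr),
                             text = scalar_chr(el$text, ptr),
                             source = src)
                      })
  cues <- tibble::as_tibble(cues)

  options <- parse_table(doc$options, "/options", c("option_id", "text"),
                         function(el, ptr) {
                           list(option_id = scalar_chr(el$option_id, ptr),
                                text = scalar_chr(el$text, ptr))
                         })
  options <- tibble::as_tibble(options)

  if (!is.list(doc$units)) parse_error("/units", "expected an array")
  n <- length(doc$units)
  units <- tibble::tibble(
    order_index = integer(n), kind = character(n),
    ref_id = NA_character_, option_ref = NA_character_,
    cue_ref = NA_character_, level = NA_integer_, is_exclusion = NA
  )
  for (i in seq_len(n)) {
    el <- doc$units[[i]]
    ptr <- sprintf("/units/%d", i - 1L)
    kind <- scalar_chr(el$kind, paste0(ptr, "/kind"))
    if (!(kind %in% unit_kinds())) {
      parse_error(paste0(ptr, "/kind"), paste("unknown unit kind", kind))
    }
    units$kind[i] <- kind
    switch(kind,
      CUE = ,
      OPTION = {
        check_fields(el, ptr, c("order_index", "kind", "ref_id"))
        units$ref_id[i] <- scalar_chr(el$ref_id, paste0(ptr, "/ref_id"))
      },
      CONFIDENCE = {
        check_fields(el, ptr, c("order_index", "kind", "option_ref", "level"),
                     c("cue_ref", "is_exclusion"))
        units$option_ref[i] <- scalar_chr(el$option_ref,
                                          paste0(ptr, "/option_ref"))
        units$level[i] <- scalar_int(el$level, paste0(ptr, "/level"))
        if (!is.null(el$cue_ref)) {
          units$cue_ref[i] <- scalar_chr(el$cue_ref, paste0(ptr, "/cue_ref"))
        }
        excl <- if (is.null(el$is_exclusion)) FALSE else el$is_exclusion
        if (!is.logical(excl) || length(excl) != 1L || is.na(excl)) {
          parse_error(paste0(ptr, "/is_exclusion"), "expected true or false")
        }
        units$is_exclusion[i] <- excl
      },
      FINAL = {
        check_fields(el, ptr, c("order_index", "kind", "option_refs"))
        refs <- el$option_refs
        if (!is.list(refs) && !is.character(refs)) {
          parse_error(paste0(ptr, "/option_refs"), "expected an array")
        }
        refs <- vapply(refs, function(r) scalar_chr(r, paste0(ptr, "/option_refs")),
                       character(1))
        if (length(refs) == 0L) {
          parse_error(paste0(ptr, "/option_refs"),
                      "FINAL must reference at least one option")
        }
        units$option_ref[i] <- paste(refs, collapse = ";")
      })
    units$order_index[i] <- scalar_int(el$order_index,
                                       paste0(ptr, "/order_index"))
  }

  dpm(units, cues, options, metadata)
}

parse_table <- function(arr, pointer, fields, fn) {
  if (!is.list(arr)) parse_error(pointer, "expected an array")
  rows <- lapply(seq_along(arr), function(i) {
    ptr <- sprintf("%s/%d", pointer, i - 1L)
    check_fields(arr[[i]], ptr, fields)
    fn(arr[[i]], ptr)
  })
  out <- stats::setNames(
    lapply(fields, function(f) vapply(rows, function(r) r[[f]], character(1))),
    fields)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @rdname read_dpm_json
#' @export
write_dpm_json <- function(x, path) {
  stopifnot(is_dpm(x))
  writeLines(dpm_to_json_string(x), path, useBytes = TRUE)
  invisible(path)
}

## deterministic serialization used by both the writer and round-trip tests
dpm_to_json_string <- function(x) {
  md <- x$metadata
  md_out <- list()
  for (f in metadata_fields()) {
    if (!is.na(md[[f]])) md_out[[f]] <- jsonlite::unbox(md[[f]])
  }
  units <- x$units[order(x$units$order_index), , drop = FALSE]
  unit_list <- lapply(seq_len(nrow(units)), function(i) {
    u <- lapply(units[i, ], identity)
    out <- list(order_index = jsonlite::unbox(u$order_index),
                kind = jsonlite::unbox(u$kind))
    switch(u$kind,
      CUE = ,
      OPTION = {
        out$ref_id <- jsonlite::unbox(u$ref_id)
      },
      CONFIDENCE = {
        out$option_ref <- jsonlite::unbox(u$option_ref)
        if (!is.na(u$cue_ref)) out$cue_ref <- jsonlite::unbox(u$cue_ref)
        out$level <- jsonlite::unbox(u$level)
        out$is_exclusion <- jsonlite::unbox(isTRUE(u$is_exclusion))
      },
      FINAL = {
        out$option_refs <- strsplit(u$option_ref, ";", fixed = TRUE)[[1L]]
      })
    out
  })
  doc <- list(
    format_version = jsonlite::unbox(FORMAT_VERSION),
    metadata = md_out,
    cues = lapply(seq_len(nrow(x$cues)), function(i) {
      list(cue_id = jsonlite::unbox(x$cues$cue_id[i]),
           text = jsonlite::unbox(x$cues$text[i]),
           source = jsonlite::unbox(x$cues$source[i]))
    }),
    options = lapply(seq_len(nrow(x$options)), function(i) {
      list(option_id = jsonlite::unbox(x$options$option_id[i]),
           text = jsonlite::unbox(x$options$text[i]))
    }),
    units = unit_list
  )
  jsonlite::toJSON(doc, pretty = 2L, digits = NA)
}
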