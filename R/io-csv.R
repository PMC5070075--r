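## Event-log CSV dialect
##
## One row per numbered unit, in order, with the fixed header
## order_index,kind,ref_id,text,option_ref,cue_ref,level,is_exclusion,source
## and the case metadata as "#key=value" lines before the header. The
## dialect is lossless with respect to the JSON form: CUE and OPTION rows
## carry the text/source of the cue or option they introduce, so the cue
## and option tables can be rebuilt exactly.

csv_header <- function() {
  c("order_index", "kind", "ref_id", "text", "option_ref", "cue_ref",
    "level", "is_exclusion", "source")
}

csv_quote <- function(x) {
  needs <- grepl('[",\n]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Read and write DPM cases as event-log CSV
#'
#' A single-file, diffable dialect: UTF-8, comma separated, one row per
#' unit in order of occurrence, metadata in leading `#key=value` lines.
#' CUE and OPTION rows define the cue/option they introduce (`ref_id`,
#' `text`, and for cues `source`); CONFIDENCE rows carry `option_ref`,
#' optional `cue_ref`, `level` and `is_exclusion`; the FINAL row lists its
#' option ids in `option_ref`, joined with `";"`. Interconversion with the
#' JSON dialect is lossless.
#'
#' @param path File path.
#' @param x A `dpm` object.
#' @return `read_dpm_csv()` returns a `dpm`; `write_dpm_csv()` returns
#'   `path`, invisibly.
#' @export
read_dpm_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- character(0)
  body_start <- 1L
  for (i in seq_along(lines)) {
    if (startsWith(lines[i], "#")) {
      meta_lines <- c(meta_lines, lines[i])
      body_start <- i + 1L
    } else break
  }
  if (body_start > length(lines)) parse_error("/", "no CSV header found")
  if (!identical(lines[body_start], paste(csv_header(), collapse = ","))) {
    parse_error("/", sprintf("row %d: expected header '%s'", body_start,
                             paste(csv_header(), collapse = ",")))
  }

  md <- list()
  for (ln in meta_lines) {
    kv <- sub("^#", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 1L) parse_error("/", paste("malformed metadata line:", ln))
    key <- substr(kv, 1L, eq - 1L)
    if (!(key %in% metadata_fields())) {
      parse_error("/", paste("unknown metadata key:", key))
    }
    md[[key]] <- substr(kv, eq + 1L, nchar(kv))
  }
  metadata <- do.call(case_metadata, md)

  body <- lines[seq.int(body_start, length(lines))]
  tab <- utils::read.csv(text = body, colClasses = "character",
                         na.strings = NULL, comment.char = "",
                         check.names = FALSE)
  if (!identical(names(tab), csv_header())) {
    parse_error("/", "CSV columns do not match the dpm-1 event-log header")
  }

  n <- nrow(tab)
  blank_na <- function(v) ifelse(v == "", NA_character_, v)
  oi <- suppressWarnings(as.integer(tab$order_index))
  for (i in seq_len(n)) {
    row_no <- body_start + i
    if (is.na(oi[i])) {
      parse_error("/", sprintf("row %d: order_index is not an integer", row_no))
    }
    if (oi[i] != i) {
      parse_error("/", sprintf(
        "row %d: order_index %d breaks consecutive numbering (expected %d)",
        row_no, oi[i], i))
    }
    if (tab$kind[i] == "CONFIDENCE") {
      if (tab$option_ref[i] == "") {
        parse_error("/", sprintf("row %d: CONFIDENCE row with empty option_ref",
                                 row_no))
      }
      if (tab$level[i] == "" ||
          is.na(suppressWarnings(as.integer(tab$level[i])))) {
        parse_error("/", sprintf("row %d: CONFIDENCE row needs an integer level",
                                 row_no))
      }
      if (!(tab$is_exclusion[i] %in% c("true", "false"))) {
        parse_error("/", sprintf("row %d: is_exclusion must be true or false",
                                 row_no))
      }
    }
    if (tab$kind[i] == "FINAL" && tab$option_ref[i] == "") {
      parse_error("/", sprintf("row %d: FINAL row with empty option_ref",
                               row_no))
    }
  }

  is_cue <- tab$kind == "CUE"
  is_opt <- tab$kind == "OPTION"
  cues <- tibble::tibble(cue_id = tab$ref_id[is_cue],
                         text = tab$text[is_cue],
                         source = tab$source[is_cue])
  options <- tibble::tibble(option_id = tab$ref_id[is_opt],
                            text = tab$text[is_opt])
  units <- tibble::tibble(
    order_index = oi,
    kind = tab$kind,
    ref_id = blank_na(tab$ref_id),
    option_ref = blank_na(tab$option_ref),
    cue_ref = blank_na(tab$cue_ref),
    level = suppressWarnings(as.integer(blank_na(tab$level))),
    is_exclusion = ifelse(tab$kind == "CONFIDENCE",
                          tab$is_exclusion == "true", NA)
  )
  dpm(units, cues, options, metadata)
}

#' @rdname read_dpm_csv
#' @export
write_dpm_csv <- function(x, path) {
  stopifnot(is_dpm(x))
  md <- x$metadata
  meta_lines <- character(0)
  for (f in metadata_fields()) {
    if (!is.na(md[[f]])) {
      meta_lines <- c(meta_lines, sprintf("#%s=%s", f, md[[f]]))
    }
  }
  u <- x$units[order(x$units$order_index), , drop = FALSE]
  cue_text <- stats::setNames(x$cues$text, x$cues$cue_id)
  cue_src <- stats::setNames(x$cues$source, x$cues$cue_id)
  opt_text <- stats::setNames(x$options$text, x$options$option_id)

  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  n <- nrow(u)
  text <- character(n)
  source <- character(n)
  is_cue <- u$kind == "CUE"
  is_opt <- u$kind == "OPTION"
  text[is_cue] <- unname(cue_text[u$ref_id[is_cue]])
  source[is_cue] <- unname(cue_src[u$ref_id[is_cue]])
  text[is_opt] <- unname(opt_text[u$ref_id[is_opt]])
  excl <- ifelse(u$kind == "CONFIDENCE",
                 ifelse(u$is_exclusion %in% TRUE, "true", "false"), "")

  rows <- paste(
    u$order_index, u$kind, csv_quote(blank(u$ref_id)), csv_quote(text),
    csv_quote(blank(u$option_ref)), csv_quote(blank(u$cue_ref)),
    blank(u$level), excl, source,
    sep = ",")
  writeLines(c(meta_lines, paste(csv_header(), collapse = ","), rows),
             path, useBytes = TRUE)
  invisible(path)
}
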