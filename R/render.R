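#' Render a case as a plain-text decision matrix
#'
#' Lays a case out in the classical matrix shape: cues as rows in order of
#' appearance, options as columns, each confidence rating shown in its
#' cell as `index:level` (e.g. `05:+2`). Row labels carry the cue's order
#' index and phase marker (`P1` generation, `P2` verification); a closing
#' `P3` row shows the final determination. A confidence unit that cites no
#' cue is placed in the row of the last cue recorded before it. Output is
#' a pure function of the case: identical input yields identical text.
#'
#' @param x A valid `dpm`.
#' @param partition Its [segment()] partition (computed if missing).
#' @return An object of class `dpm_grid`: list with `cue_rows`,
#'   `option_cols`, the cell matrix `cells` (cues x options, `""` for
#'   empty cells) and the formatted `lines`. Printing cats the lines.
#' @examples
#' fig1 <- read_dpm_json(dpm_example("fig1"))
#' g <- render_matrix(fig1)
#' c(g$cue_rows, g$option_cols)  # 18 3
#' @export
render_matrix <- function(x, partition = segment(x)) {
  stopifnot(is_dpm(x), inherits(partition, "dpm_partition"))
  u <- x$units[order(x$units$order_index), , drop = FALSE]

  cue_units <- u[u$kind == "CUE", , drop = FALSE]
  opt_units <- u[u$kind == "OPTION", , drop = FALSE]
  cue_ids <- cue_units$ref_id
  opt_ids <- opt_units$ref_id
  n_cue <- length(cue_ids)
  n_opt <- length(opt_ids)

  cells <- matrix("", nrow = n_cue, ncol = n_opt,
                  dimnames = list(cue_ids, opt_ids))
  conf <- u[u$kind == "CONFIDENCE", , drop = FALSE]
  if (nrow(conf) > 0L && n_cue > 0L) {
    for (i in seq_len(nrow(conf))) {
      cue <- conf$cue_ref[i]
      if (is.na(cue)) {
        ## attach to the most recent cue recorded before this rating
        prior <- cue_units$ref_id[cue_units$order_index < conf$order_index[i]]
        if (length(prior) == 0L) next
        cue <- prior[length(prior)]
      }
      opt <- conf$option_ref[i]
      if (!(cue %in% cue_ids) || !(opt %in% opt_ids)) next
      entry <- sprintf("%02d:%+d%s", conf$order_index[i], conf$level[i],
                       if (conf$is_exclusion[i] %in% TRUE) "!" else "")
      old <- cells[cue, opt]
      cells[cue, opt] <- if (nzchar(old)) paste(old, entry, sep = ",") else entry
    }
  }

  cue_text <- stats::setNames(x$cues$text, x$cues$cue_id)
  opt_text <- stats::setNames(x$options$text, x$options$option_id)
  phase_of_cue <- ifelse(cue_units$order_index <= partition$phase1_end,
                         "P1", "P2")
  row_labels <- sprintf("%02d %s [%s]", cue_units$order_index,
                        unname(cue_text[cue_ids]), phase_of_cue)
  col_labels <- sprintf("%02d %s", opt_units$order_index,
                        unname(opt_text[opt_ids]))

  ## final determination row
  fin <- u[u$kind == "FINAL", , drop = FALSE]
  final_row <- rep("", n_opt)
  if (nrow(fin) == 1L) {
    ids <- final_option_ids(x)
    final_row[match(ids, opt_ids)] <- sprintf("%02d:FINAL", fin$order_index)
  }

  widths <- pmax(nchar(col_labels),
                 if (n_cue > 0L) apply(rbind(cells, final_row), 2L, function(col)
                   max(nchar(col), 0L)) else nchar(final_row))
  label_w <- max(nchar(row_labels), nchar("final determination [P3]"), 0L)
  pad <- function(s, w) formatC(s, width = w, flag = "-")
  fmt_row <- function(label, entries) {
    paste(c(pad(label, label_w),
            mapply(pad, entries, widths, USE.NAMES = FALSE)),
          collapse = " | ")
  }
  lines <- c(
    fmt_row("", col_labels),
    vapply(seq_len(n_cue),
           function(i) fmt_row(row_labels[i], cells[i, , drop = TRUE]),
           character(1)),
    fmt_row("final determination [P3]", final_row)
  )

  structure(list(cue_rows = n_cue, option_cols = n_opt,
                 cells = cells, lines = lines),
            class = "dpm_grid")
}

#' @export
print.dpm_grid <- function(x, ...) {
  cat(x$lines, sep = "\n")
  invisible(x)
}
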