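# Builders and oracles shared across the suite. All fixtures are built in
# code; the only packaged file is the fig1 worked-example reconstruction.

unit_row <- function(i, kind, ref = NA, oref = NA, cref = NA, lv = NA,
                     ex = NA) {
  data.frame(order_index = i, kind = kind, ref_id = ref, option_ref = oref,
             cue_ref = cref, level = lv, is_exclusion = ex,
             stringsAsFactors = FALSE)
}

# smallest conforming-format case: cue, option, confidence, final
minimal_case <- function() {
  units <- rbind(
    unit_row(1, "CUE", "c1"),
    unit_row(2, "OPTION", "o1"),
    unit_row(3, "CONFIDENCE", oref = "o1", cref = "c1", lv = 1, ex = FALSE),
    unit_row(4, "FINAL", oref = "o1"))
  dpm(units,
      cues = data.frame(cue_id = "c1", text = "presenting complaint",
                        source = "MHT"),
      options = data.frame(option_id = "o1", text = "working diagnosis"),
      metadata = case_metadata(case_id = "minimal"))
}

fig1_case <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- read_dpm_json(dpm_example("fig1"))
    cached
  }
})

# swap the order indices of two units (returns a fresh dpm)
swap_indices <- function(x, i, j) {
  u <- x$units
  oi <- u$order_index
  u$order_index[oi == i] <- -1L
  u$order_index[u$order_index == j] <- i
  u$order_index[u$order_index == -1L] <- j
  dpm(u, x$cues, x$options, x$metadata)
}

# insert an extra CONFIDENCE unit for the first option directly before the
# first post-option cue, renumbering everything after it
insert_confidence_at_boundary <- function(x) {
  u <- x$units[order(x$units$order_index), , drop = FALSE]
  first_opt <- min(u$order_index[u$kind == "OPTION"])
  boundary <- min(u$order_index[u$kind == "CUE" & u$order_index > first_opt])
  opt_id <- u$ref_id[u$kind == "OPTION" & u$order_index == first_opt]
  lvl <- u$level[u$kind == "CONFIDENCE" & u$option_ref == opt_id][1]
  u$order_index[u$order_index >= boundary] <-
    u$order_index[u$order_index >= boundary] + 1L
  extra <- unit_row(boundary, "CONFIDENCE", oref = opt_id,
                    lv = if (is.na(lvl)) 0 else lvl, ex = FALSE)
  dpm(rbind(u, extra), x$cues, x$options, x$metadata)
}

# exhaustive permutation-null oracle for correlation p-values (tiny n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

perm_test_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  f <- if (method == "spearman") function(a, b) cor(rank(a), rank(b)) else cor
  obs <- f(x, y)
  rs <- vapply(all_perms(seq_along(y)), function(p) f(x, y[p]), numeric(1))
  mean(abs(rs) >= abs(obs) - 1e-12)
}
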