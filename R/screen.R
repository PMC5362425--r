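#' Screen compounds by oral bioavailability and drug-likeness
#'
#' A compound is kept when it satisfies the main rule
#' (OB >= `ob_min` and DL >= `dl_min`, both inclusive), the no-DL
#' fallback (DL absent but OB >= `ob_min_no_dl`), or appears on the
#' literature-rescue whitelist. Whitelisting dominates: a whitelisted
#' compound is kept regardless of its OB/DL values, with reason
#' `rescued` recorded only when the thresholds alone would not have
#' kept it. A compound with both OB and DL absent is excluded (with a
#' warning) unless whitelisted.
#'
#' @param records A `compound_table` (see [read_compound_table()]).
#' @param ob_min Minimum oral bioavailability, percent. Default 30.
#' @param dl_min Minimum drug-likeness index. Default 0.18.
#' @param ob_min_no_dl OB threshold applied when DL is absent.
#'   Default 35.
#' @param whitelist Character vector of compound ids to rescue.
#' @return A `screen_result`: list with elements `kept` (the kept rows
#'   plus a `reason` column in \{threshold, no_dl_rule, rescued\}),
#'   `excluded` (the remaining rows), `per_herb_counts` (named integer
#'   vector over all herbs present in the input) and `params`.
#' @export
screen_compounds <- function(records, ob_min = 30, dl_min = 0.18,
                             ob_min_no_dl = 35, whitelist = character(0)) {
  stopifnot(ob_min >= 0, dl_min >= 0, ob_min_no_dl >= 0)
  unknown <- setdiff(whitelist, records$compound_id)
  if (length(unknown) > 0) {
    warning("whitelist id(s) not in input: ",
            paste(unknown, collapse = ", "))
  }
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    ob <- records$ob[i]; dl <- records$dl[i]
    if (!is.na(dl) && !is.na(ob) && ob >= ob_min && dl >= dl_min) {
      reason[i] <- "threshold"
    } else if (is.na(dl) && !is.na(ob) && ob >= ob_min_no_dl) {
      reason[i] <- "no_dl_rule"
    } else if (records$compound_id[i] %in% whitelist) {
      reason[i] <- "rescued"
    }
    if (is.na(ob) && is.na(dl) && is.na(reason[i])) {
      warning("compound ", records$compound_id[i],
              ": both OB and DL absent; excluded")
    }
  }
  kept <- records[!is.na(reason), , drop = FALSE]
  kept$reason <- reason[!is.na(reason)]
  excluded <- records[is.na(reason), , drop = FALSE]
  herbs_all <- sort(unique(unlist(records$herbs)))
  counts <- vapply(herbs_all, function(h) {
    sum(vapply(kept$herbs, function(hs) h %in% hs, FALSE))
  }, 0L)
  structure(list(kept = kept, excluded = excluded,
                 per_herb_counts = counts,
                 params = list(ob_min = ob_min, dl_min = dl_min,
                               ob_min_no_dl = ob_min_no_dl,
                               whitelist = whitelist)),
            class = "screen_result")
}

#' Per-herb counts of kept compounds
#'
#' A compound belonging to several herbs is counted once for each of
#' them, so the column sum can exceed the number of kept compounds.
#'
#' @param result A `screen_result`.
#' @return data.frame with columns `herb`, `n_kept`.
#' @export
per_herb_summary <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  data.frame(herb = names(result$per_herb_counts),
             n_kept = unname(result$per_herb_counts),
             stringsAsFactors = FALSE)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result: ", nrow(x$kept), " kept (",
      sum(x$kept$reason == "threshold"), " threshold, ",
      sum(x$kept$reason == "no_dl_rule"), " no-DL rule, ",
      sum(x$kept$reason == "rescued"), " rescued), ",
      nrow(x$excluded), " excluded\n", sep = "")
  invisible(x)
}
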