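#' Merge disease-target lists from several sources
#'
#' Symbols are normalized before the union, so case or whitespace
#' variants of one gene collapse to a single record that carries the
#' tags of every source containing it. Merging is order-independent
#' and idempotent.
#'
#' @param lists Named list: source tag -> character vector of raw
#'   symbols.
#' @return A `disease_target_set`: list with `by_source` (source ->
#'   normalized symbol vector), `merged` (data.frame `symbol`,
#'   `sources` with pipe-joined source tags) and `symbols` (the merged
#'   symbol vector).
#' @export
merge_disease_targets <- function(lists) {
  stopifnot(is.list(lists), length(lists) > 0, !is.null(names(lists)))
  by_source <- lapply(lists, function(x) unique(normalize_symbol(x)))
  by_source <- lapply(by_source, function(x) x[nzchar(x)])
  symbols <- sort(unique(unlist(by_source, use.names = FALSE)))
  if (length(symbols) == 0) stop("no disease targets")
  src_names <- names(by_source)
  sources <- vapply(symbols, function(s) {
    paste(src_names[vapply(by_source, function(v) s %in% v, FALSE)],
          collapse = "|")
  }, "")
  structure(list(by_source = by_source,
                 merged = data.frame(symbol = symbols, sources = sources,
                                     stringsAsFactors = FALSE),
                 symbols = symbols),
            class = "disease_target_set")
}

#' Overlap between putative targets and disease targets
#'
#' @param putative Character vector of putative target symbols.
#' @param disease A `disease_target_set` from [merge_disease_targets()].
#' @return Sorted character vector of the shared symbols.
#' @export
overlap_targets <- function(putative, disease) {
  stopifnot(inherits(disease, "disease_target_set"))
  sort(intersect(unique(normalize_symbol(putative)), disease$symbols))
}

#' @export
print.disease_target_set <- function(x, ...) {
  cat("disease_target_set:", length(x$symbols), "merged targets from",
      length(x$by_source), "source(s) (",
      paste(names(x$by_source), lengths(x$by_source),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
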