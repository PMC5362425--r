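#' Build the compound-target bipartite network
#'
#' Compound and target nodes live in separate namespaces (vertex names
#' are prefixed `cpd:` and `tgt:` internally; a `role` vertex attribute
#' marks the side). Kept compounds with no mapped target are excluded
#' from the graph but reported in `unmapped`; map entries referring to
#' unknown compounds are ignored with a warning.
#'
#' @param kept Data.frame of kept compounds (needs a `compound_id`
#'   column; typically `screen_result$kept`).
#' @param ct_map data.frame with columns `compound_id`, `target` (see
#'   [read_ct_map()]).
#' @return A `ct_network`: list with `graph` (igraph, vertex attributes
#'   `role` and `label`), `unmapped` (compound ids with no target) and
#'   `targets` (the unique normalized target symbols).
#' @export
build_bipartite <- function(kept, ct_map) {
  ids <- kept$compound_id
  unknown <- setdiff(unique(ct_map$compound_id), ids)
  if (length(unknown) > 0) {
    warning("compound-target map refers to unknown compound(s): ",
            paste(utils::head(unknown, 5), collapse = ", "),
            if (length(unknown) > 5) ", ...")
  }
  m <- ct_map[ct_map$compound_id %in% ids, , drop = FALSE]
  m$target <- normalize_symbol(m$target)
  m <- unique(m)
  mapped <- unique(m$compound_id)
  unmapped <- setdiff(ids, mapped)
  cn <- paste0("cpd:", sort(mapped), recycle0 = TRUE)
  targets <- sort(unique(m$target))
  tn <- paste0("tgt:", targets, recycle0 = TRUE)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  if (length(cn) + length(tn) > 0) {
    g <- igraph::add_vertices(g, length(cn) + length(tn),
                              name = c(cn, tn),
                              role = c(rep("compound", length(cn)),
                                       rep("target", length(tn))),
                              label = c(sort(mapped), targets))
  }
  if (nrow(m) > 0) {
    g <- igraph::add_edges(g, rbind(
      match(paste0("cpd:", m$compound_id), igraph::V(g)$name),
      match(paste0("tgt:", m$target), igraph::V(g)$name)))
  }
  structure(list(graph = g, unmapped = unmapped, targets = targets),
            class = "ct_network")
}

#' Summary statistics of a compound-target network
#'
#' The compound-degree median uses the standard convention (mean of the
#' two middle values for even counts). `n_nodes_herb_expanded` counts
#' each compound once per herb it belongs to (plus the targets), the
#' alternative node-counting convention some published compound-target
#' networks use; it requires the kept compound table and is `NA`
#' otherwise.
#'
#' @param net A `ct_network` from [build_bipartite()].
#' @param kept Optional data.frame of kept compounds with `compound_id`
#'   and `herbs` columns, used for the herb-expanded node count.
#' @return List with `n_nodes`, `n_edges`, `n_compounds`, `n_targets`,
#'   `n_unmapped`, `median_compound_degree` (NA when no compounds),
#'   `degree_histogram` (table of compound degrees) and
#'   `n_nodes_herb_expanded`.
#' @export
bipartite_stats <- function(net, kept = NULL) {
  stopifnot(inherits(net, "ct_network"))
  g <- net$graph
  role <- igraph::V(g)$role
  cdeg <- igraph::degree(g)[role == "compound"]
  herb_exp <- NA_integer_
  if (!is.null(kept)) {
    mapped <- igraph::V(g)$label[role == "compound"]
    rows <- kept[kept$compound_id %in% mapped, , drop = FALSE]
    herb_exp <- sum(lengths(rows$herbs)) + sum(role == "target")
  }
  list(n_nodes = igraph::vcount(g),
       n_edges = igraph::ecount(g),
       n_compounds = sum(role == "compound"),
       n_targets = sum(role == "target"),
       n_unmapped = length(net$unmapped),
       median_compound_degree =
         if (length(cdeg) == 0) NA_real_ else median_of(cdeg),
       degree_histogram = table(cdeg),
       n_nodes_herb_expanded = herb_exp)
}

#' Putative targets of each herb
#'
#' The target set of a herb is the union of the targets of the kept
#' compounds that contain it, so herbs with shared compounds share
#' targets.
#'
#' @param kept Data.frame of kept compounds (`compound_id`, `herbs`).
#' @param ct_map data.frame with columns `compound_id`, `target`.
#' @return Named list: herb -> character vector of target symbols.
#' @export
per_herb_targets <- function(kept, ct_map) {
  herbs_all <- sort(unique(unlist(kept$herbs)))
  m <- ct_map[ct_map$compound_id %in% kept$compound_id, , drop = FALSE]
  out <- lapply(herbs_all, function(h) {
    in_h <- kept$compound_id[vapply(kept$herbs, function(hs) h %in% hs, FALSE)]
    sort(unique(normalize_symbol(m$target[m$compound_id %in% in_h])))
  })
  names(out) <- herbs_all
  out
}

#' @export
print.ct_network <- function(x, ...) {
  s <- bipartite_stats(x)
  cat("ct_network:", s$n_compounds, "compounds,", s$n_targets,
      "targets,", s$n_edges, "interactions;", s$n_unmapped,
      "unmapped compound(s)\n")
  invisible(x)
}
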