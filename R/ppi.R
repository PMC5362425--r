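#' Build a seed-expanded PPI subnetwork
#'
#' With `expansion = "neighbors"` (the default, mirroring the usual
#' "add the seeds and their direct interactors" behaviour of PPI
#' assembly tools), the node set is the mapped seeds plus all their PPI
#' neighbors, and the edge set is the subgraph of the PPI induced on
#' those nodes. With `expansion = "none"` only the mapped seeds and the
#' edges among them are kept. Seeds absent from the PPI are reported in
#' the `missing_seeds` graph attribute. Under `"neighbors"`, mapped
#' seeds without any interactor are dropped from the network and
#' reported in the `isolated_seeds` graph attribute; under `"none"`
#' they are retained as isolated vertices.
#'
#' @param seeds Character vector of seed symbols (normalized on entry).
#' @param ppi Simple undirected igraph with symbol vertex names.
#' @param expansion `"neighbors"` or `"none"`.
#' @return igraph with vertex attribute `provenance` (`"seed"` or
#'   `"neighbor"`) and graph attribute `missing_seeds`.
#' @export
build_seed_network <- function(seeds, ppi,
                               expansion = c("neighbors", "none")) {
  expansion <- match.arg(expansion)
  seeds <- unique(normalize_symbol(seeds))
  present <- intersect(seeds, igraph::V(ppi)$name)
  if (length(present) == 0) stop("no seeds mapped to the PPI network")
  missing <- setdiff(seeds, present)
  isolated <- character(0)
  if (expansion == "neighbors") {
    nb <- unique(unlist(lapply(igraph::adjacent_vertices(ppi, present),
                               function(v) v$name)))
    isolated <- present[igraph::degree(ppi, present) == 0]
    nodes <- setdiff(union(present, nb), isolated)
  } else {
    nodes <- present
  }
  sub <- igraph::induced_subgraph(ppi, nodes)
  igraph::V(sub)$provenance <-
    ifelse(igraph::V(sub)$name %in% present, "seed", "neighbor")
  sub <- igraph::set_graph_attr(sub, "missing_seeds", missing)
  sub <- igraph::set_graph_attr(sub, "isolated_seeds", isolated)
  sub
}

#' Intersect two PPI networks
#'
#' Returns the network whose nodes are the common nodes and whose edges
#' are the common edges. The operation is commutative and idempotent;
#' when both inputs are induced subgraphs of one parent PPI, the result
#' equals the parent's induced subgraph on the common nodes.
#'
#' @param a,b igraph objects with symbol vertex names.
#' @return igraph on the common node and edge sets.
#' @export
intersect_networks <- function(a, b) {
  nodes <- sort(intersect(igraph::V(a)$name, igraph::V(b)$name))
  key <- function(et) paste(et$from, et$to, sep = "\t")
  common <- intersect(key(edge_table(a)), key(edge_table(b)))
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(common) > 0) {
    pairs <- do.call(rbind, strsplit(common, "\t", fixed = TRUE))
    g <- igraph::add_edges(g, rbind(match(pairs[, 1], nodes),
                                    match(pairs[, 2], nodes)))
  }
  g
}
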