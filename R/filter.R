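#' Stage-1 degree filter: significant targets
#'
#' Nodes whose degree strictly exceeds twice the median degree of all
#' nodes are retained as "significant", and the network is restricted
#' to the subgraph induced on them. The strict inequality means that a
#' regular graph (every node at the median) yields an empty result,
#' which is returned with a warning rather than an error.
#'
#' @param net Non-empty simple undirected igraph.
#' @return List with `network` (the induced subgraph on the significant
#'   nodes), `significant` (their symbols) and `thresholds` (list with
#'   `stage1_median_degree` and `stage1_cut = 2 * median`).
#' @export
stage1_filter <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network")
  deg <- igraph::degree(net)
  m <- median_of(deg)
  cut <- 2 * m
  keep <- igraph::V(net)$name[deg > cut]
  if (length(keep) == 0) {
    warning("stage-1 filter kept no nodes (degree cut ", cut, ")")
  }
  sub <- igraph::induced_subgraph(net, keep)
  list(network = sub, significant = sort(keep),
       thresholds = list(stage1_median_degree = m, stage1_cut = cut))
}

#' Stage-2 six-measure median filter: candidate targets
#'
#' The six centrality measures are recomputed on the significant
#' network itself (not inherited from the parent network), the median
#' of each measure is taken over its nodes, and candidates are the
#' nodes strictly exceeding all six medians simultaneously. On any
#' vertex-transitive graph every node sits exactly at every median, so
#' the candidate set is empty.
#'
#' @param significant_net Non-empty igraph, normally the `network`
#'   element of [stage1_filter()].
#' @return List with `candidates` (sorted symbols), `thresholds`
#'   (named list `stage2_medians` over dc/bc/cc/ec/nc/lac) and
#'   `centralities` (the full `centrality_table`).
#' @export
stage2_filter <- function(significant_net) {
  if (igraph::vcount(significant_net) == 0) {
    stop("empty significant network")
  }
  tab <- compute_centralities(significant_net)
  measures <- c("dc", "bc", "cc", "ec", "nc", "lac")
  med <- vapply(measures, function(m) median_of(tab[[m]]), 0)
  pass <- rep(TRUE, nrow(tab))
  for (m in measures) pass <- pass & (tab[[m]] > med[[m]])
  list(candidates = sort(tab$node[pass]),
       thresholds = list(stage2_medians = as.list(med)),
       centralities = tab)
}

#' Run both filter stages
#'
#' @param net Non-empty simple undirected igraph (typically the
#'   intersection of the putative-target and disease-target networks).
#' @return List with `significant_network`, `significant`,
#'   `candidates`, `thresholds` (stage-1 and stage-2 combined) and
#'   `centralities` (stage-2 table). When stage 1 keeps no nodes the
#'   candidate set is empty and stage-2 medians are `NULL`.
#' @export
filter_targets <- function(net) {
  s1 <- stage1_filter(net)
  if (igraph::vcount(s1$network) == 0) {
    return(list(significant_network = s1$network,
                significant = s1$significant,
                candidates = character(0),
                thresholds = c(s1$thresholds, list(stage2_medians = NULL)),
                centralities = NULL))
  }
  s2 <- stage2_filter(s1$network)
  list(significant_network = s1$network,
       significant = s1$significant,
       candidates = s2$candidates,
       thresholds = c(s1$thresholds, s2$thresholds),
       centralities = s2$centralities)
}
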