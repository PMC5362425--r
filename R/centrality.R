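#' Median of a numeric vector
#'
#' Standard convention: the middle element for odd lengths, the mean of
#' the two middle elements for even lengths. Errors on empty input
#' (downstream threshold computations must never silently receive an
#' empty measure column).
#'
#' @param values Non-empty numeric vector.
#' @return The median.
#' @export
median_of <- function(values) {
  if (length(values) == 0) stop("median of empty list")
  stats::median(as.numeric(values))
}

#' Six topological centrality measures of a simple undirected graph
#'
#' Computes, for every node of `net`:
#' \describe{
#'   \item{dc}{degree centrality, the neighbor count.}
#'   \item{bc}{betweenness centrality, the unnormalized sum over
#'     unordered node pairs of the fraction of shortest paths passing
#'     through the node (pairs in different components contribute 0).}
#'   \item{cc}{closeness centrality, `(n_c - 1) / sum of distances`
#'     within the node's connected component of size `n_c`; 0 for
#'     isolated nodes.}
#'   \item{ec}{eigenvector centrality: the node's entry of the
#'     nonnegative principal eigenvector of its component's adjacency
#'     matrix, each component's vector scaled to unit Euclidean norm.}
#'   \item{nc}{network centrality: the sum over incident edges of the
#'     edge clustering coefficient `ECC(u,v) = z(u,v) /
#'     min(dc(u)-1, dc(v)-1)` where `z` counts triangles containing
#'     the edge; an edge with a degree-1 endpoint contributes 0.}
#'   \item{lac}{local average connectivity: the mean degree of the
#'     node's neighbors within the subgraph induced on those
#'     neighbors; 0 for isolated nodes.}
#' }
#' Degree, betweenness and closeness are delegated to igraph; the
#' eigenvector, edge-clustering and local-connectivity measures are
#' computed here (per connected component for the eigenvector, by
#' shifted power iteration from the all-ones vector to tolerance
#' 1e-12).
#'
#' @param net Simple undirected igraph with at least one node and
#'   vertex names.
#' @return A `centrality_table`: data.frame with columns `node`, `dc`,
#'   `bc`, `cc`, `ec`, `nc`, `lac`, one row per node, in vertex order.
#' @export
compute_centralities <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) stop("no nodes")
  if (igraph::any_loop(net) || igraph::any_multiple(net)) {
    stop("centralities are defined on simple graphs")
  }
  nodes <- igraph::V(net)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  dc <- as.numeric(igraph::degree(net))
  bc <- as.numeric(igraph::betweenness(net, directed = FALSE,
                                       normalized = FALSE))
  # closeness within components: (n_c - 1) / sum of finite distances
  d <- igraph::distances(net)
  cc <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (length(di) == 0) 0 else length(di) / sum(di)
  }, 0)
  ec <- eigenvector_by_component(net)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  # z[u,v] = triangles containing edge (u,v); zero off the edge set
  Z <- (A %*% A) * A
  nc <- numeric(n)
  lac <- numeric(n)
  el <- igraph::as_edgelist(net, names = FALSE)
  if (nrow(el) > 0) {
    zuv <- Z[el]
    denom <- pmin(dc[el[, 1]], dc[el[, 2]]) - 1
    ecc <- ifelse(denom > 0, zuv / denom, 0)
    for (k in seq_len(nrow(el))) {
      nc[el[k, 1]] <- nc[el[k, 1]] + ecc[k]
      nc[el[k, 2]] <- nc[el[k, 2]] + ecc[k]
    }
  }
  # sum over neighbors of their degree inside the neighbor-induced
  # subgraph = twice the triangle count at the node
  tri <- Matrix::rowSums(Z)
  lac <- ifelse(dc > 0, as.numeric(tri) / dc, 0)
  structure(data.frame(node = nodes, dc = dc, bc = bc, cc = cc, ec = ec,
                       nc = nc, lac = lac, stringsAsFactors = FALSE),
            class = c("centrality_table", "data.frame"))
}

# Principal eigenvector per connected component, nonnegative, each
# component's vector scaled to unit Euclidean norm. Power iteration on
# A + I (same eigenvectors as A; the shift makes the principal
# eigenvalue strictly dominant so bipartite components converge too),
# started from the all-ones vector.
eigenvector_by_component <- function(net, tol = 1e-12, max_iter = 1e5) {
  n <- igraph::vcount(net)
  comp <- igraph::components(net)$membership
  ec <- numeric(n)
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) {
      ec[idx] <- 1
      next
    }
    Ac <- A[idx, idx, drop = FALSE]
    x <- rep(1, length(idx)) / sqrt(length(idx))
    for (it in seq_len(max_iter)) {
      y <- as.numeric(Ac %*% x) + x    # (A + I) x
      ny <- sqrt(sum(y^2))
      if (ny == 0) break               # cannot happen with the shift
      y <- y / ny
      if (max(abs(y - x)) < tol) { x <- y; break }
      x <- y
    }
    ec[idx] <- abs(x)
  }
  ec
}

#' Write a centrality table as TSV
#'
#' @param tab A `centrality_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_centrality_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
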