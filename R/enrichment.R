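#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for the number `X` of query genes falling in a term,
#' when `n` query genes are drawn without replacement from a universe
#' of `N` genes of which `K` belong to the term.
#'
#' @param k Observed overlap.
#' @param K Term size within the universe.
#' @param n Query size within the universe.
#' @param N Universe size.
#' @return The tail probability (vectorized over the arguments).
#' @export
#' @examples
#' hypergeom_tail(5, 5, 10, 20) # = choose(15, 5) / choose(20, 10)
hypergeom_tail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of gene sets
#'
#' For each term, with `N` the universe size, `K` the number of term
#' genes in the universe, `n` the number of query genes in the universe
#' and `k` the overlap, the enrichment p-value is the upper
#' hypergeometric tail `P(X >= k)`. Query genes outside the universe
#' are dropped with a message; terms with no gene in the universe are
#' skipped with a message. Benjamini-Hochberg correction is applied
#' within each term category separately (set `by_category = FALSE` to
#' pool), and terms with `p_adj <= alpha` are flagged enriched. The
#' full table is returned regardless of the flag.
#'
#' @param query Character vector of query gene symbols.
#' @param sets A `gene_set_collection` (see [read_gmt()]).
#' @param universe Character vector, the gene universe. Defaults to all
#'   genes appearing in `sets`.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @param by_category Adjust within category (default) or pooled.
#' @return data.frame with columns `term_id`, `category`, `k`, `K`,
#'   `n`, `N`, `p`, `p_adj`, `enriched`, ordered by `p`.
#' @export
hypergeom_enrich <- function(query, sets, universe = NULL, alpha = 0.05,
                             by_category = TRUE) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(universe)) {
    universe <- unique(unlist(sets$genes, use.names = FALSE))
  }
  universe <- unique(normalize_symbol(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(normalize_symbol(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    message(length(outside), " query gene(s) outside the universe dropped")
  }
  q <- intersect(query, universe)
  if (length(q) > length(universe)) stop("universe smaller than query")
  N <- length(universe)
  n <- length(q)
  rows <- lapply(seq_along(sets$ids), function(i) {
    tg <- intersect(unique(normalize_symbol(sets$genes[[i]])), universe)
    K <- length(tg)
    if (K == 0) {
      message("term ", sets$ids[i], " has no genes in the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(tg, q))
    p <- hypergeom_tail(k, K, n, N)
    data.frame(term_id = sets$ids[i], category = sets$category[i],
               k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term_id = character(0), category = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res$p_adj <- rep(NA_real_, nrow(res))
  if (nrow(res) > 0) {
    if (by_category) {
      for (cat in unique(res$category)) {
        idx <- res$category == cat
        res$p_adj[idx] <- stats::p.adjust(res$p[idx], method = "BH")
      }
    } else {
      res$p_adj <- stats::p.adjust(res$p, method = "BH")
    }
  }
  res$enriched <- res$p_adj <= alpha
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  res
}

#' Cohen's kappa between two gene memberships
#'
#' Agreement of two binary membership vectors over a reference gene
#' set: with `a` genes in both sets, `b`/`c` in exactly one, and `d`
#' in neither, observed agreement is `po = (a + d) / N` and chance
#' agreement `pe = ((a+b)(a+c) + (c+d)(b+d)) / N^2`;
#' `kappa = (po - pe) / (1 - pe)`, defined as 1 when `pe = 1`.
#'
#' @param set_a,set_b Character vectors of gene symbols.
#' @param reference Non-empty character vector, the reference gene set
#'   over which memberships are compared.
#' @return The kappa statistic (a single number, at most 1).
#' @export
cohen_kappa <- function(set_a, set_b, reference) {
  reference <- unique(reference)
  Nr <- length(reference)
  if (Nr == 0) stop("empty reference")
  ina <- reference %in% set_a
  inb <- reference %in% set_b
  a <- sum(ina & inb); b <- sum(ina & !inb)
  c_ <- sum(!ina & inb); d <- sum(!ina & !inb)
  po <- (a + d) / Nr
  pe <- ((a + b) * (a + c_) + (c_ + d) * (b + d)) / Nr^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Group enriched terms by kappa similarity
#'
#' Every pair of enriched terms is linked when the kappa agreement of
#' their gene memberships over `reference` reaches `kappa_min`; groups
#' are the connected components of the link graph (singleton terms form
#' singleton groups). Each group's leading term is its member with the
#' smallest adjusted p-value, ties broken by lexicographically smallest
#' term id.
#'
#' @param results Enrichment table (normally the `enriched == TRUE`
#'   rows of [hypergeom_enrich()]).
#' @param sets The `gene_set_collection` the terms came from.
#' @param reference Non-empty character vector of gene symbols over
#'   which term memberships are compared (typically the universe).
#' @param kappa_min Minimum kappa to link two terms. Default 0.4.
#' @return List with `groups` (data.frame `term_id`, `group`,
#'   `leading`) and `links` (data.frame `term_a`, `term_b`, `kappa`
#'   for every linked pair).
#' @export
kappa_group_terms <- function(results, sets, reference, kappa_min = 0.4) {
  stopifnot(inherits(sets, "gene_set_collection"))
  reference <- unique(normalize_symbol(reference))
  if (length(reference) == 0) stop("empty reference")
  empty <- list(groups = data.frame(term_id = character(0),
                                    group = integer(0),
                                    leading = logical(0),
                                    stringsAsFactors = FALSE),
                links = data.frame(term_a = character(0),
                                   term_b = character(0),
                                   kappa = numeric(0),
                                   stringsAsFactors = FALSE))
  if (is.null(results) || nrow(results) == 0) return(empty)
  ids <- results$term_id
  missing <- setdiff(ids, sets$ids)
  if (length(missing) > 0) {
    stop("term(s) absent from the collection: ",
         paste(missing, collapse = ", "))
  }
  genes <- lapply(sets$genes[ids], function(g) {
    intersect(unique(normalize_symbol(g)), reference)
  })
  m <- length(ids)
  links <- list()
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq((i + 1), m)) {
        kap <- cohen_kappa(genes[[i]], genes[[j]], reference)
        if (kap >= kappa_min) {
          links[[length(links) + 1]] <-
            data.frame(term_a = ids[i], term_b = ids[j], kappa = kap,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  links <- if (length(links) > 0) do.call(rbind, links) else empty$links
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, m, name = ids)
  if (nrow(links) > 0) {
    g <- igraph::add_edges(g, rbind(match(links$term_a, ids),
                                    match(links$term_b, ids)))
  }
  membership <- igraph::components(g)$membership
  leading <- logical(m)
  for (grp in unique(membership)) {
    idx <- which(membership == grp)
    padj <- results$p_adj[match(ids[idx], results$term_id)]
    best <- idx[order(padj, ids[idx])][1]
    leading[best] <- TRUE
  }
  list(groups = data.frame(term_id = ids,
                           group = as.integer(membership),
                           leading = leading, stringsAsFactors = FALSE),
       links = links)
}
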