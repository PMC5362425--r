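#' Configuration for the synthetic study-data generator
#'
#' Defaults describe a desk-scale study: eight herbs contributing 20
#' compounds each with occasional cross-herb sharing, oral
#' bioavailability uniform on \[0, 80\] percent, a Beta(2, 5)
#' drug-likeness index with a small missing fraction, a hub-skewed
#' compound-target map over a 120-protein pool, a 300-node scale-free
#' PPI graph carrying a 15-node planted module wired at density 0.9
#' (the ground-truth "true targets" the topological filter should
#' recover), five overlapping disease-target sources enriched for the
#' module, and a gene-set collection with terms planted on the module.
#'
#' @param seed Integer RNG seed; a fixed seed makes the whole bundle
#'   reproducible byte for byte.
#' @param n_herbs,compounds_per_herb Herb count and compounds per herb.
#' @param herb_sharing_prob Probability that a compound belongs to more
#'   than one herb.
#' @param ob_range Range of the uniform OB distribution, percent.
#' @param dl_shape Two Beta shape parameters for the DL index.
#' @param missing_dl_fraction Fraction of compounds with absent DL.
#' @param unmapped_compound_fraction Fraction of compounds with no
#'   predicted target.
#' @param n_targets Size of the target pool (always contains the
#'   planted module).
#' @param bipartite_attachment_exponent Preferential-attachment
#'   exponent for target selection; 1 gives linear attachment and
#'   heavy-tailed target degrees.
#' @param target_mu Mean of the negative-binomial (size 1) draw for
#'   targets per mapped compound (plus one).
#' @param ppi_n_nodes,ppi_attachment_m Scale-free PPI size and edges
#'   added per node.
#' @param planted_module_size,planted_module_density Size of the
#'   planted true-target module and the probability wiring each
#'   intra-module pair.
#' @param n_disease_sources Number of disease-target sources.
#' @param disease_overlap_with_module Probability that each module gene
#'   enters each disease source.
#' @param n_terms Number of background gene-set terms.
#' @param planted_term_count Number of terms planted on the module.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 42,
                             n_herbs = 8,
                             compounds_per_herb = 20,
                             herb_sharing_prob = 0.15,
                             ob_range = c(0, 80),
                             dl_shape = c(2, 5),
                             missing_dl_fraction = 0.05,
                             unmapped_compound_fraction = 0.15,
                             n_targets = 120,
                             bipartite_attachment_exponent = 1,
                             target_mu = 7,
                             ppi_n_nodes = 300,
                             ppi_attachment_m = 3,
                             planted_module_size = 15,
                             planted_module_density = 0.9,
                             n_disease_sources = 5,
                             disease_overlap_with_module = 0.8,
                             n_terms = 30,
                             planted_term_count = 3) {
  cfg <- list(seed = as.integer(seed), n_herbs = n_herbs,
              compounds_per_herb = compounds_per_herb,
              herb_sharing_prob = herb_sharing_prob,
              ob_range = ob_range, dl_shape = dl_shape,
              missing_dl_fraction = missing_dl_fraction,
              unmapped_compound_fraction = unmapped_compound_fraction,
              n_targets = n_targets,
              bipartite_attachment_exponent = bipartite_attachment_exponent,
              target_mu = target_mu,
              ppi_n_nodes = ppi_n_nodes,
              ppi_attachment_m = ppi_attachment_m,
              planted_module_size = planted_module_size,
              planted_module_density = planted_module_density,
              n_disease_sources = n_disease_sources,
              disease_overlap_with_module = disease_overlap_with_module,
              n_terms = n_terms,
              planted_term_count = planted_term_count)
  probs <- c("herb_sharing_prob", "missing_dl_fraction",
             "unmapped_compound_fraction", "planted_module_density",
             "disease_overlap_with_module")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0,1]")
  }
  sizes <- c("n_herbs", "compounds_per_herb", "n_targets", "ppi_n_nodes",
             "ppi_attachment_m", "planted_module_size",
             "n_disease_sources", "n_terms", "planted_term_count")
  for (p in sizes) {
    if (cfg[[p]] < 0) stop(p, " must be >= 0")
  }
  if (cfg$planted_module_size > cfg$ppi_n_nodes) {
    stop("planted module larger than the PPI graph")
  }
  if (cfg$n_targets > cfg$ppi_n_nodes) {
    stop("target pool larger than the PPI graph")
  }
  if (cfg$planted_module_size > cfg$n_targets) {
    stop("planted module larger than the target pool")
  }
  structure(cfg, class = "synthetic_config")
}

#' Generate a complete synthetic input bundle with ground truth
#'
#' Draws every input the pipeline consumes — compound table,
#' compound-target map, PPI edge list, disease-target lists, gene-set
#' collection and rescue whitelist — under the given configuration,
#' together with a ground-truth manifest recording the compounds that
#' survive the screening rules, the planted PPI module and the planted
#' gene-set terms. The same configuration (including seed) always
#' yields the identical bundle; with `dir` set, the files written are
#' byte-identical across runs.
#'
#' @param cfg A `synthetic_config`.
#' @param dir Optional directory; when given, all bundle files are
#'   written there (created if needed) and their paths returned in
#'   `$paths`.
#' @return A `synthetic_bundle`: list with `compounds`, `ct_map`,
#'   `ppi` (igraph), `disease_lists`, `gene_sets`, `whitelist`,
#'   `manifest`, `cfg` and (when written) `paths`.
#' @export
simulate_bundle <- function(cfg = synthetic_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)

  ## --- PPI: scale-free backbone + planted dense module ---------------
  ppi <- igraph::sample_pa(cfg$ppi_n_nodes, power = 1,
                           m = cfg$ppi_attachment_m, directed = FALSE)
  gene_names <- sprintf("G%03d", seq_len(cfg$ppi_n_nodes))
  igraph::V(ppi)$name <- gene_names
  # true targets are planted among the well-connected proteins (disease
  # proteins sit high in the PPI degree distribution, and the filter is
  # hub-seeking by design): sample the module from the top of the
  # degree ranking, twice the module size wide
  ranked <- gene_names[order(igraph::degree(ppi), decreasing = TRUE)]
  topk <- utils::head(ranked, max(2 * cfg$planted_module_size,
                                  cfg$planted_module_size))
  module <- sort(sample(topk, cfg$planted_module_size))
  if (length(module) > 1) {
    pairs <- utils::combn(module, 2)
    wire <- stats::runif(ncol(pairs)) < cfg$planted_module_density
    if (any(wire)) {
      ppi <- igraph::add_edges(
        ppi, rbind(match(pairs[1, wire], gene_names),
                   match(pairs[2, wire], gene_names)))
    }
  }
  ppi <- igraph::simplify(ppi)

  ## --- compounds ------------------------------------------------------
  herbs <- sprintf("HERB%d", seq_len(cfg$n_herbs))
  n_cpd <- cfg$n_herbs * cfg$compounds_per_herb
  ids <- sprintf("C%03d", seq_len(n_cpd))
  primary <- rep(herbs, each = cfg$compounds_per_herb)
  herb_sets <- vector("list", n_cpd)
  for (i in seq_len(n_cpd)) {
    hs <- primary[i]
    if (cfg$n_herbs > 1 && stats::runif(1) < cfg$herb_sharing_prob) {
      extra <- sample(setdiff(herbs, hs),
                      min(sample(1:3, 1), cfg$n_herbs - 1))
      hs <- c(hs, extra)
    }
    herb_sets[[i]] <- sort(hs)
  }
  ob <- stats::runif(n_cpd, cfg$ob_range[1], cfg$ob_range[2])
  dl <- stats::rbeta(n_cpd, cfg$dl_shape[1], cfg$dl_shape[2])
  dl[stats::runif(n_cpd) < cfg$missing_dl_fraction] <- NA_real_

  ## screening ground truth (literal restatement of the rules)
  survives <- (!is.na(dl) & !is.na(ob) & ob >= 30 & dl >= 0.18) |
    (is.na(dl) & !is.na(ob) & ob >= 35)
  failing <- ids[!survives]
  whitelist <- sort(sample(failing, min(8, length(failing))))
  rescued <- ids %in% whitelist

  compounds <- data.frame(compound_id = ids,
                          name = sprintf("compound-%03d", seq_len(n_cpd)),
                          stringsAsFactors = FALSE)
  compounds$herbs <- herb_sets
  compounds$ob <- round(ob, 4)
  compounds$dl <- round(dl, 4)
  compounds$rescued <- rescued
  compounds$rescue_note <- ifelse(rescued,
                                  "reported pharmacological activity", "")
  compounds <- validate_compound_table(compounds)
  # rounding can push a borderline value across a threshold; recompute
  survives <- with(compounds,
                   (!is.na(dl) & !is.na(ob) & ob >= 30 & dl >= 0.18) |
                     (is.na(dl) & !is.na(ob) & ob >= 35))

  ## --- compound-target map: hub-skewed preferential attachment -------
  pool <- sort(unique(c(module,
                        sample(setdiff(gene_names, module),
                               cfg$n_targets - length(module)))))
  tdeg <- stats::setNames(rep(0, length(pool)), pool)
  map_rows <- list()
  for (i in seq_len(n_cpd)) {
    if (stats::runif(1) < cfg$unmapped_compound_fraction) next
    k <- 1 + stats::rnbinom(1, size = 1, mu = cfg$target_mu)
    k <- min(k, length(pool))
    w <- (tdeg + 1)^cfg$bipartite_attachment_exponent
    tg <- sample(pool, k, prob = w)
    tdeg[tg] <- tdeg[tg] + 1
    map_rows[[length(map_rows) + 1]] <-
      data.frame(compound_id = ids[i], target = tg,
                 stringsAsFactors = FALSE)
  }
  ct_map <- do.call(rbind, map_rows)

  ## --- disease-target lists ------------------------------------------
  sources <- sprintf("SOURCE%d", seq_len(cfg$n_disease_sources))
  background <- setdiff(gene_names, module)
  disease_lists <- lapply(sources, function(s) {
    from_module <- module[stats::runif(length(module)) <
                            cfg$disease_overlap_with_module]
    n_bg <- sample(10:50, 1)
    sort(unique(c(from_module, sample(background, n_bg))))
  })
  names(disease_lists) <- sources

  ## --- gene sets: planted module terms + background terms ------------
  gmt_ids <- character(0); gmt_desc <- character(0)
  gmt_cat <- character(0); gmt_genes <- list()
  cats <- c("signaling_pathway", "molecular_function_biological_process")
  for (t in seq_len(cfg$planted_term_count)) {
    sz <- min(sample(10:12, 1), length(module))
    gs <- sort(unique(c(sample(module, sz), sample(background, 3))))
    gmt_ids <- c(gmt_ids, sprintf("PLANTED%02d", t))
    gmt_desc <- c(gmt_desc, sprintf("planted module process %d", t))
    gmt_cat <- c(gmt_cat, cats[(t %% 2) + 1])
    gmt_genes[[length(gmt_genes) + 1]] <- gs
  }
  for (t in seq_len(cfg$n_terms)) {
    gs <- sort(unique(sample(gene_names, sample(10:40, 1))))
    gmt_ids <- c(gmt_ids, sprintf("TERM%02d", t))
    gmt_desc <- c(gmt_desc, sprintf("background process %d", t))
    gmt_cat <- c(gmt_cat, cats[(t %% 2) + 1])
    gmt_genes[[length(gmt_genes) + 1]] <- gs
  }
  names(gmt_genes) <- gmt_ids
  gene_sets <- structure(list(ids = gmt_ids, description = gmt_desc,
                              category = gmt_cat, genes = gmt_genes),
                         class = "gene_set_collection")

  manifest <- list(
    true_threshold_survivors = ids[survives],
    expected_kept = sort(union(ids[survives], whitelist)),
    planted_module = module,
    planted_terms = gmt_ids[grepl("^PLANTED", gmt_ids)],
    parameters = unclass(cfg))

  bundle <- structure(list(compounds = compounds, ct_map = ct_map,
                           ppi = ppi, disease_lists = disease_lists,
                           gene_sets = gene_sets, whitelist = whitelist,
                           manifest = manifest, cfg = cfg),
                      class = "synthetic_bundle")
  if (!is.null(dir)) {
    bundle$paths <- write_bundle(bundle, dir)
  }
  bundle
}

#' Write a synthetic bundle to disk
#'
#' Emits exactly the formats the readers in this package consume:
#' `compounds.tsv`, `ct_map.tsv`, `ppi_edges.tsv`, one
#' `disease_<source>.tsv` per source, `gene_sets.gmt`,
#' `whitelist.txt` and `manifest.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    compounds = file.path(dir, "compounds.tsv"),
    ct_map = file.path(dir, "ct_map.tsv"),
    ppi = file.path(dir, "ppi_edges.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    whitelist = file.path(dir, "whitelist.txt"),
    manifest = file.path(dir, "manifest.json"))
  write_compound_table(bundle$compounds, paths$compounds)
  utils::write.table(bundle$ct_map, paths$ct_map, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_network(bundle$ppi, paths$ppi, format = "tsv")
  write_gmt(bundle$gene_sets, paths$gene_sets)
  writeLines(bundle$whitelist, paths$whitelist)
  disease <- list()
  for (s in names(bundle$disease_lists)) {
    p <- file.path(dir, paste0("disease_", s, ".tsv"))
    writeLines(c("symbol", bundle$disease_lists[[s]]), p)
    disease[[s]] <- p
  }
  paths$disease <- disease
  jsonlite::write_json(bundle$manifest, paths$manifest,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}

#' Independent recount of a bundle's headline statistics
#'
#' Recomputes, by naive enumeration over the raw bundle tables and
#' edge lists (never through the pipeline code paths), the statistics
#' the pipeline reports: the kept/excluded screening split, bipartite
#' node and edge counts, the merged disease-target count, the
#' putative/disease overlap, the two seed-network sizes and the size
#' of their intersection. Used as the equivalence oracle in tests.
#'
#' @param bundle A `synthetic_bundle`.
#' @return Named list of counts.
#' @export
recount_oracle <- function(bundle) {
  cpd <- bundle$compounds
  ob <- cpd$ob; dl <- cpd$dl
  kept_rule <- (!is.na(dl) & !is.na(ob) & ob >= 30 & dl >= 0.18) |
    (is.na(dl) & !is.na(ob) & ob >= 35)
  kept_ids <- unique(c(cpd$compound_id[kept_rule],
                       intersect(bundle$whitelist, cpd$compound_id)))
  map <- unique(bundle$ct_map[bundle$ct_map$compound_id %in% kept_ids,
                              , drop = FALSE])
  mapped <- unique(map$compound_id)
  putative <- unique(toupper(trimws(map$target)))
  merged <- unique(toupper(trimws(unlist(bundle$disease_lists,
                                         use.names = FALSE))))
  el <- igraph::as_edgelist(bundle$ppi)
  seed_net_size <- function(seeds) {
    seeds <- intersect(seeds, unique(c(el[, 1], el[, 2],
                                       igraph::V(bundle$ppi)$name)))
    touch <- el[, 1] %in% seeds | el[, 2] %in% seeds
    nodes <- unique(c(seeds, el[touch, 1], el[touch, 2]))
    inside <- el[, 1] %in% nodes & el[, 2] %in% nodes
    list(nodes = sort(nodes),
         edges = sort(paste(pmin(el[inside, 1], el[inside, 2]),
                            pmax(el[inside, 1], el[inside, 2]))))
  }
  a <- seed_net_size(putative)
  b <- seed_net_size(merged)
  list(n_kept = length(kept_ids),
       n_excluded = nrow(cpd) - length(kept_ids),
       n_mapped_compounds = length(mapped),
       n_putative_targets = length(putative),
       n_bipartite_nodes = length(mapped) + length(putative),
       n_bipartite_edges = nrow(map),
       n_merged_disease = length(merged),
       n_overlap = length(intersect(putative, merged)),
       putative_net_nodes = length(a$nodes),
       putative_net_edges = length(a$edges),
       disease_net_nodes = length(b$nodes),
       disease_net_edges = length(b$edges),
       intersection_nodes = length(intersect(a$nodes, b$nodes)),
       intersection_edges = length(intersect(a$edges, b$edges)))
}

#' Jaccard similarity of two sets
#'
#' @param a,b Character vectors.
#' @return `|a intersect b| / |a union b|`; 1 when both are empty.
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("synthetic_bundle: ", nrow(x$compounds), " compounds, ",
      igraph::vcount(x$ppi), "-node PPI, module of ",
      length(x$manifest$planted_module), ", ",
      length(x$disease_lists), " disease sources, ",
      length(x$gene_sets$ids), " terms (seed ", x$cfg$seed, ")\n",
      sep = "")
  invisible(x)
}
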