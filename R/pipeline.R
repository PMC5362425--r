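default_params <- function() {
  list(ob_min = 30, dl_min = 0.18, ob_min_no_dl = 35,
       alpha = 0.05, kappa_min = 0.4, expansion = "neighbors",
       enrich_by_category = TRUE)
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cfg <- do.call(synthetic_config, sim[names(sim) %in%
                                           names(formals(synthetic_config))])
    bundle <- simulate_bundle(cfg)
    return(list(compounds = bundle$compounds, ct_map = bundle$ct_map,
                ppi = bundle$ppi, disease_lists = bundle$disease_lists,
                gene_sets = bundle$gene_sets,
                whitelist = bundle$whitelist, bundle = bundle))
  }
  inp <- config$inputs
  needed <- c("compounds", "ct_map", "ppi", "disease", "gene_sets")
  for (key in needed) {
    if (is.null(inp[[key]])) {
      stop("config is missing required input ", dQuote(key))
    }
  }
  paths <- c(inp$compounds, inp$ct_map, inp$ppi, inp$gene_sets,
             unlist(inp$disease), inp$whitelist)
  absent <- paths[!file.exists(paths)]
  if (length(absent) > 0) {
    stop("input file(s) not found: ", paste(absent, collapse = ", "))
  }
  if (is.null(names(inp$disease)) || any(!nzchar(names(inp$disease)))) {
    stop("disease inputs must be a named source -> path mapping")
  }
  list(compounds = read_compound_table(inp$compounds),
       ct_map = read_ct_map(inp$ct_map),
       ppi = read_ppi_edges(inp$ppi),
       disease_lists = lapply(inp$disease, read_gene_list),
       gene_sets = read_gmt(inp$gene_sets),
       whitelist = if (is.null(inp$whitelist)) character(0)
                   else read_whitelist(inp$whitelist),
       bundle = NULL)
}

#' Run the full target-identification pipeline
#'
#' Executes the stages in order: compound screening; compound-target
#' network construction; disease-target merging and overlap;
#' seed-expanded PPI network construction for the putative and the
#' disease targets; network intersection; the two-stage topological
#' filter; hypergeometric enrichment of the candidate targets with
#' kappa term grouping. Inputs come either from files named in the
#' config or from the seeded synthetic generator (a `simulate` block),
#' so a fixed config always reproduces the identical report.
#'
#' @param config Path to a YAML config file, or an equivalent list.
#'   Recognized blocks: `simulate` ([synthetic_config()] fields),
#'   `inputs` (`compounds`, `ct_map`, `ppi`, `disease` = named
#'   source->path map, `gene_sets`, optional `whitelist`) and `params`
#'   (`ob_min` 30, `dl_min` 0.18, `ob_min_no_dl` 35, `alpha` 0.05,
#'   `kappa_min` 0.4, `expansion`, `enrich_by_category`).
#' @param out_dir Optional output directory; when given, stage outputs
#'   (networks as GraphML, candidate and enrichment tables as TSV,
#'   thresholds and the run report as JSON) are written there.
#' @return A `pipeline_report`: list with one element per stage
#'   (counts, thresholds, parameters) plus `candidates`, `enrichment`,
#'   `groups` and, for simulated runs, `recovery` (Jaccard of
#'   candidates vs the planted module and the enrichment status of the
#'   planted terms).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  params <- utils::modifyList(default_params(),
                              if (is.null(config$params)) list()
                              else config$params)
  inputs <- load_pipeline_inputs(config)

  note <- function(...) message("[netpharm] ", ...)

  note("stage 1/8: compound screening")
  screen <- screen_compounds(inputs$compounds, ob_min = params$ob_min,
                             dl_min = params$dl_min,
                             ob_min_no_dl = params$ob_min_no_dl,
                             whitelist = inputs$whitelist)

  note("stage 2/8: compound-target network")
  ct <- build_bipartite(screen$kept, inputs$ct_map)
  ct_stats <- bipartite_stats(ct, kept = screen$kept)

  note("stage 3/8: disease-target merge and overlap")
  disease <- merge_disease_targets(inputs$disease_lists)
  shared <- overlap_targets(ct$targets, disease)

  note("stage 4/8: seed-expanded PPI networks")
  put_net <- build_seed_network(ct$targets, inputs$ppi,
                                expansion = params$expansion)
  dis_net <- build_seed_network(disease$symbols, inputs$ppi,
                                expansion = params$expansion)

  note("stage 5/8: network intersection")
  inter <- intersect_networks(put_net, dis_net)

  note("stage 6/8: stage-1 degree filter")
  note("stage 7/8: stage-2 six-measure filter")
  filt <- filter_targets(inter)

  note("stage 8/8: enrichment")
  universe <- intersect(
    unique(unlist(inputs$gene_sets$genes, use.names = FALSE)),
    igraph::V(inter)$name)
  enr <- NULL; groups <- NULL
  if (length(filt$candidates) > 0 && length(universe) > 0) {
    enr <- hypergeom_enrich(filt$candidates, inputs$gene_sets,
                            universe = universe, alpha = params$alpha,
                            by_category = params$enrich_by_category)
    groups <- kappa_group_terms(enr[enr$enriched, , drop = FALSE],
                                inputs$gene_sets, reference = universe,
                                kappa_min = params$kappa_min)
  }

  report <- list(
    params = params,
    stages = list(
      screen = list(n_input = nrow(inputs$compounds),
                    n_kept = nrow(screen$kept),
                    n_excluded = nrow(screen$excluded),
                    reasons = as.list(table(screen$kept$reason)),
                    per_herb = as.list(screen$per_herb_counts)),
      ct_network = ct_stats[c("n_nodes", "n_edges", "n_compounds",
                              "n_targets", "n_unmapped",
                              "median_compound_degree",
                              "n_nodes_herb_expanded")],
      disease = list(n_sources = length(disease$by_source),
                     by_source = as.list(lengths(disease$by_source)),
                     n_merged = length(disease$symbols),
                     n_overlap = length(shared)),
      ppi = list(putative_nodes = igraph::vcount(put_net),
                 putative_edges = igraph::ecount(put_net),
                 disease_nodes = igraph::vcount(dis_net),
                 disease_edges = igraph::ecount(dis_net),
                 missing_putative_seeds =
                   length(igraph::graph_attr(put_net, "missing_seeds")),
                 missing_disease_seeds =
                   length(igraph::graph_attr(dis_net, "missing_seeds"))),
      intersection = list(n_nodes = igraph::vcount(inter),
                          n_edges = igraph::ecount(inter)),
      filter = list(n_significant = length(filt$significant),
                    significant_edges =
                      igraph::ecount(filt$significant_network),
                    n_candidates = length(filt$candidates)),
      enrichment = list(
        n_universe = length(universe),
        n_terms_tested = if (is.null(enr)) 0L else nrow(enr),
        n_enriched = if (is.null(enr)) 0L else sum(enr$enriched),
        n_groups = if (is.null(groups) || nrow(groups$groups) == 0) 0L
                   else length(unique(groups$groups$group)))),
    thresholds = filt$thresholds,
    shared_targets = shared,
    candidates = filt$candidates,
    enrichment = enr,
    groups = groups)

  if (!is.null(inputs$bundle)) {
    man <- inputs$bundle$manifest
    planted <- man$planted_terms
    flagged <- if (is.null(enr)) character(0)
               else enr$term_id[enr$enriched]
    report$recovery <- list(
      module_jaccard = jaccard(filt$candidates, man$planted_module),
      planted_terms = planted,
      planted_terms_enriched = intersect(planted, flagged),
      manifest = man)
  }
  class(report) <- "pipeline_report"

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_network(inter, file.path(out_dir, "intersection.graphml"),
                  "graphml")
    write_network(filt$significant_network,
                  file.path(out_dir, "significant.graphml"), "graphml")
    writeLines(c("symbol", filt$candidates),
               file.path(out_dir, "candidates.tsv"))
    if (!is.null(enr)) {
      utils::write.table(enr, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(report$thresholds,
                         file.path(out_dir, "thresholds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(report[c("params", "stages", "thresholds")],
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Tabulate every threshold a pipeline run used
#'
#' One row per cutoff, with its value and provenance: fixed by the
#' configuration (`config`) or computed from the data as a median
#' (`computed`).
#'
#' @param report A `pipeline_report` from [run_pipeline()].
#' @return data.frame with columns `threshold`, `value`, `provenance`.
#' @export
explain_thresholds <- function(report) {
  stopifnot(inherits(report, "pipeline_report"))
  p <- report$params
  th <- report$thresholds
  rows <- data.frame(
    threshold = c("ob_min", "dl_min", "ob_min_no_dl",
                  "stage1_median_degree", "stage1_cut"),
    value = c(p$ob_min, p$dl_min, p$ob_min_no_dl,
              th$stage1_median_degree, th$stage1_cut),
    provenance = c("config", "config", "config", "computed", "computed"),
    stringsAsFactors = FALSE)
  if (!is.null(th$stage2_medians)) {
    med <- th$stage2_medians
    rows <- rbind(rows, data.frame(
      threshold = paste0("stage2_median_", names(med)),
      value = unlist(med), provenance = "computed",
      stringsAsFactors = FALSE))
  }
  rows <- rbind(rows, data.frame(
    threshold = c("alpha", "kappa_min"),
    value = c(p$alpha, p$kappa_min),
    provenance = c("config", "config"), stringsAsFactors = FALSE))
  rownames(rows) <- NULL
  rows
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$stages
  cat("pipeline_report\n",
      "  kept compounds:      ", s$screen$n_kept, "/", s$screen$n_input, "\n",
      "  compound-target net: ", s$ct_network$n_nodes, " nodes, ",
      s$ct_network$n_edges, " edges\n",
      "  disease targets:     ", s$disease$n_merged, " merged, ",
      s$disease$n_overlap, " shared with putative\n",
      "  intersection:        ", s$intersection$n_nodes, " nodes, ",
      s$intersection$n_edges, " edges\n",
      "  significant targets: ", s$filter$n_significant, "\n",
      "  candidate targets:   ", s$filter$n_candidates, "\n",
      "  enriched terms:      ", s$enrichment$n_enriched, " in ",
      s$enrichment$n_groups, " group(s)\n", sep = "")
  invisible(x)
}
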