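test_that("configuration validation rejects infeasible settings", {
  expect_error(synthetic_config(planted_module_size = 400),
               "module larger than the PPI")
  expect_error(synthetic_config(missing_dl_fraction = 1.5), "\\[0,1\\]")
  expect_error(synthetic_config(n_targets = 500), "target pool")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("the same seed reproduces the bundle byte for byte", {
  cfg <- synthetic_config(seed = 7, ppi_n_nodes = 80,
                          planted_module_size = 8, n_targets = 40,
                          compounds_per_herb = 5)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- simulate_bundle(cfg, dir = d1)
  b2 <- simulate_bundle(cfg, dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  expect_identical(b1$manifest, b2$manifest)
})

test_that("bundle files are readable by the package's own readers", {
  cfg <- synthetic_config(seed = 9, ppi_n_nodes = 80,
                          planted_module_size = 8, n_targets = 40,
                          compounds_per_herb = 5)
  dir <- withr::local_tempdir()
  b <- simulate_bundle(cfg, dir = dir)
  cpd <- read_compound_table(b$paths$compounds)
  expect_equal(cpd$compound_id, b$compounds$compound_id)
  expect_equal(cpd$ob, b$compounds$ob)
  expect_equal(cpd$dl, b$compounds$dl)
  ppi <- read_ppi_edges(b$paths$ppi)
  expect_equal(edge_table(ppi), edge_table(b$ppi))
  sets <- read_gmt(b$paths$gene_sets)
  expect_equal(sets$genes, b$gene_sets$genes)
  expect_setequal(read_whitelist(b$paths$whitelist), b$whitelist)
  for (s in names(b$disease_lists)) {
    expect_equal(read_gene_list(b$paths$disease[[s]]),
                 b$disease_lists[[s]])
  }
})

test_that("generated structures respect the configuration", {
  cfg <- synthetic_config(seed = 13, missing_dl_fraction = 0,
                          ppi_n_nodes = 100, planted_module_size = 10,
                          n_targets = 50, compounds_per_herb = 6)
  b <- simulate_bundle(cfg)
  expect_false(anyNA(b$compounds$dl))
  expect_length(b$manifest$planted_module, 10)
  # manifest sets are subsets of the generated entities
  expect_true(all(b$manifest$planted_module %in%
                    igraph::V(b$ppi)$name))
  expect_true(all(b$manifest$expected_kept %in%
                    b$compounds$compound_id))
  expect_true(all(b$manifest$planted_terms %in% b$gene_sets$ids))
  # PPI is simple
  expect_false(igraph::any_loop(b$ppi))
  expect_false(igraph::any_multiple(b$ppi))
  # planted module is dense: realized density near the configured 0.9
  sub <- igraph::induced_subgraph(b$ppi, b$manifest$planted_module)
  dens <- igraph::ecount(sub) / choose(10, 2)
  expect_gt(dens, 0.7)
})

test_that("pipeline counts equal the naive recount oracle", {
  for (seed in c(3, 14)) {
    cfg <- synthetic_config(seed = seed, ppi_n_nodes = 120,
                            planted_module_size = 10, n_targets = 60,
                            compounds_per_herb = 8)
    b <- simulate_bundle(cfg)
    oracle <- recount_oracle(b)
    scr <- suppressWarnings(
      screen_compounds(b$compounds, whitelist = b$whitelist))
    expect_equal(nrow(scr$kept), oracle$n_kept)
    expect_equal(nrow(scr$excluded), oracle$n_excluded)
    ct <- suppressWarnings(build_bipartite(scr$kept, b$ct_map))
    s <- bipartite_stats(ct)
    expect_equal(s$n_compounds + s$n_targets, oracle$n_bipartite_nodes)
    expect_equal(s$n_edges, oracle$n_bipartite_edges)
    dis <- merge_disease_targets(b$disease_lists)
    expect_length(dis$symbols, oracle$n_merged_disease)
    expect_length(overlap_targets(ct$targets, dis), oracle$n_overlap)
    pn <- build_seed_network(ct$targets, b$ppi)
    dn <- build_seed_network(dis$symbols, b$ppi)
    expect_equal(igraph::vcount(pn), oracle$putative_net_nodes)
    expect_equal(igraph::ecount(pn), oracle$putative_net_edges)
    expect_equal(igraph::vcount(dn), oracle$disease_net_nodes)
    expect_equal(igraph::ecount(dn), oracle$disease_net_edges)
    inter <- intersect_networks(pn, dn)
    expect_equal(igraph::vcount(inter), oracle$intersection_nodes)
    expect_equal(igraph::ecount(inter), oracle$intersection_edges)
  }
})

test_that("screening edge configurations recount to all or nothing", {
  cfg <- synthetic_config(seed = 5, ppi_n_nodes = 60,
                          planted_module_size = 6, n_targets = 30,
                          compounds_per_herb = 4,
                          ob_range = c(60, 80), missing_dl_fraction = 0)
  b <- simulate_bundle(cfg)
  # force every DL above threshold: everything passes
  b$compounds$dl <- pmax(b$compounds$dl, 0.2)
  res <- screen_compounds(b$compounds, whitelist = character(0))
  expect_equal(nrow(res$kept), nrow(b$compounds))
})
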