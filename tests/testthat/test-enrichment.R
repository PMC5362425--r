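make_sets <- function(genes, category = NULL) {
  ids <- names(genes)
  structure(list(ids = ids,
                 description = paste("set", ids),
                 category = if (is.null(category)) rep("other", length(ids))
                            else category,
                 genes = genes),
            class = "gene_set_collection")
}

# exact tail by explicit enumeration of choose() ratios
tail_by_enumeration <- function(k, K, n, N) {
  i <- seq(k, min(K, n))
  if (length(i) == 0 || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

test_that("worked hypergeometric case gives 3003/184756", {
  uni <- sprintf("g%02d", 1:20)
  sets <- make_sets(list(T1 = uni[1:5]))
  res <- hypergeom_enrich(uni[1:10], sets, universe = uni)
  expect_equal(res$k, 5)
  expect_equal(res$p, 3003 / 184756, tolerance = 1e-12)
  expect_equal(res$p, choose(15, 5) / choose(20, 10), tolerance = 1e-12)
})

test_that("tail probabilities match enumeration over the full lattice", {
  for (N in c(5, 12, 19, 25)) {
    for (K in 0:N) for (n in 0:N) {
      k <- 0:min(K, n)
      want <- vapply(k, tail_by_enumeration, 0, K = K, n = n, N = N)
      expect_equal(hypergeom_tail(k, K, n, N), want, tolerance = 1e-12)
    }
  }
  # k = 0 has the whole mass
  expect_equal(hypergeom_tail(0, 3, 4, 10), 1)
})

test_that("BH correction follows the step-up procedure per category", {
  uni <- sprintf("g%02d", 1:40)
  # three terms in one category engineered to raw p {0.01-ish ordering}
  sets <- make_sets(list(A = uni[1:6], B = uni[1:12], C = uni[1:20]),
                    category = rep("signaling_pathway", 3))
  res <- hypergeom_enrich(uni[1:8], sets, universe = uni)
  expect_equal(res$p_adj,
               stats::p.adjust(res$p, "BH"), tolerance = 1e-12)
  expect_true(all(res$p <= res$p_adj + 1e-15))
  expect_true(all(res$p_adj <= 1))
  expect_true(all(diff(res$p_adj) >= -1e-15))  # ordered by raw p

  # hand-computed step-up: {0.01, 0.02, 0.03} -> {0.03, 0.03, 0.03}
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"),
               rep(0.03, 3))

  # categories are adjusted separately
  sets2 <- make_sets(list(A = uni[1:6], B = uni[1:12], C = uni[1:20]),
                     category = c("signaling_pathway",
                                  "molecular_function_biological_process",
                                  "signaling_pathway"))
  res2 <- hypergeom_enrich(uni[1:8], sets2, universe = uni)
  for (cat in unique(res2$category)) {
    idx <- res2$category == cat
    expect_equal(res2$p_adj[idx], stats::p.adjust(res2$p[idx], "BH"),
                 tolerance = 1e-12)
  }
  pooled <- hypergeom_enrich(uni[1:8], sets2, universe = uni,
                             by_category = FALSE)
  expect_equal(pooled$p_adj, stats::p.adjust(pooled$p, "BH"),
               tolerance = 1e-12)
})

test_that("universe restriction and degenerate terms are handled", {
  uni <- sprintf("g%02d", 1:15)
  sets <- make_sets(list(T1 = c(uni[1:4], "OUTSIDE1"),
                         T2 = c("OUTSIDE2", "OUTSIDE3")))
  msgs <- testthat::capture_messages(
    res <- hypergeom_enrich(c(uni[1:5], "NOTINUNI"), sets,
                            universe = uni))
  expect_true(any(grepl("outside the universe", msgs)))
  expect_true(any(grepl("skipped", msgs)))
  expect_equal(nrow(res), 1)            # T2 skipped (K = 0)
  expect_equal(res$K, 4)                # OUTSIDE1 not counted
  expect_equal(res$n, 5)
  expect_equal(res$N, 15)
  expect_equal(res$k, 4)
  expect_error(hypergeom_enrich("A", sets, universe = character(0)),
               "empty universe")
})

test_that("kappa agrees with 2x2-table arithmetic", {
  ref <- sprintf("r%03d", 1:100)
  # a=10, b=5, c=5, d=80 -> po=0.90, pe=0.745, kappa ~ 0.6078
  sa <- ref[1:15]                        # a + b
  sb <- c(ref[1:10], ref[16:20])         # a + c
  expect_equal(cohen_kappa(sa, sb, ref), (0.90 - 0.745) / (1 - 0.745),
               tolerance = 1e-12)
  # disjoint 15-gene sets: a=0, d=70 -> kappa < 0
  expect_lt(cohen_kappa(ref[1:15], ref[16:30], ref), 0)
  # identical restricted memberships give exactly 1
  expect_equal(cohen_kappa(ref[1:7], ref[1:7], ref), 1)
  # symmetry and relabel invariance
  set.seed(71)
  for (i in 1:10) {
    x <- sample(ref, 20); y <- sample(ref, 30)
    expect_equal(cohen_kappa(x, y, ref), cohen_kappa(y, x, ref))
    perm <- sample(ref)
    expect_equal(cohen_kappa(x, y, ref), cohen_kappa(x, y, perm))
  }
  # pe = 1 when both sets cover the whole reference
  expect_equal(cohen_kappa(ref, ref, ref), 1)
})

test_that("kappa grouping links terms and picks leading terms", {
  ref <- sprintf("r%03d", 1:100)
  sets <- make_sets(list(A = ref[1:15],
                         B = c(ref[1:10], ref[16:20]),  # kappa ~ 0.61 vs A
                         C = ref[40:54]))               # disjoint
  res <- data.frame(term_id = c("A", "B", "C"),
                    p_adj = c(0.01, 0.001, 0.02),
                    stringsAsFactors = FALSE)
  grp <- kappa_group_terms(res, sets, reference = ref)
  g <- grp$groups
  expect_equal(g$group[g$term_id == "A"], g$group[g$term_id == "B"])
  expect_false(g$group[g$term_id == "C"] == g$group[g$term_id == "A"])
  expect_true(g$leading[g$term_id == "B"])   # smallest p_adj in group
  expect_false(g$leading[g$term_id == "A"])
  expect_true(g$leading[g$term_id == "C"])   # singleton leads itself
  expect_equal(nrow(grp$links), 1)
  expect_gte(grp$links$kappa, 0.4)

  # tie on p_adj -> lexicographically smallest term id leads
  sets2 <- make_sets(list(A = ref[1:15], B = ref[1:15]))
  res2 <- data.frame(term_id = c("B", "A"), p_adj = c(0.01, 0.01),
                     stringsAsFactors = FALSE)
  g2 <- kappa_group_terms(res2, sets2, reference = ref)$groups
  expect_true(g2$leading[g2$term_id == "A"])
  expect_false(g2$leading[g2$term_id == "B"])

  empty <- kappa_group_terms(res[0, ], sets, reference = ref)
  expect_equal(nrow(empty$groups), 0)
})
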