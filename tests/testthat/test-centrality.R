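test_that("closed forms hold on stars, triangles and paths", {
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("C", "L1", "L2", "L3", "L4")
  tab <- compute_centralities(star)
  centre <- tab[tab$node == "C", ]
  expect_equal(centre$dc, 4)
  expect_equal(centre$bc, 6)      # all C(4,2) leaf pairs route via C
  expect_equal(centre$cc, 1)
  expect_equal(centre$nc, 0)      # no triangles
  expect_equal(centre$lac, 0)
  leaf <- tab[tab$node == "L1", ]
  expect_equal(leaf$bc, 0)
  expect_equal(leaf$cc, 4 / 7)

  k3 <- igraph::make_full_graph(3)
  igraph::V(k3)$name <- c("A", "B", "C")
  t3 <- compute_centralities(k3)
  expect_equal(t3$dc, rep(2, 3))
  expect_equal(t3$bc, rep(0, 3))
  expect_equal(t3$cc, rep(1, 3))
  expect_equal(t3$ec, rep(1 / sqrt(3), 3), tolerance = 1e-10)
  expect_equal(round(t3$ec, 5), rep(0.57735, 3))
  expect_equal(t3$nc, rep(2, 3))  # each edge in 1 triangle, denom 1
  expect_equal(t3$lac, rep(1, 3))

  p3 <- graph_from_symbol_pairs(c("A", "B"), c("B", "C"))
  tp <- compute_centralities(p3)
  expect_equal(tp$bc[tp$node == "B"], 1)
})

test_that("all six measures match the brute-force oracle", {
  set.seed(51)
  for (i in 1:60) {
    A <- random_adjacency(sample(2:30, 1), runif(1, 0.05, 0.6))
    expect_centralities_match(A, tol = 1e-8)
  }
})

test_that("measure-level invariants hold on random graphs", {
  set.seed(52)
  for (i in 1:20) {
    A <- random_adjacency(sample(3:25, 1), runif(1, 0.1, 0.5))
    g <- graph_from_adjacency(A)
    tab <- compute_centralities(g)
    expect_equal(sum(tab$dc), 2 * igraph::ecount(g))
    expect_true(all(tab$bc >= 0))
    expect_true(all(tab$cc >= 0 & tab$cc <= 1))
    expect_true(all(tab$nc <= tab$dc + 1e-12))
    expect_true(all(tab$lac <= pmax(tab$dc - 1, 0) + 1e-12))
    # unit Euclidean norm of the eigenvector within each component
    comp <- igraph::components(g)$membership
    for (c0 in unique(comp)) {
      expect_equal(sum(tab$ec[comp == c0]^2), 1, tolerance = 1e-9)
    }
    # relabeling permutes the table identically
    perm <- sample(nrow(A))
    B <- A[perm, perm]
    tb <- compute_centralities(graph_from_adjacency(B))
    tb <- tb[match(tab$node, tb$node), ]
    for (m in c("dc", "bc", "cc", "ec", "nc", "lac")) {
      expect_equal(tb[[m]], tab[[m]], tolerance = 1e-9,
                   ignore_attr = TRUE)
    }
  }
})

test_that("betweenness vanishes on complete graphs", {
  for (n in c(4, 6)) {
    g <- igraph::make_full_graph(n)
    igraph::V(g)$name <- as.character(seq_len(n))
    expect_equal(compute_centralities(g)$bc, rep(0, n))
  }
})

test_that("disconnected graphs get per-component closeness and EC", {
  # triangle plus an isolated edge plus an isolated node
  g <- graph_from_symbol_pairs(c("A", "B", "C", "X"),
                               c("B", "C", "A", "Y"))
  g <- igraph::add_vertices(g, 1, name = "Z")
  tab <- compute_centralities(g)
  expect_equal(tab$cc[tab$node == "Z"], 0)
  expect_equal(tab$ec[tab$node == "Z"], 1)   # its own component
  expect_equal(tab$cc[tab$node == "X"], 1)   # 2-node component
  expect_equal(tab$ec[tab$node == "X"], 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(tab$bc, rep(0, 6))
})

test_that("median_of follows the mean-of-middle-two convention", {
  expect_equal(median_of(c(1, 2, 3)), 2)
  expect_equal(median_of(c(1, 2, 3, 4)), 2.5)
  expect_equal(median_of(5), 5)
  expect_error(median_of(numeric(0)), "empty")
})

test_that("degenerate graphs are handled or rejected explicitly", {
  expect_error(compute_centralities(igraph::make_empty_graph(0)),
               "no nodes")
  one <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(one)$name <- "A"
  tab <- compute_centralities(one)
  expect_equal(tab[, c("dc", "bc", "cc", "nc", "lac")],
               data.frame(dc = 0, bc = 0, cc = 0, nc = 0, lac = 0),
               ignore_attr = TRUE)
})
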