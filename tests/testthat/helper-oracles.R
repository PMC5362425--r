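# Brute-force oracles, deliberately independent of the package's code
# paths: distances and shortest-path counts come from adjacency-matrix
# powers, eigenvectors from base eigen(), triangles from explicit
# loops.

random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  if (n > 1) {
    up <- which(upper.tri(A))
    A[up] <- as.numeric(stats::runif(length(up)) < p)
    A <- A + t(A)
  }
  dimnames(A) <- list(sprintf("N%02d", 1:n), sprintf("N%02d", 1:n))
  A
}

graph_from_adjacency <- function(A) {
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# distance matrix and shortest-path counts: the number of walks of
# minimal length between two nodes equals the number of shortest paths
oracle_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- diag(n)                       # shortest-path counts
  D[A > 0] <- 1
  S[A > 0] <- A[A > 0]
  Ak <- A
  k <- 1
  while (k < n && any(is.infinite(D[upper.tri(D)]))) {
    Ak <- Ak %*% A
    k <- k + 1
    new <- is.infinite(D) & Ak > 0
    D[new] <- k
    S[new] <- Ak[new]
    diag(D) <- 0
  }
  list(D = D, S = S)
}

oracle_centralities <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  ps <- oracle_paths(A)
  D <- ps$D; S <- ps$S
  bc <- numeric(n)
  for (v in seq_len(n)) {
    through <- outer(D[, v], D[v, ], `+`) == D & is.finite(D)
    cnt <- outer(S[, v], S[v, ]) / ifelse(S > 0, S, 1)
    contrib <- ifelse(through, cnt, 0)
    contrib[v, ] <- 0; contrib[, v] <- 0; diag(contrib) <- 0
    bc[v] <- sum(contrib[upper.tri(contrib)])
  }
  cc <- vapply(seq_len(n), function(v) {
    dv <- D[v, -v]; dv <- dv[is.finite(dv)]
    if (length(dv) == 0) 0 else length(dv) / sum(dv)
  }, 0)
  # eigenvector per connected component via base eigen()
  comp <- rep(NA_integer_, n); cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1
      comp[is.finite(D[v, ])] <- cid
    }
  }
  ec <- numeric(n)
  for (c0 in unique(comp)) {
    idx <- which(comp == c0)
    if (length(idx) == 1) { ec[idx] <- 1; next }
    e <- eigen(A[idx, idx], symmetric = TRUE)
    v1 <- abs(e$vectors[, which.max(e$values)])
    ec[idx] <- v1 / sqrt(sum(v1^2))
  }
  # triangles per edge by explicit loop
  nc <- numeric(n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u < v && A[u, v] > 0) {
      z <- 0
      for (w in seq_len(n)) if (A[u, w] > 0 && A[v, w] > 0) z <- z + 1
      dmin <- min(deg[u], deg[v]) - 1
      ecc <- if (dmin > 0) z / dmin else 0
      nc[u] <- nc[u] + ecc; nc[v] <- nc[v] + ecc
    }
  }
  lac <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) next
    tot <- 0
    for (u in nb) tot <- tot + sum(A[u, nb])
    lac[v] <- tot / length(nb)
  }
  data.frame(node = rownames(A), dc = deg, bc = bc, cc = cc, ec = ec,
             nc = nc, lac = lac, stringsAsFactors = FALSE,
             row.names = NULL)
}

expect_centralities_match <- function(A, tol = 1e-8) {
  got <- compute_centralities(graph_from_adjacency(A))
  want <- oracle_centralities(A)
  got <- got[match(want$node, got$node), ]
  for (m in c("dc", "bc", "cc", "ec", "nc", "lac")) {
    expect_equal(got[[m]], want[[m]], tolerance = tol,
                 ignore_attr = TRUE, label = paste("measure", m))
  }
}

# random compound tables exercising the screening boundaries
random_compound_table <- function(n, herbs = c("H1", "H2", "H3")) {
  ob_pool <- c(29.9, 30, 30.1, 34.9, 35, 36, NA,
               round(stats::runif(3, 0, 80), 2))
  dl_pool <- c(0.17, 0.18, 0.19, NA, NA,
               round(stats::runif(3, 0, 1), 3))
  df <- data.frame(compound_id = sprintf("X%03d", seq_len(n)),
                   name = sprintf("cpd%03d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df$herbs <- replicate(n, sample(herbs, sample(1:2, 1)),
                        simplify = FALSE)
  df$ob <- sample(ob_pool, n, replace = TRUE)
  df$dl <- sample(dl_pool, n, replace = TRUE)
  df$rescued <- FALSE
  df$rescue_note <- ""
  validate_compound_table(df)
}

# literal vectorized restatement of the screening rule
oracle_screen <- function(df, ob_min = 30, dl_min = 0.18,
                          ob_min_no_dl = 35, whitelist = character(0)) {
  rule <- (!is.na(df$dl) & !is.na(df$ob) &
             df$ob >= ob_min & df$dl >= dl_min) |
    (is.na(df$dl) & !is.na(df$ob) & df$ob >= ob_min_no_dl)
  df$compound_id[rule | df$compound_id %in% whitelist]
}
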