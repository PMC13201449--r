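# Brute-force oracles, independent of the package implementation (and of
# igraph): everything is computed from a plain adjacency matrix with
# Floyd-Warshall distances, a path-count DP, dense eigen(), and explicit
# triangle counting.

# All-pairs hop distances by Floyd-Warshall.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Shortest-path counts sigma[s, t] by distance-layered DP.
oracle_sigma <- function(A, D) {
  n <- nrow(A)
  sigma <- diag(1, n)
  maxd <- max(D[is.finite(D)])
  if (maxd >= 1) {
    for (L in seq_len(maxd)) {
      M <- (sigma * (D == L - 1)) %*% A
      sigma[D == L] <- M[D == L]
    }
  }
  sigma
}

# Raw betweenness: each unordered pair counted once, endpoints excluded.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  sigma <- oracle_sigma(A, D)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    on_path <- outer(D[, v], D[v, ], `+`) == D & is.finite(D)
    contrib <- outer(sigma[, v], sigma[v, ]) / sigma
    contrib[!on_path | sigma == 0] <- 0
    contrib[v, ] <- 0
    contrib[, v] <- 0
    diag(contrib) <- 0
    btw[v] <- sum(contrib[upper.tri(contrib)])
  }
  btw
}

oracle_aspl_closeness <- function(A) {
  D <- oracle_distances(A)
  aspl <- apply(D, 1, function(row) {
    r <- row[is.finite(row) & row > 0]
    if (length(r) == 0) NA_real_ else mean(r)
  })
  list(aspl = aspl, closeness = ifelse(is.na(aspl), 0, 1 / aspl))
}

# Components by plain BFS; returns membership vector.
oracle_components <- function(A) {
  n <- nrow(A)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] > 0 & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Principal eigenvector (unit 2-norm, non-negative) of the largest
# component via dense eigen-decomposition; other components get 0.
oracle_eigenvector <- function(A) {
  n <- nrow(A)
  comp <- oracle_components(A)
  sizes <- tabulate(comp)
  lcc <- which(comp == which.max(sizes))
  x <- numeric(n)
  if (length(lcc) == 1) {
    x[lcc] <- 1
    return(x)
  }
  ev <- eigen(A[lcc, lcc, drop = FALSE], symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- abs(v) / sqrt(sum(v^2))
  x[lcc] <- v
  x
}

# LAC and NC by explicit neighbourhood/triangle enumeration.
oracle_lac_nc <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A)
  lac <- numeric(n)
  nc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) next
    sub <- A[nb, nb, drop = FALSE]
    lac[v] <- mean(rowSums(sub))
    for (u in nb) {
      tri <- sum(A[v, ] > 0 & A[u, ] > 0)  # common neighbours of edge (v,u)
      denom <- min(deg[v] - 1, deg[u] - 1)
      if (denom > 0) nc[v] <- nc[v] + tri / denom
    }
  }
  list(lac = lac, nc = nc)
}

# Exact hypergeometric upper tail by direct binomial-coefficient summation.
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Adjacency matrix of an Erdos-Renyi G(n, p) draw.
random_adjacency <- function(n, p) {
  A <- matrix(0, n, n)
  up <- upper.tri(A)
  A[up] <- as.numeric(stats::runif(sum(up)) < p)
  A + t(A)
}

# igraph object from an adjacency matrix, nodes named V1..Vn.
graph_from_adj <- function(A) {
  dimnames(A) <- list(paste0("V", seq_len(nrow(A))),
                      paste0("V", seq_len(nrow(A))))
  igraph::graph_from_adjacency_matrix(A, mode = "undirected")
}

# Compare a centrality_profile() output with all oracles on one adjacency
# matrix; eigenvector is only compared when the largest component is unique.
expect_profile_matches_oracles <- function(A, tol = 1e-8) {
  g <- graph_from_adj(A)
  prof <- centrality_profile(g)
  ord <- match(paste0("V", seq_len(nrow(A))), prof$node_id)
  prof <- prof[ord, ]
  expect_equal(prof$degree, unname(rowSums(A)), ignore_attr = TRUE)
  expect_equal(prof$betweenness, oracle_betweenness(A), tolerance = tol,
               ignore_attr = TRUE)
  oc <- oracle_aspl_closeness(A)
  expect_equal(prof$closeness, unname(oc$closeness), tolerance = tol,
               ignore_attr = TRUE)
  ln <- oracle_lac_nc(A)
  expect_equal(prof$lac, ln$lac, tolerance = tol, ignore_attr = TRUE)
  expect_equal(prof$nc, ln$nc, tolerance = tol, ignore_attr = TRUE)
  comp <- oracle_components(A)
  sizes <- tabulate(comp)
  if (sum(sizes == max(sizes)) == 1) {
    expect_equal(prof$eigenvector, oracle_eigenvector(A), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  invisible(prof)
}

# Every labeled simple graph on n nodes (n small), as adjacency matrices.
all_labeled_graphs <- function(n) {
  m <- n * (n - 1) / 2
  lapply(seq_len(2^m) - 1, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(m)]
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- bits
    A + t(A)
  })
}
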