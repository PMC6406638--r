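# Independent brute-force oracles used to cross-check the package's
# estimators on small instances. Deliberately naive implementations that
# share no code with the package internals.

# Transfer entropy by materializing the full joint frequency table and
# summing the defining formula term by term.
oracle_te <- function(xs, ys, B) {
  n <- length(xs)
  stopifnot(length(ys) == n)
  x1 <- xs[2:n]; x0 <- xs[1:(n - 1)]; y0 <- ys[1:(n - 1)]
  M <- n - 1
  te <- 0
  for (a in 0:(B - 1)) for (b in 0:(B - 1)) for (c in 0:(B - 1)) {
    p3 <- sum(x1 == a & x0 == b & y0 == c) / M
    if (p3 == 0) next
    px <- sum(x0 == b) / M
    pxy <- sum(x0 == b & y0 == c) / M
    pxx <- sum(x1 == a & x0 == b) / M
    te <- te + p3 * log2(p3 * px / (pxy * pxx))
  }
  te
}

oracle_cond_entropy <- function(xs, B) {
  n <- length(xs)
  x1 <- xs[2:n]; x0 <- xs[1:(n - 1)]
  M <- n - 1
  h <- 0
  for (a in 0:(B - 1)) for (b in 0:(B - 1)) {
    pp <- sum(x1 == a & x0 == b) / M
    if (pp == 0) next
    px <- sum(x0 == b) / M
    h <- h - pp * log2(pp / px)
  }
  h
}

# Breadth-first-search shortest path lengths from every node; adjacency in
# the package's target-row orientation (edge j -> i at [i, j]).
oracle_path_length <- function(adj) {
  n <- nrow(adj)
  dists <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[, u])) {  # u -> v
          if (is.infinite(dist[v])) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
        }
      }
      frontier <- nxt
    }
    dists[s, ] <- dist
  }
  off <- dists[row(dists) != col(dists)]
  list(L = if (any(is.finite(off))) mean(off[is.finite(off)]) else NA_real_,
       frac_unreachable = mean(!is.finite(off)))
}

# Fagiolo directed clustering by explicit triangle enumeration over ordered
# neighbour pairs (no matrix powers).
oracle_clustering <- function(adj) {
  A <- 1 * t(adj)  # [from, to]
  n <- nrow(A)
  S <- A + t(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    tri <- 0
    for (j in seq_len(n)) for (k in seq_len(n)) {
      if (j != i && k != i && j != k) tri <- tri + S[i, j] * S[j, k] * S[k, i]
    }
    tri <- tri / 2
    dt <- sum(A[i, ]) + sum(A[, i])
    db <- sum(A[i, ] * A[, i])
    den <- dt * (dt - 1) - 2 * db
    cc[i] <- if (den > 0) tri / den else 0
  }
  cc
}

# Directed transitivity by explicit path enumeration.
oracle_transitivity <- function(adj) {
  A <- 1 * t(adj)
  n <- nrow(A)
  paths <- 0; closed <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i != j && j != k && i != k && A[i, j] && A[j, k]) {
      paths <- paths + 1
      if (A[i, k]) closed <- closed + 1
    }
  }
  if (paths == 0) 0 else closed / paths
}

# Motif census through igraph: classify each induced 3-node subgraph by
# isomorphism against the igraph representatives of the 16 directed triad
# classes, then map to the package's class order by matching representatives.
oracle_motif_census <- function(adj) {
  reps <- lapply(0:15, function(i) igraph::graph_from_isomorphism_class(3, i, directed = TRUE))
  connected_rep <- vapply(reps, function(g) igraph::is_connected(g, mode = "weak"), logical(1))
  pkg_reps <- lapply(motif_classes(), function(a) {
    igraph::graph_from_adjacency_matrix(a, mode = "directed")
  })
  # bijection igraph class -> package class
  to_pkg <- rep(NA_integer_, 16)
  for (i in which(connected_rep)) {
    for (p in seq_along(pkg_reps)) {
      if (igraph::isomorphic(reps[[i]], pkg_reps[[p]])) { to_pkg[i] <- p; break }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(1 * t(adj), mode = "directed")
  counts <- integer(13)
  n <- nrow(adj)
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(g, tri)
    for (i in seq_along(reps)) {
      if (igraph::isomorphic(sub, reps[[i]])) {
        if (!is.na(to_pkg[i])) counts[to_pkg[i]] <- counts[to_pkg[i]] + 1L
        break
      }
    }
  }
  counts
}

# Random directed graph (no self loops), target-row orientation.
random_digraph <- function(n, p) {
  a <- matrix(stats::runif(n * n) < p, n, n)
  diag(a) <- FALSE
  a
}

# Small synthetic recording with the canonical 14 channels.
toy_recording <- function(n = 1280, fs = 128, ann = NULL, seed = 1) {
  s <- with_seed_test(seed, matrix(stats::rnorm(14 * n), 14))
  rownames(s) <- NTEFBN_CHANNELS
  eeg_recording(s, fs, ann %||% data.frame(state = "rest", start = 1L, end = n))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
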