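complete14 <- function() fbn_digraph(matrix(TRUE, 14, 14))

test_that("binarization uses a strict threshold", {
  m <- matrix(0, 14, 14)
  expect_equal(sum(binarize(m)), 0)
  m[2, 1] <- 0.001; m[3, 1] <- 0.0011
  g <- binarize(m, threshold = 0.001)
  expect_false(g[2, 1])  # exactly at threshold: excluded
  expect_true(g[3, 1])
  expect_equal(sum(binarize(matrix(0.5, 14, 14), 0.001)), 182)
})

test_that("connectivity density spans the unit interval", {
  expect_equal(connectivity_density(complete14()), 1)
  expect_equal(connectivity_density(fbn_digraph(matrix(FALSE, 14, 14))), 0)
  set.seed(1)
  a <- matrix(FALSE, 14, 14)
  a[sample(which(row(a) != col(a)), 91)] <- TRUE
  expect_equal(connectivity_density(fbn_digraph(a)), 0.5)
})

test_that("there are exactly 13 connected 3-node digraph classes", {
  expect_length(motif_classes(), 13)
  # all 64 labelled graphs map to a class or to none (disconnected)
  mm <- ntefbn:::motif_class_map()
  expect_length(mm$map, 64)
  expect_equal(sort(unique(mm$map[!is.na(mm$map)])), 1:13)
  # disconnected labelled graphs: 1 empty + 6 single-edge + 3 mutual-dyad
  expect_equal(sum(is.na(mm$map)), 10)
  # igraph agrees: 16 directed triad classes, 3 of them disconnected
  reps <- lapply(0:15, function(i) igraph::graph_from_isomorphism_class(3, i, directed = TRUE))
  expect_equal(sum(vapply(reps, function(g) igraph::is_connected(g, mode = "weak"),
                          logical(1))), 13)
})

test_that("motif census handles canonical cases", {
  empty <- fbn_digraph(matrix(FALSE, 14, 14))
  expect_equal(motif_census(empty)$total, 0)
  mc <- motif_census(complete14())
  expect_equal(mc$total, choose(14, 3))
  expect_equal(sum(mc$counts > 0), 1)  # every triple is the full bidirectional class
  # single directed 3-cycle
  a <- matrix(FALSE, 3, 3); a[2, 1] <- a[3, 2] <- a[1, 3] <- TRUE
  mc3 <- motif_census(fbn_digraph(a))
  expect_equal(mc3$total, 1)
  expect_equal(sum(mc3$counts > 0), 1)
})

test_that("motif census matches the igraph isomorphism oracle on random graphs", {
  set.seed(42)
  for (p in c(0.1, 0.3, 0.5)) {
    for (rep in 1:34) {
      a <- random_digraph(8, p)
      g <- fbn_digraph(a)
      expect_identical(as.integer(motif_census(g)$counts), oracle_motif_census(a))
    }
  }
})

test_that("motif totals are bounded by the number of triples", {
  set.seed(5)
  for (rep in 1:20) {
    g <- fbn_digraph(random_digraph(14, runif(1, 0.05, 0.6)))
    mc <- motif_census(g)
    expect_lte(mc$total, choose(14, 3))
    expect_equal(mc$total, sum(mc$counts))
  }
})

test_that("directed clustering matches brute-force triangle enumeration", {
  expect_equal(unname(clustering_coefficients(complete14())), rep(1, 14))
  expect_equal(unname(clustering_coefficients(fbn_digraph(matrix(FALSE, 14, 14)))),
               rep(0, 14))
  a <- matrix(FALSE, 3, 3); a[2, 1] <- a[3, 2] <- a[1, 3] <- TRUE
  expect_equal(unname(clustering_coefficients(fbn_digraph(a))), oracle_clustering(a))
  set.seed(6)
  for (rep in 1:40) {
    a <- random_digraph(sample(4:10, 1), runif(1, 0.1, 0.7))
    expect_equal(unname(clustering_coefficients(fbn_digraph(a))),
                 oracle_clustering(a), tolerance = 1e-12)
  }
})

test_that("characteristic path length matches a BFS oracle and flags disconnection", {
  expect_equal(characteristic_path_length(complete14())$L, 1)
  # directed path a -> b -> c: finite dists {1, 1, 2}, 3 of 6 pairs unreachable
  a <- matrix(FALSE, 3, 3); a[2, 1] <- TRUE; a[3, 2] <- TRUE
  pl <- characteristic_path_length(fbn_digraph(a))
  expect_equal(pl$L, 4 / 3)
  expect_equal(pl$frac_unreachable, 0.5)
  empty <- characteristic_path_length(fbn_digraph(matrix(FALSE, 5, 5)))
  expect_false(empty$defined)
  set.seed(7)
  for (rep in 1:40) {
    a <- random_digraph(sample(4:12, 1), runif(1, 0.1, 0.6))
    got <- characteristic_path_length(fbn_digraph(a))
    want <- oracle_path_length(a)
    if (is.na(want$L)) expect_false(got$defined)
    else {
      expect_equal(got$L, want$L, tolerance = 1e-12)
      expect_equal(got$frac_unreachable, want$frac_unreachable)
    }
  }
})

test_that("directed transitivity matches path enumeration and the ER expectation", {
  set.seed(8)
  for (rep in 1:20) {
    a <- random_digraph(sample(4:10, 1), runif(1, 0.2, 0.8))
    expect_equal(transitivity_directed(fbn_digraph(a)), oracle_transitivity(a),
                 tolerance = 1e-12)
  }
  # E[transitivity] ~ p for directed ER: mean over graphs within 3 SE
  p <- 0.3
  vals <- vapply(1:100, function(r) {
    transitivity_directed(fbn_digraph(random_digraph(14, p)))
  }, numeric(1))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - p), 3 * se + 1e-9)
})

test_that("degree-preserving rewiring is seeded and fixes complete graphs", {
  g <- complete14()
  ref <- random_reference(g, n_random = 5, seed = 1)
  expect_equal(ref$C_rand, 1)
  expect_equal(ref$L_rand, 1)
  set.seed(9)
  g2 <- fbn_digraph(random_digraph(14, 0.3))
  r1 <- random_reference(g2, n_random = 10, seed = 7)
  r2 <- random_reference(g2, n_random = 10, seed = 7)
  expect_identical(r1, r2)
  expect_warning(random_reference(fbn_digraph(matrix(FALSE, 14, 14)), 5, 1),
                 "fewer than 2 edges")
  # rewiring preserves in- and out-degree sequences
  ig <- ntefbn:::as_igraph(g2)
  rg <- with_seed_test(3, igraph::rewire(ig, igraph::keeping_degseq(niter = 200)))
  expect_identical(igraph::degree(rg, mode = "in"), igraph::degree(ig, mode = "in"))
  expect_identical(igraph::degree(rg, mode = "out"), igraph::degree(ig, mode = "out"))
})

test_that("small-world index is 1 on complete graphs and detects ring lattices", {
  sw <- small_world_index(complete14(), n_random = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$sigma, (sw$C_d / sw$C_rand) / (sw$L_d / sw$L_rand))

  # directed ring lattice (k = 4 neighbours, both directions) rewired at p = 0.1
  hits <- 0
  for (r in 1:25) {
    ws <- with_seed_test(r, igraph::sample_smallworld(1, 14, 2, 0.1))
    a <- as.matrix(igraph::as_adjacency_matrix(ws)) > 0
    sw <- small_world_index(fbn_digraph(a), n_random = 20, seed = r)
    if (!sw$degenerate && sw$sigma > 1) hits <- hits + 1
  }
  expect_gte(hits, 23)  # >= 95% of seeds in the frozen replicate study

  # a dense random digraph is its own null: sigma near 1
  inside <- 0
  for (r in 1:20) {
    g <- fbn_digraph(with_seed_test(100 + r, random_digraph(14, 0.7)))
    sw <- small_world_index(g, n_random = 20, seed = r)
    if (sw$sigma > 0.9 && sw$sigma < 1.1) inside <- inside + 1
  }
  expect_gte(inside, 18)
})

test_that("node strengths sum incoming and outgoing weights", {
  m <- matrix(0, 14, 14, dimnames = list(NTEFBN_CHANNELS, NTEFBN_CHANNELS))
  m[2, 1] <- 0.5  # channel 1 -> channel 2
  s <- node_strengths(m)
  expect_equal(unname(s[1]), 0.5)
  expect_equal(unname(s[2]), 0.5)
  expect_equal(sum(s), 2 * sum(m))
  set.seed(10)
  w <- matrix(runif(196), 14); diag(w) <- 0
  expect_equal(sum(node_strengths(w)), 2 * sum(w))
  expect_equal(unname(node_strengths(matrix(0, 14, 14))), rep(0, 14))
})

test_that("graph metrics are invariant under node relabelling", {
  set.seed(11)
  a <- random_digraph(14, 0.3)
  perm <- sample(14)
  b <- a[perm, perm]
  expect_equal(connectivity_density(fbn_digraph(a)), connectivity_density(fbn_digraph(b)))
  expect_equal(motif_census(fbn_digraph(a))$counts, motif_census(fbn_digraph(b))$counts)
  expect_equal(transitivity_directed(fbn_digraph(a)), transitivity_directed(fbn_digraph(b)))
  expect_equal(characteristic_path_length(fbn_digraph(a))$L,
               characteristic_path_length(fbn_digraph(b))$L)
  expect_equal(sort(unname(clustering_coefficients(fbn_digraph(a)))),
               sort(unname(clustering_coefficients(fbn_digraph(b)))))
  w <- matrix(runif(196), 14); diag(w) <- 0
  expect_equal(sort(unname(node_strengths(w))), sort(unname(node_strengths(w[perm, perm]))))
})

test_that("digraphs export to GraphML and edge lists", {
  set.seed(12)
  g <- fbn_digraph(random_digraph(14, 0.2))
  p1 <- tempfile(fileext = ".graphml"); p2 <- tempfile(fileext = ".tsv")
  write_graphml(g, p1)
  expect_true(file.exists(p1))
  back <- igraph::read_graph(p1, format = "graphml")
  expect_equal(igraph::ecount(back), sum(g))
  write_edgelist_tsv(g, p2)
  el <- read.delim(p2)
  expect_equal(nrow(el), sum(g))
})
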