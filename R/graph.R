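#' Binary directed functional brain network
#'
#' `binarize()` thresholds an NTE matrix into a binary digraph: edge
#' `j -> i` exists iff `value[i, j] > threshold` (strictly; entries equal to
#' the threshold are excluded). The default threshold 0.001 removes only the
#' weakest connections. `fbn_digraph()` wraps an adjacency matrix directly;
#' orientation is the same target-row/source-column convention as
#' [nte_matrix()].
#'
#' @param m an `nte_matrix` (or any square weight matrix, zero diagonal).
#' @param threshold nonnegative edge threshold. Default 0.001.
#' @param adjacency square logical/0-1 matrix, entry `[i, j]` = edge `j -> i`.
#' @return an `fbn_digraph` (logical adjacency matrix with node labels).
#' @export
binarize <- function(m, threshold = 0.001) {
  stopifnot(threshold >= 0)
  fbn_digraph(unclass(m) > threshold)
}

#' @rdname binarize
#' @export
fbn_digraph <- function(adjacency) {
  a <- adjacency != 0
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  diag(a) <- FALSE
  if (is.null(rownames(a)) && nrow(a) == length(NTEFBN_CHANNELS)) {
    dimnames(a) <- list(NTEFBN_CHANNELS, NTEFBN_CHANNELS)
  }
  structure(a, class = c("fbn_digraph", "matrix"))
}

#' @export
print.fbn_digraph <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<fbn_digraph> %d nodes, %d / %d directed edges (density %.3f)\n",
              n, sum(x), n * (n - 1), sum(x) / (n * (n - 1))))
  invisible(x)
}

# igraph uses source-row orientation; our adjacency is target-row.
as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(t(unclass(g) * 1), mode = "directed")
}

#' Connectivity density
#'
#' Ratio of realized directed edges to the `n(n-1)` possible ones; 1 for a
#' complete digraph, 0 for an empty one.
#'
#' @param g an `fbn_digraph`.
#' @return density in `[0, 1]`.
#' @export
connectivity_density <- function(g) {
  n <- nrow(g)
  sum(g) / (n * (n - 1))
}

.ntefbn_env <- new.env(parent = emptyenv())

# A 3-node digraph on an ordered node triple (a, b, c) is encoded by 6 bits:
# a->b, b->a, a->c, c->a, b->c, c->b. Its isomorphism class is the minimum
# code over the 6 node permutations; weak connectivity on 3 nodes is simply
# "no isolated node".
motif_code_of <- function(a) {
  bits <- c(a[1, 2], a[2, 1], a[1, 3], a[3, 1], a[2, 3], a[3, 2])
  sum(bits * 2^(0:5))
}

motif_class_map <- function() {
  if (!is.null(.ntefbn_env$motifs)) return(.ntefbn_env$motifs)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  canon <- integer(64); conn <- logical(64)
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[1:6]
    a <- matrix(0L, 3, 3)
    a[1, 2] <- bits[1]; a[2, 1] <- bits[2]; a[1, 3] <- bits[3]
    a[3, 1] <- bits[4]; a[2, 3] <- bits[5]; a[3, 2] <- bits[6]
    conn[code + 1] <- all(rowSums(a) + colSums(a) > 0)
    canon[code + 1] <- min(apply(perms, 1, function(p) motif_code_of(a[p, p])))
  }
  classes <- sort(unique(canon[conn]))
  out <- list(map = ifelse(conn, match(canon, classes), NA_integer_),
              classes = classes)
  .ntefbn_env$motifs <- out
  out
}

#' The 13 connected 3-node digraph classes
#'
#' Enumerates the isomorphism classes of weakly-connected 3-node directed
#' graphs by canonicalizing all 64 labelled graphs. Returns one representative
#' adjacency matrix per class, in canonical (ascending minimum-code) order —
#' the order used for motif counts everywhere in the package.
#'
#' @return list of 13 binary 3x3 adjacency matrices (`[from, to]` = 1).
#' @export
motif_classes <- function() {
  lapply(motif_class_map()$classes, function(code) {
    bits <- as.integer(intToBits(code))[1:6]
    a <- matrix(0L, 3, 3)
    a[1, 2] <- bits[1]; a[2, 1] <- bits[2]; a[1, 3] <- bits[3]
    a[3, 1] <- bits[4]; a[2, 3] <- bits[5]; a[3, 2] <- bits[6]
    a
  })
}

#' 3-node motif census
#'
#' Classifies every weakly-connected induced 3-node subgraph into one of the
#' 13 isomorphism classes of connected 3-node digraphs ([motif_classes()])
#' and counts occurrences; each node triple is counted at most once, and
#' triples whose induced subgraph is disconnected are not counted. The class
#' order also fixes the motif feature positions in [extract_features()].
#'
#' @param g an `fbn_digraph`.
#' @return a `motif_census`: list with `counts` (named integer, 13 classes)
#'   and `total`.
#' @export
motif_census <- function(g) {
  mm <- motif_class_map()
  a <- t(unclass(g) * 1L)  # [from, to]
  n <- nrow(a)
  counts <- integer(13)
  if (n >= 3) {
    tri <- utils::combn(n, 3)
    i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
    code <- a[cbind(i, j)] + 2L * a[cbind(j, i)] +
      4L * a[cbind(i, k)] + 8L * a[cbind(k, i)] +
      16L * a[cbind(j, k)] + 32L * a[cbind(k, j)]
    cls <- mm$map[code + 1L]
    counts <- tabulate(cls[!is.na(cls)], nbins = 13)
  }
  names(counts) <- sprintf("motif%02d", 1:13)
  structure(list(counts = counts, total = sum(counts)), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat(sprintf("<motif_census> %d connected 3-node subgraphs across %d classes\n",
              x$total, length(x$counts)))
  print(x$counts)
  invisible(x)
}

#' Directed local clustering coefficients
#'
#' Per-node directed clustering in the Fagiolo form, which counts all directed
#' triangles through a node regardless of edge orientation:
#' `C_i = [(A + A')^3]_ii / (2 * (d_i (d_i - 1) - 2 d_i^bi))`, where `d_i` is
#' the total (in + out) degree and `d_i^bi` the number of reciprocal
#' neighbours. Reduces to the Watts-Strogatz coefficient on symmetric graphs.
#' Nodes with a zero denominator (degree < 2 non-reciprocal slots) get 0.
#'
#' @param g an `fbn_digraph`.
#' @return named numeric vector of per-node coefficients in `[0, 1]`.
#' @export
clustering_coefficients <- function(g) {
  A <- unclass(g) * 1
  # our adjacency is target-row; Fagiolo's formula is orientation-symmetric
  # in A + A', so no transpose is needed
  S <- A + t(A)
  tri <- diag(S %*% S %*% S) / 2
  d_tot <- rowSums(A) + colSums(A)
  d_bi <- rowSums(A * t(A))
  denom <- d_tot * (d_tot - 1) - 2 * d_bi
  cc <- ifelse(denom > 0, tri / denom, 0)
  names(cc) <- rownames(g)
  cc
}

#' Characteristic path length
#'
#' Mean directed shortest-path length (hops) over all ordered node pairs with
#' a finite path; unreachable pairs are excluded and their fraction reported.
#' A graph with no reachable pair at all is flagged undefined.
#'
#' @param g an `fbn_digraph`.
#' @return list with `L` (mean hops; `NA` if undefined), `frac_unreachable`
#'   (fraction of ordered pairs with no path), and `defined` (logical).
#' @export
characteristic_path_length <- function(g) {
  d <- igraph::distances(as_igraph(g), mode = "out")
  d <- d[row(d) != col(d)]
  finite <- is.finite(d)
  if (!any(finite)) {
    return(list(L = NA_real_, frac_unreachable = 1, defined = FALSE))
  }
  list(L = mean(d[finite]), frac_unreachable = mean(!finite), defined = TRUE)
}

#' Directed transitivity (global clustering)
#'
#' Fraction of directed 2-paths `i -> j -> k` (with `i != k`) that are closed
#' by the edge `i -> k`. For a directed Erdos-Renyi graph its expectation is
#' the edge probability. This is the global "transitive" clustering used in
#' the small-world index; per-node clustering is reported separately by
#' [clustering_coefficients()].
#'
#' @param g an `fbn_digraph`.
#' @return transitivity in `[0, 1]` (0 for a graph with no 2-paths).
#' @export
transitivity_directed <- function(g) {
  A <- t(unclass(g) * 1)  # source-row orientation
  P <- A %*% A
  paths <- sum(P) - sum(diag(P))
  if (paths == 0) return(0)
  sum(A * P) / paths
}

#' Degree-matched random reference networks
#'
#' Generates `n_random` degree-sequence-preserving rewirings of `g` (seeded
#' directed edge swaps, `10 * |E|` swap attempts each) and returns the mean
#' directed transitivity and mean characteristic path length across the
#' realizations — the Monte-Carlo null for the small-world index. Graphs with
#' fewer than 2 edges return their own values with a warning.
#'
#' @param g an `fbn_digraph`.
#' @param n_random number of random realizations (>= 1). Default 100.
#' @param seed integer seed.
#' @return list with `C_rand` and `L_rand`.
#' @export
random_reference <- function(g, n_random = 100L, seed = 1L) {
  stopifnot(n_random >= 1)
  if (sum(g) < 2) {
    warning("graph has fewer than 2 edges; returning its own values")
    return(list(C_rand = transitivity_directed(g),
                L_rand = characteristic_path_length(g)$L))
  }
  ig <- as_igraph(g)
  n_swaps <- 10L * igraph::ecount(ig)
  vals <- with_seed(seed, {
    vapply(seq_len(n_random), function(r) {
      rg <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE, niter = n_swaps))
      a <- as.matrix(igraph::as_adjacency_matrix(rg))
      gg <- fbn_digraph(t(a))
      c(transitivity_directed(gg), characteristic_path_length(gg)$L)
    }, numeric(2))
  })
  list(C_rand = mean(vals[1, ]), L_rand = mean(vals[2, ], na.rm = TRUE))
}

#' Small-world index
#'
#' sigma = (C_d / C_rand) / (L_d / L_rand), with `C_d` the graph's directed
#' transitivity, `L_d` its characteristic path length, and the `_rand` values
#' from [random_reference()]. sigma > 1 marks a small-world topology (high
#' clustering with short paths relative to degree-matched random networks).
#'
#' @inheritParams random_reference
#' @return a `small_world_result`: list with `C_d`, `C_rand`, `L_d`, `L_rand`,
#'   `sigma`, `n_random`, `degenerate` (TRUE if a null value was 0 or the path
#'   length undefined).
#' @export
small_world_index <- function(g, n_random = 100L, seed = 1L) {
  C_d <- transitivity_directed(g)
  pl <- characteristic_path_length(g)
  ref <- random_reference(g, n_random = n_random, seed = seed)
  degenerate <- !pl$defined || is.na(ref$C_rand) || is.na(ref$L_rand) ||
    ref$C_rand == 0 || ref$L_rand == 0
  sigma <- if (degenerate) NA_real_ else (C_d / ref$C_rand) / (pl$L / ref$L_rand)
  structure(list(C_d = C_d, C_rand = ref$C_rand, L_d = pl$L,
                 L_rand = ref$L_rand, sigma = sigma, n_random = n_random,
                 degenerate = degenerate),
            class = "small_world_result")
}

#' @export
print.small_world_result <- function(x, ...) {
  cat(sprintf("<small_world_result> Cd=%.4f Crand=%.4f Ld=%.4f Lrand=%.4f sigma=%.4f (n_random=%d)\n",
              x$C_d, x$C_rand, x$L_d, x$L_rand, x$sigma, x$n_random))
  invisible(x)
}

#' Node strengths of the weighted network
#'
#' Strength of node `i` = sum of incoming plus outgoing NTE weights (row sum
#' plus column sum of the unthresholded weight matrix).
#'
#' @param m an `nte_matrix` (or square weight matrix).
#' @return named numeric vector of strengths.
#' @export
node_strengths <- function(m) {
  w <- unclass(m)
  s <- rowSums(w) + colSums(w)
  names(s) <- rownames(w)
  s
}

#' Export a digraph
#'
#' GraphML via igraph, or a two-column source/target edge-list TSV.
#' @param g an `fbn_digraph`.
#' @param path output path.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
write_edgelist_tsv <- function(g, path) {
  idx <- which(unclass(g), arr.ind = TRUE)
  df <- data.frame(source = colnames(g)[idx[, 2]], target = rownames(g)[idx[, 1]])
  df <- df[order(df$source, df$target), , drop = FALSE]
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
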