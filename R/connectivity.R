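#' Symbol sequences for plug-in entropy estimation
#'
#' A `symbol_sequence` is an integer sequence in `[0, B-1]` with alphabet size
#' `B`. `quantize()` maps a real-valued signal onto symbols by equiprobable
#' (quantile-edge) binning computed from the sequence itself: values are ranked
#' (ties share the lowest rank, i.e. break toward the lower bin) and ranks are
#' split into `B` equal-count bins. On distinct values each bin count is within
#' one of `length(signal)/B`. A constant signal maps to all-zero symbols
#' (entropy zero).
#'
#' @param signal numeric vector, length >= 2.
#' @param B alphabet size (number of bins), >= 2. Default 8.
#' @return a `symbol_sequence`: list with `symbols` (integer, 0-based) and `B`.
#' @export
quantize <- function(signal, B = 8L) {
  stopifnot(is.numeric(signal), length(signal) >= 2, B >= 2)
  symbol_sequence(cpp_quantize(as.numeric(signal), as.integer(B)), B)
}

#' @param symbols integer vector in `[0, B-1]`.
#' @rdname quantize
#' @export
symbol_sequence <- function(symbols, B) {
  symbols <- as.integer(symbols)
  B <- as.integer(B)
  stopifnot(length(symbols) >= 2, B >= 2, all(symbols >= 0L), all(symbols < B))
  structure(list(symbols = symbols, B = B), class = "symbol_sequence")
}

as_symseq <- function(x, B = 8L) {
  if (inherits(x, "symbol_sequence")) x else quantize(x, B)
}

#' Plug-in conditional entropy H(x[n+1] | x[n])
#'
#' Entropy (bits) of the next symbol given the current one, estimated from the
#' pair frequencies over the `N - 1` consecutive pairs, with `0 log 0 := 0`.
#' This is the normalizer of the normalized transfer entropy: the target
#' channel's own next-step information budget.
#'
#' @param x a `symbol_sequence` (or numeric vector, quantized with `B` bins).
#' @param B bins used if `x` is numeric.
#' @return conditional entropy in bits.
#' @export
conditional_entropy <- function(x, B = 8L) {
  x <- as_symseq(x, B)
  cpp_cond_entropy(x$symbols, x$B)
}

#' Plug-in transfer entropy TE(y -> x)
#'
#' Transfer entropy in bits with embedding dimension 1 and lag 1: the
#' conditional mutual information between the target's next symbol and the
#' source's current symbol given the target's current symbol, using plug-in
#' triple frequencies. Non-negative by construction; zero for independent
#' sequences in the large-sample limit.
#'
#' @param x target `symbol_sequence`.
#' @param y source `symbol_sequence`, same length as `x`.
#' @param B bins used if inputs are numeric.
#' @return transfer entropy in bits.
#' @export
transfer_entropy <- function(x, y, B = 8L) {
  x <- as_symseq(x, B); y <- as_symseq(y, B)
  if (length(x$symbols) != length(y$symbols)) {
    stop("dimension error: sequences differ in length", call. = FALSE)
  }
  cpp_te(x$symbols, y$symbols, max(x$B, y$B))
}

#' Normalized transfer entropy with shuffled surrogates
#'
#' NTE(y -> x) = (TE(y -> x) - mean TE(y_shuffle -> x)) / H(x[n+1] | x[n]),
#' where each surrogate shuffles the source symbols with a seeded uniform
#' random permutation. The surrogate subtraction removes the small-sample bias
#' of plug-in TE; division by the target's conditional entropy scales the
#' result to `[0, 1]` (1 = the source explains all of the target's next-step
#' uncertainty). Negative values after bias subtraction are clipped to 0; if
#' the target's conditional entropy is 0 the NTE is defined as 0.
#'
#' @inheritParams transfer_entropy
#' @param n_shuffles number of shuffled surrogates (>= 1). Default 20.
#' @param rng_seed integer seed for the surrogate permutations.
#' @return NTE in `[0, 1]`.
#' @export
normalized_te <- function(x, y, n_shuffles = 20L, rng_seed = 1L, B = 8L) {
  stopifnot(n_shuffles >= 1)
  x <- as_symseq(x, B); y <- as_symseq(y, B)
  if (length(x$symbols) != length(y$symbols)) {
    stop("dimension error: sequences differ in length", call. = FALSE)
  }
  n <- length(y$symbols)
  perms <- with_seed(rng_seed, {
    vapply(seq_len(n_shuffles), function(s) sample.int(n), integer(n))
  })
  res <- cpp_nte_pair(x$symbols, y$symbols, max(x$B, y$B), perms - 1L)
  res$nte
}

#' Directed NTE matrix of an epoch set
#'
#' Computes, for every ordered channel pair and every epoch, the surrogate
#' corrected NTE, and averages across epochs. The orientation is
#' `value[target, source]`: row `i`, column `j` holds NTE(channel j -> channel
#' i). Quantization is per channel per epoch; the shuffle permutations are
#' drawn once per epoch (seeded from `seed`) and shared across source
#' channels.
#'
#' @param es an `epoch_set` (see [epoch_by_state()]) or a list of
#'   channels-by-samples matrices.
#' @param B bins for quantization. Default 8.
#' @param n_shuffles surrogates per epoch. Default 20.
#' @param seed integer seed.
#' @param state optional state label recorded on the result.
#' @return an `nte_matrix`: 14x14 numeric matrix, zero diagonal, entries in
#'   `[0, 1]`, with attributes `state` and `n_epochs_averaged`.
#' @export
nte_matrix <- function(es, B = 8L, n_shuffles = 20L, seed = 1L, state = NULL) {
  if (inherits(es, "epoch_set")) {
    state <- state %||% es$state
    epochs <- es$epochs
  } else {
    epochs <- es
  }
  if (length(epochs) == 0) stop("empty-input error: no epochs to average", call. = FALSE)
  C <- nrow(epochs[[1]])
  acc <- matrix(0, C, C)
  for (e in seq_along(epochs)) {
    ep <- epochs[[e]]
    n <- ncol(ep)
    sym <- matrix(0L, C, n)
    for (ch in seq_len(C)) sym[ch, ] <- cpp_quantize(ep[ch, ], as.integer(B))
    perms <- with_seed(derive_seed(seed, paste0("epoch-", e)), {
      vapply(seq_len(n_shuffles), function(s) sample.int(n), integer(n))
    })
    acc <- acc + cpp_nte_epoch(sym, B, perms - 1L)
  }
  m <- acc / length(epochs)
  labs <- rownames(epochs[[1]]) %||%
    (if (C == length(NTEFBN_CHANNELS)) NTEFBN_CHANNELS else NULL)
  if (!is.null(labs)) dimnames(m) <- list(labs, labs)
  structure(m, class = c("nte_matrix", "matrix"),
            state = state, n_epochs_averaged = length(epochs))
}

#' @export
print.nte_matrix <- function(x, ...) {
  cat(sprintf("<nte_matrix> %dx%d, state = %s, averaged over %d epoch(s)\n",
              nrow(x), ncol(x), attr(x, "state") %||% "<none>",
              attr(x, "n_epochs_averaged") %||% NA))
  cat(sprintf("  mean off-diagonal NTE = %.4f, max = %.4f\n",
              mean(x[row(x) != col(x)]), max(x)))
  invisible(x)
}

#' @export
plot.nte_matrix <- function(x, main = NULL, ...) {
  m <- unclass(x)[rev(seq_len(nrow(x))), ]
  graphics::image(t(m), axes = FALSE, main = main %||%
                    sprintf("NTE (%s)", attr(x, "state") %||% ""),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(x)), labels = colnames(x),
                 las = 2, cex.axis = 0.6)
  graphics::axis(2, at = seq(0, 1, length.out = nrow(x)), labels = rev(rownames(x)),
                 las = 2, cex.axis = 0.6)
  invisible(x)
}

#' Write / read an NTE matrix as TSV
#'
#' Tab-separated with a channel-label header row and first column (rows =
#' targets, columns = sources).
#' @param m an `nte_matrix` (or plain matrix).
#' @param path output path.
#' @export
write_nte_tsv <- function(m, path) {
  df <- data.frame(channel = rownames(m), unclass(m), check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname write_nte_tsv
#' @export
read_nte_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  structure(m, class = c("nte_matrix", "matrix"))
}
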