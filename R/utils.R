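#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, runs `expr`, and restores
#' the previous state, so seeded internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # materialize a state so it can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Every source of randomness in the pipeline takes its seed from the master
#' seed through this map, so per-subject / per-stage streams are decoupled but
#' fully determined. The result is always in `[0, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param salt character label (e.g. "subject-3-simulate").
#' @return integer seed.
#' @export
derive_seed <- function(master, salt) {
  h <- as.numeric(master) %% 2147483647
  for (b in utf8ToInt(as.character(salt))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer(h)
}

msg <- function(..., verbose = getOption("ntefbn.verbose", FALSE)) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
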