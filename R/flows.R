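#' Hemisphere-wise information flow
#'
#' Splits the 14x14 NTE matrix into the four source-to-target hemisphere
#' blocks (LH->LH, LH->RH, RH->LH, RH->RH; 7 electrodes per hemisphere,
#' 10-20 parity) and computes each electrode's total outflow within the
#' block. Blocks are returned in source-row/target-column orientation, so a
#' row sum is the information an electrode sends into the block's target
#' hemisphere (within-hemisphere diagonals are zero, so an LH->LH row sums
#' over 6 cells and an LH->RH row over 7).
#'
#' @param m an `nte_matrix` (target-row/source-column orientation).
#' @return a `hemisphere_flows`: list of four 7x7 `blocks` and matching
#'   `outflow` vectors.
#' @export
hemisphere_flows <- function(m) {
  hemi <- hemisphere_channels()
  w <- t(unclass(m))  # -> source-row, target-column
  blocks <- list()
  for (src in c("LH", "RH")) {
    for (tgt in c("LH", "RH")) {
      blocks[[paste0(src, "->", tgt)]] <- w[hemi[[src]], hemi[[tgt]], drop = FALSE]
    }
  }
  structure(list(blocks = blocks, outflow = lapply(blocks, rowSums)),
            class = "hemisphere_flows")
}

#' @export
print.hemisphere_flows <- function(x, ...) {
  tot <- vapply(x$blocks, sum, numeric(1))
  cat("<hemisphere_flows> block totals:\n")
  print(round(tot, 4))
  invisible(x)
}

#' Region-based information flow
#'
#' Sums NTE over the six directed inter-region pairs among the frontal (F),
#' central-temporal (C) and parieto-occipital (P) 4-electrode nodes
#' (AF3/AF4 belong to no node; within-region flows are excluded). Also labels
#' the maximum and minimum flowing pair.
#'
#' @param m an `nte_matrix`.
#' @return a `region_flows`: list with `flows` (named numeric of `F-C`, `C-F`,
#'   `F-P`, `P-F`, `P-C`, `C-P`), `max_pair`, `min_pair` (NA if all zero).
#' @export
region_flows <- function(m) {
  reg <- region_channels()
  w <- t(unclass(m))  # source-row, target-column
  pairs <- c("F-C", "C-F", "F-P", "P-F", "P-C", "C-P")
  flows <- vapply(pairs, function(p) {
    st <- strsplit(p, "-", fixed = TRUE)[[1]]
    sum(w[reg[[st[1]]], reg[[st[2]]]])
  }, numeric(1))
  all_zero <- all(flows == 0)
  structure(list(flows = flows,
                 max_pair = if (all_zero) NA_character_ else names(which.max(flows)),
                 min_pair = if (all_zero) NA_character_ else names(which.min(flows))),
            class = "region_flows")
}

#' @export
print.region_flows <- function(x, ...) {
  cat("<region_flows>\n")
  print(round(x$flows, 4))
  cat(sprintf("  max: %s, min: %s\n", x$max_pair, x$min_pair))
  invisible(x)
}

#' Mean information flow per electrode
#'
#' Each electrode's total outgoing NTE: under the target-row/source-column
#' orientation this is the column sum for each source electrode.
#'
#' @param m an `nte_matrix`.
#' @return named numeric vector, one outflow per electrode.
#' @export
mean_information_flow <- function(m) {
  f <- colSums(unclass(m))
  names(f) <- colnames(m)
  f
}

#' Welch two-sample t-test
#'
#' Two-sample t-test with unequal variances (Welch-Satterthwaite degrees of
#' freedom), two-tailed, with the 95% confidence interval of the mean
#' difference. Thin wrapper around [stats::t.test()] returning the tabular
#' fields used by the reporting layer.
#'
#' @param a,b numeric samples (each length >= 2).
#' @param conf_level confidence level. Default 0.95.
#' @return a `stat_test_result`: list with `mean_difference`, `ci_low`,
#'   `ci_high`, `df`, `t`, `p`, `significant` (at alpha = 0.05).
#' @export
welch_ttest <- function(a, b, conf_level = 0.95) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      return(structure(list(mean_difference = 0, ci_low = 0, ci_high = 0,
                            df = NA_real_, t = NA_real_, p = 1,
                            significant = FALSE, undefined = TRUE),
                       class = "stat_test_result"))
    }
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, conf.level = conf_level)
  structure(list(mean_difference = unname(tt$estimate[1] - tt$estimate[2]),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 df = unname(tt$parameter), t = unname(tt$statistic),
                 p = tt$p.value, significant = tt$p.value < 0.05,
                 undefined = FALSE),
            class = "stat_test_result")
}

#' @export
print.stat_test_result <- function(x, ...) {
  cat(sprintf("mean diff %.4f (95%% CI %.4f, %.4f), t(%.1f) = %.3f, p = %.4g%s\n",
              x$mean_difference, x$ci_low, x$ci_high, x$df, x$t, x$p,
              if (isTRUE(x$significant)) " *" else ""))
  invisible(x)
}

#' One-way ANOVA with Tukey-Kramer multiple comparisons
#'
#' Fits a one-way ANOVA across the groups and follows it with the
#' Tukey-Kramer procedure (simultaneous 95% intervals) for all pairwise mean
#' differences.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @param labels group labels; defaults to list names or `group1`, ...
#' @return list with `F`, `p` (overall test), and `pairwise` — a data.frame
#'   with columns `pair`, `mean_difference`, `ci_low`, `ci_high`, `p_adj`,
#'   `significant`.
#' @export
anova_multicompare <- function(groups, labels = NULL) {
  stopifnot(length(groups) >= 2)
  labels <- labels %||% names(groups) %||% paste0("group", seq_along(groups))
  small <- vapply(groups, length, integer(1)) < 2
  if (any(small)) {
    stop(sprintf("group(s) with fewer than 2 observations: %s",
                 paste(labels[small], collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(y = unlist(groups),
                   g = factor(rep(labels, vapply(groups, length, integer(1))),
                              levels = labels))
  fit <- stats::aov(y ~ g, data = df)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$g
  pairwise <- data.frame(pair = rownames(tk),
                         mean_difference = tk[, "diff"],
                         ci_low = tk[, "lwr"], ci_high = tk[, "upr"],
                         p_adj = tk[, "p adj"],
                         significant = tk[, "p adj"] < 0.05,
                         row.names = NULL)
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], pairwise = pairwise)
}
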