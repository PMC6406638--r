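#' Sliding task windows
#'
#' Cuts every annotated span of the requested task states into 20-s windows
#' whose starts are 1 s apart (each window is one classification sample).
#' Windows never cross a state boundary; spans shorter than one window yield
#' nothing.
#'
#' @param rec an [eeg_recording].
#' @param states states to window. Default `c("drawing", "manipulation")`
#'   (the rest baseline is not used for expertise classification).
#' @param win window length in seconds. Default 20.
#' @param step distance between window starts in seconds. Default 1.
#' @return list of windows, each a list with `samples` (channels x samples),
#'   `state`, and `start` (absolute start sample). Empty list (with a
#'   warning) if no span is long enough.
#' @export
sliding_windows <- function(rec, states = c("drawing", "manipulation"),
                            win = 20, step = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- as.integer(round(win * rec$fs))
  stride <- as.integer(round(step * rec$fs))
  out <- list()
  ann <- rec$annotations[rec$annotations$state %in% states, , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    s0 <- ann$start[i]
    while (s0 + len - 1L <= ann$end[i]) {
      out[[length(out) + 1L]] <- list(
        samples = rec$samples[, s0:(s0 + len - 1L), drop = FALSE],
        state = ann$state[i], start = s0)
      s0 <- s0 + stride
    }
  }
  if (length(out) == 0) warning("no annotated span is at least one window long")
  out
}

#' Per-window feature names, in canonical order
#'
#' The 43-entry layout: \[1\] connectivity density; \[2-14\] the 13 motif-class
#' counts; \[15-28\] per-electrode directed clustering coefficients (canonical
#' channel order); \[29\] characteristic path length; \[30-43\] per-electrode
#' mean information flow.
#' @return character vector of length 43.
#' @export
feature_names <- function() {
  c("cd", sprintf("motif%02d", 1:13),
    paste0("cc_", NTEFBN_CHANNELS), "cpl",
    paste0("mif_", NTEFBN_CHANNELS))
}

#' Extract the 43-entry feature vector of one window
#'
#' Estimates the window's NTE matrix (the whole window as a single epoch),
#' binarizes it at `threshold`, and fills the [feature_names()] layout.
#' An undefined characteristic path length (no reachable pair) is encoded as
#' 0 with the attribute `cpl_undefined = TRUE`.
#'
#' @param window a window from [sliding_windows()] or a channels x samples
#'   matrix.
#' @param B,n_shuffles,seed NTE estimation parameters (see [nte_matrix()]).
#' @param threshold binarization threshold. Default 0.001.
#' @return named numeric vector of length 43.
#' @export
extract_features <- function(window, B = 8L, n_shuffles = 20L, seed = 1L,
                             threshold = 0.001) {
  samples <- if (is.list(window)) window$samples else window
  m <- nte_matrix(list(samples), B = B, n_shuffles = n_shuffles, seed = seed)
  features_from_nte(m, threshold = threshold)
}

#' @param m a 14x14 `nte_matrix` (or plain weight matrix).
#' @rdname extract_features
#' @export
features_from_nte <- function(m, threshold = 0.001) {
  g <- binarize(m, threshold)
  mc <- motif_census(g)
  pl <- characteristic_path_length(g)
  v <- c(connectivity_density(g), as.numeric(mc$counts),
         as.numeric(clustering_coefficients(g)),
         if (pl$defined) pl$L else 0,
         as.numeric(mean_information_flow(m)))
  names(v) <- feature_names()
  if (!pl$defined) attr(v, "cpl_undefined") <- TRUE
  v
}

#' Window-level feature table for a cohort
#'
#' Preprocesses each subject (filtering with the given parameters), cuts
#' 20-s/1-s sliding windows over the task states, and extracts the 43
#' features per window. Window seeds are derived from `seed` per subject and
#' window, so the table is fully reproducible.
#'
#' @param cohort result of [make_cohort()] (list of subject entries) or a
#'   list of `list(recording, profile)` pairs.
#' @param seed master integer seed.
#' @param B,n_shuffles,threshold see [extract_features()].
#' @param win,step,states see [sliding_windows()].
#' @param filter logical: apply [filter_recording()] first. Default TRUE.
#' @param ... passed to [filter_recording()].
#' @return list with `X` (windows x 43 feature matrix), `y` (factor of
#'   expertise labels) and `meta` (data.frame subject, state, start).
#' @export
cohort_features <- function(cohort, seed = 1L, B = 8L, n_shuffles = 20L,
                            threshold = 0.001, win = 20, step = 1,
                            states = c("drawing", "manipulation"),
                            filter = TRUE, ...) {
  rows <- list(); labs <- character(0); meta <- list()
  for (subj in cohort) {
    rec <- subj$recording
    if (filter) rec <- filter_recording(rec, ...)
    wins <- sliding_windows(rec, states = states, win = win, step = step)
    sid <- subj$profile$subject_id
    for (k in seq_along(wins)) {
      wseed <- derive_seed(seed, paste0(sid, "-window-", k))
      rows[[length(rows) + 1L]] <- extract_features(
        wins[[k]], B = B, n_shuffles = n_shuffles, seed = wseed,
        threshold = threshold)
      labs <- c(labs, subj$profile$expertise)
      meta[[length(meta) + 1L]] <- data.frame(
        subject = sid, state = wins[[k]]$state, start = wins[[k]]$start,
        stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, rows)
  list(X = X, y = factor(labs, levels = c("expert", "novice")),
       meta = do.call(rbind, meta))
}

#' Write a feature table as CSV
#'
#' Header = feature names plus `expertise`, `subject`, `state`, `start`.
#' @param ft result of [cohort_features()].
#' @param path output path.
#' @export
write_feature_csv <- function(ft, path) {
  df <- data.frame(ft$X, expertise = as.character(ft$y), ft$meta,
                   check.names = FALSE)
  data.table::fwrite(df, path)
  invisible(path)
}
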