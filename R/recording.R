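#' Multichannel EEG recording container
#'
#' An `eeg_recording` holds a channels-by-samples numeric matrix (microvolt-like
#' units), the sampling rate, and state annotations. Channels are always stored
#' in the canonical montage order ([NTEFBN_CHANNELS]); constructors reorder on
#' the way in.
#'
#' @param samples numeric matrix, channels x samples; rownames must be the 14
#'   canonical channel labels (any order, reordered internally).
#' @param fs sampling rate in Hz.
#' @param annotations data.frame with columns `state` (character), `start`,
#'   `end` (1-based inclusive sample indices). Spans must be disjoint and in
#'   bounds. May be empty.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(samples, fs, annotations = empty_annotations()) {
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stop("`samples` must be a numeric matrix (channels x samples)", call. = FALSE)
  }
  if (nrow(samples) != length(NTEFBN_CHANNELS)) {
    stop(sprintf("dimension error: expected %d channels, got %d",
                 length(NTEFBN_CHANNELS), nrow(samples)), call. = FALSE)
  }
  labs <- rownames(samples)
  if (is.null(labs)) {
    rownames(samples) <- NTEFBN_CHANNELS
  } else {
    missing <- setdiff(NTEFBN_CHANNELS, labs)
    if (length(missing) > 0) {
      stop(sprintf("format error: missing channel(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    samples <- samples[NTEFBN_CHANNELS, , drop = FALSE]
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  annotations <- validate_annotations(annotations, ncol(samples))
  structure(list(samples = samples, fs = fs, annotations = annotations),
            class = "eeg_recording")
}

empty_annotations <- function() {
  data.frame(state = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann, n_samples) {
  stopifnot(is.data.frame(ann), all(c("state", "start", "end") %in% names(ann)))
  ann <- ann[, c("state", "start", "end")]
  ann$state <- as.character(ann$state)
  ann$start <- as.integer(ann$start)
  ann$end <- as.integer(ann$end)
  if (nrow(ann) == 0) return(ann)
  if (any(ann$start < 1L) || any(ann$end > n_samples) || any(ann$end < ann$start)) {
    stop("annotation spans out of bounds", call. = FALSE)
  }
  ann <- ann[order(ann$start), , drop = FALSE]
  if (nrow(ann) > 1 && any(ann$start[-1] <= ann$end[-nrow(ann)])) {
    stop("annotation spans overlap", call. = FALSE)
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs, ncol(x$samples) / x$fs))
  if (nrow(x$annotations) > 0) {
    spans <- sprintf("%s [%.1f-%.1f s]", x$annotations$state,
                     (x$annotations$start - 1) / x$fs, x$annotations$end / x$fs)
    cat("  states:", paste(spans, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write recordings
#'
#' `write_recording_csv()` writes one row per sample with the 14 channel-label
#' columns plus a `state` column (empty string outside annotated spans), and a
#' sidecar JSON (`<path>.json`) carrying the sampling rate and, for synthetic
#' subjects, the generating profile and ground-truth coupling.
#' `read_recording()` reads either that CSV dialect (`format = "csv"`; `fs`
#' from the sidecar if present, else the `fs` argument) or 16-bit EDF+
#' (`format = "edf"`, see [write_recording_edf()]). Channels are normalized to
#' canonical order; a missing channel is a format error naming the channel.
#'
#' @param rec an `eeg_recording`.
#' @param path file path.
#' @param sidecar optional list stored in the sidecar JSON next to the CSV.
#' @param format `"csv"` or `"edf"` (default: from file extension).
#' @param fs fallback sampling rate for CSV without a sidecar.
#' @return `read_recording()` returns an `eeg_recording`; writers return the
#'   path invisibly.
#' @export
write_recording_csv <- function(rec, path, sidecar = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  state <- rep("", ncol(rec$samples))
  for (i in seq_len(nrow(rec$annotations))) {
    a <- rec$annotations[i, ]
    state[a$start:a$end] <- a$state
  }
  dt <- data.table::as.data.table(t(rec$samples))
  # serialize amplitudes as %.17g so the decimal text parses back to the
  # identical double (bit-exact round trip)
  for (ch in names(dt)) data.table::set(dt, j = ch, value = sprintf("%.17g", dt[[ch]]))
  data.table::set(dt, j = "state", value = state)
  data.table::fwrite(dt, path, quote = FALSE)
  meta <- c(list(fs = rec$fs), sidecar)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"), fs = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf",
                     stop(sprintf("usage error: unknown format '%s'", ext), call. = FALSE))
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "edf") return(read_recording_edf(path))
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  missing <- setdiff(NTEFBN_CHANNELS, names(dt))
  if (length(missing) > 0) {
    stop(sprintf("format error: missing channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  sc_path <- paste0(path, ".json")
  if (file.exists(sc_path)) {
    meta <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
    fs <- meta$fs
  }
  if (is.null(fs)) stop("sampling rate unknown: no sidecar JSON and no `fs` given", call. = FALSE)
  samples <- t(as.matrix(dt[, NTEFBN_CHANNELS]))
  ann <- state_vector_to_annotations(if ("state" %in% names(dt)) as.character(dt$state) else character(0))
  eeg_recording(samples, fs = fs, annotations = ann)
}

state_vector_to_annotations <- function(state) {
  if (length(state) == 0 || all(state == "")) return(empty_annotations())
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != ""
  data.frame(state = r$values[keep], start = starts[keep], end = ends[keep],
             stringsAsFactors = FALSE)
}

#' Restrict a recording to one annotated state
#'
#' Returns the concatenated annotated spans for `state` as a list of
#' channels-by-samples segments (spans are kept separate so no downstream
#' window ever crosses a span boundary).
#' @keywords internal
state_spans <- function(rec, state) {
  ann <- rec$annotations[rec$annotations$state == state, , drop = FALSE]
  if (nrow(ann) == 0) {
    stop(sprintf("lookup error: state '%s' not present in annotations", state),
         call. = FALSE)
  }
  lapply(seq_len(nrow(ann)), function(i) {
    rec$samples[, ann$start[i]:ann$end[i], drop = FALSE]
  })
}
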