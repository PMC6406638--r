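# Minimal EDF+ (16-bit) writer/reader for 14-channel recordings.
#
# Implements the fixed-layout EDF header, per-signal headers, int16 data
# records (1 s each), and a single "EDF Annotations" signal whose TALs carry
# the state spans. Physical scaling is per-channel min/max over the recording,
# so amplitudes round-trip only to 16-bit precision (the CSV path is the exact
# one). The true sample count is stamped in the patient-id field because EDF
# pads the last record to a whole second.

edf_pad <- function(x, width) {
  x <- substr(x, 1, width)
  paste0(x, strrep(" ", width - nchar(x)))
}

edf_num <- function(x, width) edf_pad(format(x, trim = TRUE, scientific = FALSE), width)

# Render a real into <= 8 chars and return both the string and its parsed
# value, so writer-side scaling uses exactly what the reader will see.
edf_real8 <- function(v) {
  for (d in 7:1) {
    s <- formatC(v, digits = d, format = "g", width = 0)
    if (nchar(s) <= 8) return(list(str = s, val = as.numeric(s)))
  }
  list(str = "0", val = 0)
}

#' Write / read a recording as EDF+
#'
#' `write_recording_edf()` stores the 14 channels as 16-bit EDF+ signals
#' (1-second data records) plus an annotation signal holding the state spans.
#' `read_recording_edf()` parses the same subset of EDF+ back into an
#' [eeg_recording]. Amplitudes are quantized to the 16-bit digital range, so
#' the round trip is accurate to about 1/65000 of each channel's range.
#'
#' @param rec an `eeg_recording`.
#' @param path output path.
#' @return the path (writer, invisibly) or an `eeg_recording` (reader).
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n <- ncol(rec$samples)
  n_rec <- as.integer(ceiling(n / fs))
  nsig <- nrow(rec$samples) + 1L  # + annotation signal

  # physical/digital scaling per channel; render header strings first so the
  # writer scales with exactly the values the reader will parse back
  lo_r <- lapply(apply(rec$samples, 1, min) - 1e-9 -
                   1e-7 * abs(apply(rec$samples, 1, min)), edf_real8)
  hi_r <- lapply(apply(rec$samples, 1, max) + 1e-9 +
                   1e-7 * abs(apply(rec$samples, 1, max)), edf_real8)
  phys_lo <- vapply(lo_r, `[[`, numeric(1), "val")
  phys_hi <- vapply(hi_r, `[[`, numeric(1), "val")
  flat <- phys_hi - phys_lo < 1e-9
  hi_r[flat] <- lapply(phys_lo[flat] + 1, edf_real8)
  phys_hi[flat] <- vapply(hi_r[flat], `[[`, numeric(1), "val")
  dmin <- -32768; dmax <- 32767
  dig <- round((rec$samples - phys_lo) / (phys_hi - phys_lo) * (dmax - dmin) + dmin)
  dig[] <- pmin(pmax(dig, dmin), dmax)  # guard header rounding

  # annotation byte streams: record-onset TAL per record; state TALs in record 0
  ann <- rec$annotations
  tals <- vapply(seq_len(nrow(ann)), function(i) {
    paste0("+", format((ann$start[i] - 1) / fs, trim = TRUE, scientific = FALSE),
           "\x15", format((ann$end[i] - ann$start[i] + 1) / fs, trim = TRUE, scientific = FALSE),
           "\x14", ann$state[i], "\x14")
  }, character(1))
  rec_streams <- lapply(seq_len(n_rec) - 1L, function(r) {
    s <- paste0("+", r, "\x14\x14")
    if (r == 0L && length(tals) > 0) s <- paste0(s, paste(tals, collapse = ""))
    charToRaw(s)
  })
  ann_bytes <- max(vapply(rec_streams, length, integer(1))) + 2L
  ann_bytes <- ann_bytes + (ann_bytes %% 2L)  # even -> whole int16 slots
  ann_spr <- ann_bytes %/% 2L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  header_bytes <- 256L * (1L + nsig)
  wr(edf_pad("0", 8))
  wr(edf_pad(sprintf("nsamples=%d", n), 80))           # true length (see note above)
  wr(edf_pad("Startdate 01-JAN-2000 synthetic", 80))
  wr("01.01.00"); wr("00.00.00")
  wr(edf_num(header_bytes, 8))
  wr(edf_pad("EDF+C", 44))
  wr(edf_num(n_rec, 8))
  wr(edf_num(1, 8))
  wr(edf_num(nsig, 4))

  labels <- c(rownames(rec$samples), "EDF Annotations")
  for (l in labels) wr(edf_pad(l, 16))
  for (i in seq_len(nsig)) wr(edf_pad("", 80))
  for (i in seq_len(nsig)) wr(edf_pad("uV", 8))
  for (s in c(vapply(lo_r, `[[`, character(1), "str"), "-1")) wr(edf_pad(s, 8))
  for (s in c(vapply(hi_r, `[[`, character(1), "str"), "1")) wr(edf_pad(s, 8))
  for (i in seq_len(nsig)) wr(edf_num(dmin, 8))
  for (i in seq_len(nsig)) wr(edf_num(dmax, 8))
  for (i in seq_len(nsig)) wr(edf_pad("", 80))
  for (v in c(rep(fs, nsig - 1L), ann_spr)) wr(edf_num(v, 8))
  for (i in seq_len(nsig)) wr(edf_pad("", 32))

  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):min(r * fs, n)
    for (ch in seq_len(nsig - 1L)) {
      v <- dig[ch, idx]
      if (length(v) < fs) v <- c(v, rep(0L, fs - length(v)))
      writeBin(as.integer(v), con, size = 2L, endian = "little")
    }
    stream <- rec_streams[[r]]
    stream <- c(stream, raw(ann_bytes - length(stream)))
    writeBin(stream, con)
  }
  invisible(path)
}

#' @rdname write_recording_edf
#' @export
read_recording_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nc) readChar(con, nc, useBytes = TRUE)
  rd(8)
  patient <- trimws(rd(80))
  rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(trimws(rd(8)))
  rd(8)
  nsig <- as.integer(trimws(rd(4)))

  labels <- trimws(vapply(seq_len(nsig), function(i) rd(16), character(1)))
  for (i in seq_len(nsig)) rd(80)
  for (i in seq_len(nsig)) rd(8)
  pmin <- as.numeric(vapply(seq_len(nsig), function(i) trimws(rd(8)), character(1)))
  pmax <- as.numeric(vapply(seq_len(nsig), function(i) trimws(rd(8)), character(1)))
  dmin <- as.numeric(vapply(seq_len(nsig), function(i) trimws(rd(8)), character(1)))
  dmax <- as.numeric(vapply(seq_len(nsig), function(i) trimws(rd(8)), character(1)))
  for (i in seq_len(nsig)) rd(80)
  spr <- as.integer(vapply(seq_len(nsig), function(i) trimws(rd(8)), character(1)))
  for (i in seq_len(nsig)) rd(32)

  is_ann <- labels == "EDF Annotations"
  data <- vector("list", nsig)
  for (i in seq_len(nsig)) data[[i]] <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nsig)) {
      if (is_ann[i]) {
        data[[i]][[r]] <- readBin(con, "raw", n = 2L * spr[i])
      } else {
        data[[i]][[r]] <- readBin(con, "integer", n = spr[i], size = 2L,
                                  endian = "little", signed = TRUE)
      }
    }
  }

  chan_idx <- which(!is_ann)
  chan_labels <- labels[chan_idx]
  missing <- setdiff(NTEFBN_CHANNELS, chan_labels)
  if (length(missing) > 0) {
    stop(sprintf("format error: missing channel(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  fs <- spr[chan_idx[1]]  # 1-second records
  samples <- do.call(rbind, lapply(seq_along(chan_idx), function(k) {
    i <- chan_idx[k]
    d <- unlist(data[[i]])
    pmin[i] + (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i])
  }))
  rownames(samples) <- chan_labels
  n <- ncol(samples)
  m <- regmatches(patient, regexec("nsamples=([0-9]+)", patient))[[1]]
  if (length(m) == 2) n <- min(n, as.integer(m[2]))
  samples <- samples[, seq_len(n), drop = FALSE]

  ann <- empty_annotations()
  if (any(is_ann)) {
    stream <- rawToChar(unlist(data[[which(is_ann)[1]]])[
      unlist(data[[which(is_ann)[1]]]) != as.raw(0)])
    tals <- strsplit(stream, "\x14\x14", fixed = TRUE)[[1]]
    rows <- list()
    for (t in tals) {
      parts <- strsplit(t, "\x14", fixed = TRUE)[[1]]
      for (p in parts) {
        od <- strsplit(p, "\x15", fixed = TRUE)[[1]]
        if (length(od) == 2) {
          onset <- suppressWarnings(as.numeric(od[1]))
          dur <- suppressWarnings(as.numeric(od[2]))
          rows[[length(rows) + 1L]] <- c(onset, dur)
        } else if (length(rows) > 0 && length(od) == 1 && nchar(od) > 0 &&
                   !grepl("^[+-][0-9.]+$", od)) {
          rows[[length(rows)]] <- c(rows[[length(rows)]], od)
        }
      }
    }
    rows <- Filter(function(r) length(r) == 3, rows)
    if (length(rows) > 0) {
      ann <- data.frame(
        state = vapply(rows, `[`, character(1), 3),
        start = vapply(rows, function(r) as.integer(round(as.numeric(r[1]) * fs)) + 1L, integer(1)),
        end = vapply(rows, function(r) {
          as.integer(round((as.numeric(r[1]) + as.numeric(r[2])) * fs))
        }, integer(1)),
        stringsAsFactors = FALSE)
    }
  }
  eeg_recording(samples, fs = fs, annotations = ann)
}
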