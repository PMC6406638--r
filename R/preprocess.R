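# FIR preprocessing: baseline removal, band and notch filtering, epoching.

# Zero-padded FFT linear convolution, centre-aligned so the output has the
# input's length and the kernel's group delay (L-1)/2 is removed.
conv_same <- function(x, h) {
  n <- length(x); L <- length(h)
  N <- stats::nextn(n + L - 1L, 2)
  y <- Re(stats::fft(stats::fft(c(x, numeric(N - n))) *
                       stats::fft(c(h, numeric(N - L))), inverse = TRUE)) / N
  d <- (L - 1L) %/% 2L
  y[(d + 1L):(d + n)]
}

# Forward-backward application: net phase zero, magnitude response squared.
zero_phase <- function(x, h) {
  rev(conv_same(rev(conv_same(x, h)), h))
}

#' Filter a recording
#'
#' Applies, in order: per-channel baseline (mean) removal, FIR low-pass,
#' FIR high-pass, and FIR band-stop notches, each a Hamming-windowed
#' linear-phase design of the given order, applied forward-backward so the
#' net phase response is zero and output length equals input length. Notch
#' stages whose upper band edge reaches the Nyquist frequency are skipped
#' with a warning.
#'
#' @param rec an [eeg_recording].
#' @param low_pass low-pass cutoff in Hz. Default 45.
#' @param high_pass high-pass cutoff in Hz. Default 0.1.
#' @param notches centre frequencies (Hz) of band-stop notches. Default
#'   `c(50, 60)`.
#' @param order FIR filter order (taps - 1). Default 300.
#' @param notch_halfwidth half-width of each notch band in Hz. Default 2.
#' @return the filtered [eeg_recording] (same length, same annotations).
#' @export
filter_recording <- function(rec, low_pass = 45, high_pass = 0.1,
                             notches = c(50, 60), order = 300,
                             notch_halfwidth = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$samples)
  if (n < 3 * order) {
    stop(sprintf("too-short error: recording has %d samples, need >= %d (3x filter order)",
                 n, 3 * order), call. = FALSE)
  }
  nyq <- rec$fs / 2
  kernels <- list()
  if (!is.null(low_pass) && low_pass < nyq) {
    kernels <- c(kernels, list(signal::fir1(order, low_pass / nyq, type = "low")))
  }
  if (!is.null(high_pass) && high_pass > 0) {
    kernels <- c(kernels, list(signal::fir1(order, high_pass / nyq, type = "high")))
  }
  for (f0 in notches) {
    hi <- f0 + notch_halfwidth
    if (hi >= nyq) {
      warning(sprintf("notch at %g Hz skipped: band edge %g Hz reaches Nyquist (%g Hz)",
                      f0, hi, nyq))
      next
    }
    kernels <- c(kernels, list(signal::fir1(order, c(f0 - notch_halfwidth, hi) / nyq,
                                            type = "stop")))
  }
  # cascade as one composite kernel, then one forward-backward pass
  h <- Reduce(function(a, b) stats::convolve(a, rev(b), type = "open"), kernels)
  out <- rec$samples - rowMeans(rec$samples)
  for (ch in seq_len(nrow(out))) out[ch, ] <- zero_phase(out[ch, ], h)
  eeg_recording(out, fs = rec$fs, annotations = rec$annotations)
}

#' Extract fixed-length epochs of one state
#'
#' Tiles every annotated span of `state` with epochs of `epoch_len` seconds
#' whose starts are `epoch_len + gap` seconds apart (default 2 s epochs with a
#' 0.5 s gap, i.e. starts every 2.5 s). Partial trailing windows are
#' discarded; no epoch crosses a span boundary. Setting `step` instead tiles
#' with overlapping epochs whose starts are `step` seconds apart.
#'
#' @param rec an [eeg_recording].
#' @param state state label present in the annotations.
#' @param epoch_len epoch length in seconds. Default 2.
#' @param gap gap between consecutive epochs in seconds. Default 0.5.
#' @param step if non-`NULL`, distance between epoch starts in seconds
#'   (overrides `gap`).
#' @return an `epoch_set`: list with `epochs` (list of channels x samples
#'   matrices), `state`, `fs`, and `starts` (absolute start samples).
#' @export
epoch_by_state <- function(rec, state, epoch_len = 2, gap = 0.5, step = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  ann <- rec$annotations[rec$annotations$state == state, , drop = FALSE]
  if (nrow(ann) == 0) {
    stop(sprintf("lookup error: state '%s' not present in annotations", state),
         call. = FALSE)
  }
  len <- as.integer(round(epoch_len * rec$fs))
  stride <- as.integer(round((if (is.null(step)) epoch_len + gap else step) * rec$fs))
  epochs <- list(); starts <- integer(0)
  for (i in seq_len(nrow(ann))) {
    s0 <- ann$start[i]
    while (s0 + len - 1L <= ann$end[i]) {
      epochs[[length(epochs) + 1L]] <- rec$samples[, s0:(s0 + len - 1L), drop = FALSE]
      starts <- c(starts, s0)
      s0 <- s0 + stride
    }
  }
  structure(list(epochs = epochs, state = state, fs = rec$fs, starts = starts),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epoch(s) of state '%s', %s samples each @ %g Hz\n",
              length(x$epochs), x$state,
              if (length(x$epochs)) ncol(x$epochs[[1]]) else 0, x$fs))
  invisible(x)
}

#' Drop epochs exceeding an amplitude limit
#'
#' Automated stand-in for manual artifact screening: epochs whose peak
#' absolute amplitude exceeds `amplitude_limit` are removed. If everything is
#' rejected the (empty) epoch set is returned with a warning.
#'
#' @param es an `epoch_set`.
#' @param amplitude_limit positive amplitude threshold (signal units).
#'   Default 100.
#' @return the filtered `epoch_set`.
#' @export
reject_bad_epochs <- function(es, amplitude_limit = 100) {
  stopifnot(inherits(es, "epoch_set"), amplitude_limit > 0)
  keep <- vapply(es$epochs, function(e) max(abs(e)) <= amplitude_limit, logical(1))
  n_drop <- sum(!keep)
  if (n_drop > 0) msg(sprintf("rejected %d epoch(s) above %g units", n_drop, amplitude_limit))
  es$epochs <- es$epochs[keep]
  es$starts <- es$starts[keep]
  if (length(es$epochs) == 0) {
    warning("all epochs rejected: empty epoch set")
  }
  es
}
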