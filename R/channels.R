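#' Canonical 14-channel montage
#'
#' Channel labels of the 14-electrode consumer EEG montage (international
#' 10-20 positions), in the canonical order used by every matrix-valued
#' object in this package. All recordings are normalized to this order on
#' read, and every 14-by-14 connectivity matrix indexes channels this way.
#'
#' @format Character vector of length 14.
#' @export
NTEFBN_CHANNELS <- c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1",
                     "O2", "P8", "T8", "FC6", "F4", "F8", "AF4")

# Hemisphere membership follows 10-20 parity: odd suffix = left, even = right.
#' Electrode groupings used by the flow analyses
#'
#' `hemisphere_channels()` returns the left/right hemisphere split (7 + 7
#' electrodes, 10-20 parity). `region_channels()` returns the three 4-electrode
#' region nodes: frontal `F`, central-temporal `C`, parieto-occipital `P`
#' (AF3/AF4 belong to no region node).
#'
#' @return Named list of character vectors of channel labels.
#' @export
hemisphere_channels <- function() {
  list(LH = c("AF3", "F7", "F3", "FC5", "T7", "P7", "O1"),
       RH = c("AF4", "F8", "F4", "FC6", "T8", "P8", "O2"))
}

#' @rdname hemisphere_channels
#' @export
region_channels <- function() {
  list(F = c("F7", "F3", "F4", "F8"),
       C = c("FC5", "T7", "T8", "FC6"),
       P = c("P7", "O1", "O2", "P8"))
}

#' States recognized by the pipeline
#' @keywords internal
NTEFBN_STATES <- c("rest", "drawing", "manipulation")
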