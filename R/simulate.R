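#' Ground-truth directed coupling specification
#'
#' A nonnegative 14x14 matrix with zero diagonal; entry `[i, j]` is the drive
#' from channel `j` onto channel `i` (same target-row/source-column orientation
#' as [nte_matrix()]). `default_coupling()` returns the package's fixed base
#' network: 16 directed edges of strength 1.5 running front-to-back within
#' each hemisphere plus a reciprocal frontal cross-hemisphere link, chosen so
#' state-dependent rescaling modulates a sparse, recoverable structure.
#'
#' @param matrix 14x14 nonnegative numeric matrix, zero diagonal.
#' @return a `coupling_spec` (a validated matrix with channel dimnames).
#' @export
coupling_spec <- function(matrix) {
  if (!is.matrix(matrix) || any(dim(matrix) != length(NTEFBN_CHANNELS))) {
    stop(sprintf("dimension error: coupling matrix must be %dx%d",
                 length(NTEFBN_CHANNELS), length(NTEFBN_CHANNELS)), call. = FALSE)
  }
  if (any(matrix < 0)) stop("coupling strengths must be nonnegative", call. = FALSE)
  if (any(diag(matrix) != 0)) stop("coupling diagonal must be zero", call. = FALSE)
  dimnames(matrix) <- list(target = NTEFBN_CHANNELS, source = NTEFBN_CHANNELS)
  structure(matrix, class = c("coupling_spec", "matrix"))
}

#' @rdname coupling_spec
#' @export
default_coupling <- function() {
  edges <- rbind(  # source -> target
    c("AF3", "F3"), c("AF4", "F4"),
    c("F3", "FC5"), c("F3", "T7"), c("F4", "FC6"), c("F4", "T8"),
    c("F7", "T7"), c("F8", "T8"),
    c("FC5", "P7"), c("FC6", "P8"),
    c("T7", "O1"), c("T8", "O2"),
    c("P7", "O1"), c("P8", "O2"),
    c("F3", "F4"), c("F4", "F3"))
  g <- matrix(0, 14, 14, dimnames = list(NTEFBN_CHANNELS, NTEFBN_CHANNELS))
  for (k in seq_len(nrow(edges))) g[edges[k, 2], edges[k, 1]] <- 1.5
  coupling_spec(g)
}

#' Synthetic subject profile
#'
#' Describes one simulated participant: expertise label, per-state task
#' durations (seconds), per-state multipliers on the base coupling matrix,
#' and noise levels. The coupling multipliers encode the generative ground
#' truth the cohort is built to carry: a novice's coupling rises monotonically
#' rest < drawing < manipulation, while an expert's rises from rest to drawing
#' and then stays flat (drawing and manipulation within 5% of each other).
#'
#' @param subject_id character id.
#' @param expertise `"novice"` or `"expert"`.
#' @param state_durations named numeric (seconds), names among
#'   `rest`, `drawing`, `manipulation`; all positive. Default: 120 s rest and
#'   mid-range task durations.
#' @param coupling_scale named numeric multipliers per state. Defaults:
#'   novice `c(rest = 0.25, drawing = 0.70, manipulation = 1.30)`; expert
#'   `c(rest = 0.25, drawing = 1.00, manipulation = 1.00)`.
#' @param noise_sd innovation noise standard deviation (signal units).
#' @param line_noise_amplitude amplitude of the 50 Hz mains component.
#' @param osc_amplitude amplitude of the 10 Hz background oscillation.
#' @param seed integer seed; the subject's samples are a pure function of the
#'   profile, the coupling and this seed.
#' @return a `subject_profile` list.
#' @export
subject_profile <- function(subject_id,
                            expertise = c("novice", "expert"),
                            state_durations = c(rest = 120, drawing = 90,
                                                manipulation = 100),
                            coupling_scale = NULL,
                            noise_sd = 1,
                            line_noise_amplitude = 0.5 * noise_sd,
                            osc_amplitude = 0.5 * noise_sd,
                            seed = 1L) {
  expertise <- match.arg(expertise)
  if (is.null(coupling_scale)) {
    coupling_scale <- if (expertise == "novice") {
      c(rest = 0.25, drawing = 0.70, manipulation = 1.30)
    } else {
      c(rest = 0.25, drawing = 1.00, manipulation = 1.00)
    }
  }
  stopifnot(all(names(state_durations) %in% NTEFBN_STATES),
            all(names(coupling_scale) %in% NTEFBN_STATES))
  if (any(state_durations <= 0)) {
    stop("configuration error: state durations must be positive", call. = FALSE)
  }
  if (any(coupling_scale < 0)) {
    stop("configuration error: coupling multipliers must be nonnegative", call. = FALSE)
  }
  cs <- coupling_scale
  if (expertise == "novice") {
    if (!(cs["rest"] < cs["drawing"] && cs["drawing"] < cs["manipulation"])) {
      stop("configuration error: novice coupling must rise rest < drawing < manipulation",
           call. = FALSE)
    }
  } else {
    if (!(cs["rest"] < cs["drawing"]) ||
        abs(cs["drawing"] - cs["manipulation"]) > 0.05 * cs["drawing"] + 1e-9) {
      stop("configuration error: expert coupling must rise rest < drawing and stay flat (within 5%) drawing vs manipulation",
           call. = FALSE)
    }
  }
  structure(list(subject_id = as.character(subject_id), expertise = expertise,
                 state_durations = state_durations, coupling_scale = coupling_scale,
                 noise_sd = noise_sd, line_noise_amplitude = line_noise_amplitude,
                 osc_amplitude = osc_amplitude, seed = as.integer(seed)),
            class = "subject_profile")
}

#' Simulate one subject's multichannel recording
#'
#' Nonlinear coupled autoregressive network with background rhythm and mains
#' contamination. Per state `s` (in order rest, drawing, manipulation), each
#' channel evolves as
#' \deqn{x_i[t] = \alpha x_i[t-1] + scale(s) \sum_j g_{ij} \tanh(x_j[t-1])
#'   + A \sin(2\pi 10 t/f_s + \phi_i) + L \sin(2\pi 50 t/f_s) + \epsilon_t,}
#' with \eqn{\alpha = 0.9}, \eqn{\epsilon \sim N(0, noise\_sd^2)}, channel
#' phases \eqn{\phi_i} drawn once per subject, and state spans concatenated
#' continuously (the AR state carries across boundaries). The tanh saturation
#' makes the interaction nonlinear, which is what a transfer-entropy estimator
#' is built to detect; the 50 Hz term exercises the notch filter downstream.
#' Output is deterministic given the profile's seed.
#'
#' @param profile a [subject_profile()].
#' @param base_coupling a [coupling_spec()]; default [default_coupling()].
#' @param fs sampling rate in Hz (>= 64).
#' @param alpha AR(1) memory coefficient. Default 0.9.
#' @return an [eeg_recording] with one annotation span per state.
#' @export
simulate_subject <- function(profile, base_coupling = default_coupling(),
                             fs = 128, alpha = 0.9) {
  stopifnot(inherits(profile, "subject_profile"))
  if (fs < 64) stop("configuration error: fs must be >= 64 Hz", call. = FALSE)
  if (!is.matrix(base_coupling) || any(dim(base_coupling) != 14)) {
    stop("dimension error: coupling matrix must be 14x14", call. = FALSE)
  }
  states <- intersect(NTEFBN_STATES, names(profile$state_durations))
  n_per_state <- vapply(states, function(s) {
    as.integer(round(profile$state_durations[[s]] * fs))
  }, integer(1))
  n_total <- sum(n_per_state)
  burn <- as.integer(2 * fs)

  C <- 14L
  samples <- with_seed(profile$seed, {
    phi <- stats::runif(C, 0, 2 * pi)
    eps <- matrix(stats::rnorm(C * (n_total + burn), sd = profile$noise_sd),
                  nrow = C)
    x <- numeric(C)
    out <- matrix(0, C, n_total)
    scale_seq <- rep(profile$coupling_scale[states], times = n_per_state)
    t_idx <- 0L
    g <- unclass(base_coupling)
    for (t in seq_len(n_total + burn)) {
      sc <- if (t <= burn) profile$coupling_scale[[states[1]]] else
        scale_seq[[t - burn]]
      drive <- as.vector(g %*% tanh(x))
      x <- alpha * x + sc * drive +
        profile$osc_amplitude * sin(2 * pi * 10 * t / fs + phi) +
        profile$line_noise_amplitude * sin(2 * pi * 50 * t / fs) +
        eps[, t]
      if (t > burn) out[, t - burn] <- x
    }
    out
  })
  rownames(samples) <- NTEFBN_CHANNELS
  ends <- cumsum(n_per_state)
  ann <- data.frame(state = states, start = c(1L, utils::head(ends, -1) + 1L),
                    end = ends, stringsAsFactors = FALSE)
  eeg_recording(samples, fs = fs, annotations = ann)
}

#' Task-duration ranges the generator draws from
#'
#' The eight-participant study the generator emulates reports per-subject task
#' durations of 38-137 s for drawing and 72-125 s for manipulation, with a
#' fixed 120 s eyes-open rest baseline; cohort subjects draw their durations
#' uniformly from these ranges.
#' @return named list with `drawing`, `manipulation` ranges and `rest` length.
#' @export
duration_ranges <- function() {
  list(drawing = c(38, 137), manipulation = c(72, 125), rest = 120)
}

#' Generate a synthetic cohort
#'
#' Simulates `n_novice + n_expert` subjects with per-subject seeds derived
#' reproducibly from the master seed. Durations are drawn uniformly within
#' [duration_ranges()]; coupling multipliers are the profile defaults for each
#' expertise. The default cohort is 5 novices + 3 experts.
#'
#' @param n_novice,n_expert subject counts (>= 0).
#' @param seed master integer seed.
#' @param fs sampling rate. Default 128 Hz.
#' @param base_coupling a [coupling_spec()].
#' @param noise_sd innovation noise SD passed to each profile.
#' @return list of subjects, each a list with elements `recording`
#'   ([eeg_recording]), `profile` ([subject_profile()]) and `coupling`
#'   (ground-truth [coupling_spec()]).
#' @export
make_cohort <- function(n_novice = 5L, n_expert = 3L, seed = 1L, fs = 128,
                        base_coupling = default_coupling(), noise_sd = 1) {
  stopifnot(n_novice >= 0, n_expert >= 0)
  expertise <- c(rep("novice", n_novice), rep("expert", n_expert))
  dr <- duration_ranges()
  lapply(seq_along(expertise), function(k) {
    sseed <- derive_seed(seed, paste0("subject-", k))
    dur <- with_seed(derive_seed(seed, paste0("durations-", k)), {
      c(rest = dr$rest,
        drawing = round(stats::runif(1, dr$drawing[1], dr$drawing[2])),
        manipulation = round(stats::runif(1, dr$manipulation[1], dr$manipulation[2])))
    })
    prof <- subject_profile(subject_id = sprintf("S%02d", k),
                            expertise = expertise[k],
                            state_durations = dur, noise_sd = noise_sd,
                            seed = sseed)
    list(recording = simulate_subject(prof, base_coupling, fs = fs),
         profile = prof, coupling = base_coupling)
  })
}

#' Write a cohort to disk
#'
#' One file per subject (`<id>.csv` or `<id>.edf`) plus a sidecar JSON with
#' the generating profile and the ground-truth coupling matrix.
#'
#' @param cohort result of [make_cohort()].
#' @param dir output directory (created if needed).
#' @param format `"csv"` or `"edf"`.
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(cohort, function(subj) {
    p <- file.path(dir, paste0(subj$profile$subject_id, ".", format))
    meta <- list(profile = unclass(subj$profile),
                 coupling = unclass(subj$coupling))
    if (format == "csv") {
      write_recording_csv(subj$recording, p, sidecar = meta)
    } else {
      write_recording_edf(subj$recording, p)
      jsonlite::write_json(c(list(fs = subj$recording$fs), meta),
                           paste0(p, ".json"), auto_unbox = TRUE, digits = NA)
    }
    p
  }, character(1))
  invisible(paths)
}
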