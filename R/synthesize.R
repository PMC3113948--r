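# Synthetic surface-EMG generation.
#
# The carrier model is amplitude-modulated band-limited Gaussian noise: a
# zero-mean white process is band-pass filtered (zero-phase 4th-order
# Butterworth, emulating the hardware acquisition band) and multiplied by a
# per-channel amplitude envelope. The methods exercised downstream depend only
# on amplitude and spectral statistics, so no motor-unit physiology is
# simulated.

band_carrier <- function(n, fs, band_hz) {
  bf <- signal::butter(4, band_hz / (fs / 2), type = "pass")
  # pad to suppress filtfilt edge transients, then trim
  pad <- min(n, 4L * ceiling(fs / band_hz[1]))
  x <- signal::filtfilt(bf, rnorm(n + 2L * pad))
  x <- x[(pad + 1L):(pad + n)]
  x / sd(x)
}

# Normalized contraction envelope (0 at the boundaries, 1 over the hold).
contraction_envelope <- function(n_ramp, n_hold, shape = c("cosine", "linear")) {
  shape <- match.arg(shape)
  t_up <- seq_len(n_ramp) / n_ramp
  up <- switch(shape,
    cosine = 0.5 - 0.5 * cos(pi * t_up),
    linear = t_up
  )
  c(up, rep(1, n_hold), rev(up))
}

#' Generate one synthetic recording session
#'
#' Produces a multichannel recording in which each of the protocol's classes
#' (including rest) appears `reps_per_session` times in a seed-determined
#' random order. Active-class contractions follow the ramp/hold/ramp envelope;
#' the rest class and inter-contraction intervals carry the rest-level carrier
#' only. Every sample is covered by exactly one annotation.
#'
#' @param subject An [emg_subject()].
#' @param protocol An [emg_protocol()].
#' @param session_index Session number in `1..n_sessions`.
#' @param seed Integer seed controlling contraction order and noise.
#' @return An object of class `emg_session`: a list with `signal`
#'   (`n_channels x n_samples` matrix), `fs`, and `annotations`, a tibble of
#'   half-open 0-based sample intervals `(start, end, class_id, phase)` with
#'   `phase` one of `"rest"`, `"ramp_up"`, `"hold"`, `"ramp_down"`.
#' @examples
#' p <- emg_protocol(n_classes = 3, n_channels = 2, fs = 256,
#'                   ramp_s = 0.5, hold_s = 1, rest_s = 0.5)
#' s <- generate_session(make_subject(p, 1), p, 1, seed = 2)
#' dim(s$signal)
#' @export
generate_session <- function(subject, protocol, session_index, seed) {
  stopifnot(inherits(subject, "emg_subject"), inherits(protocol, "emg_protocol"))
  session_index <- assert_count(session_index, "session_index")
  if (session_index > protocol$n_sessions) {
    abort("`session_index` must be in 1..n_sessions.")
  }
  seed <- assert_count(seed, "seed", min = 0L)

  fs <- protocol$fs
  n_ramp <- as.integer(round(protocol$ramp_s * fs))
  n_hold <- as.integer(round(protocol$hold_s * fs))
  n_rest <- as.integer(round(protocol$rest_s * fs))
  n_contr <- 2L * n_ramp + n_hold
  n_slots <- protocol$n_classes * protocol$reps_per_session
  n_samples <- n_slots * (n_rest + n_contr) + n_rest

  with_seed(seed, {
    order <- sample(rep(seq_len(protocol$n_classes), protocol$reps_per_session))

    ann <- vector("list", 4L * n_slots + 1L)
    ai <- 0L
    pos <- 0L
    push <- function(len, class_id, phase) {
      ai <<- ai + 1L
      ann[[ai]] <<- list(start = pos, end = pos + len,
                         class_id = class_id, phase = phase)
      pos <<- pos + len
    }

    # per-channel amplitude envelope, in units of the rest noise SD
    amp <- matrix(1, protocol$n_channels, n_samples)
    peak_gain <- 10^(subject$snr_db / 20)
    env <- contraction_envelope(n_ramp, n_hold, protocol$envelope)
    # EMG amplitude does not track limb position: movement demands activity
    # near the hold level, with short rise/fall skirts at the rest boundaries
    n_tau <- max(1L, round(protocol$onset_tau_s * fs))
    skirt <- rep(1, n_contr)
    ramp_in <- 0.5 - 0.5 * cos(pi * seq_len(min(n_tau, n_contr)) /
                                 min(n_tau, n_contr))
    skirt[seq_along(ramp_in)] <- ramp_in
    skirt[n_contr + 1 - seq_along(ramp_in)] <-
      pmin(skirt[n_contr + 1 - seq_along(ramp_in)], ramp_in)
    amp_env <- skirt *
      (protocol$dyn_amplitude + (1 - protocol$dyn_amplitude) * env)

    for (slot in seq_len(n_slots)) {
      cls <- order[slot]
      push(n_rest, protocol$rest_class, "rest")
      if (cls == protocol$rest_class) {
        push(n_contr, protocol$rest_class, "rest")
      } else {
        idx <- pos + seq_len(n_contr) # 1-based sample indices of contraction
        rep_scale <- exp(rnorm(1, 0, 0.05)) # trial-to-trial amplitude jitter
        # coordination blends from the movement pattern into the holding
        # pattern as the target position is approached; the overall drive is
        # maintained (unit channel maximum) while relative weights shift
        blend <- outer(subject$activation_dyn[cls, ], 1 - env) +
          outer(subject$activation[cls, ], env)
        blend <- sweep(blend, 2, pmax(apply(blend, 2, max), 1e-12), `/`)
        g <- peak_gain * subject$activity[cls] * rep_scale * blend
        amp[, idx] <- 1 + pmax(g - 1, 0) *
          matrix(amp_env, protocol$n_channels, n_contr, byrow = TRUE)
        push(n_ramp, cls, "ramp_up")
        push(n_hold, cls, "hold")
        push(n_ramp, cls, "ramp_down")
      }
    }
    push(n_rest, protocol$rest_class, "rest")

    sig <- matrix(0, protocol$n_channels, n_samples)
    for (ch in seq_len(protocol$n_channels)) {
      x <- band_carrier(n_samples, fs, protocol$band_hz) * amp[ch, ]
      sig[ch, ] <- x - mean(x)
    }

    annotations <- dplyr::bind_rows(lapply(ann[seq_len(ai)], as_tibble))
    emg_session(sig, fs, annotations,
                subject_id = subject$id, session = session_index)
  })
}

#' Construct a recording session object
#'
#' @param signal `n_channels x n_samples` numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param annotations Tibble with columns `start`, `end` (half-open, 0-based
#'   sample intervals), `class_id`, `phase`; must be sorted, non-overlapping,
#'   and cover every sample exactly once.
#' @param subject_id,session Provenance identifiers.
#' @return An `emg_session` object.
#' @export
emg_session <- function(signal, fs, annotations, subject_id = NA, session = NA) {
  signal <- as.matrix(signal)
  annotations <- as_tibble(annotations)
  need <- c("start", "end", "class_id", "phase")
  if (!all(need %in% names(annotations))) {
    abort("`annotations` must have columns start, end, class_id, phase.")
  }
  annotations <- arrange(annotations, .data$start)
  if (any(annotations$end <= annotations$start)) {
    abort("annotations must be non-empty half-open intervals.")
  }
  if (nrow(annotations) > 1 &&
      any(annotations$start[-1] != annotations$end[-nrow(annotations)])) {
    abort("annotations must tile the signal without gaps or overlaps.")
  }
  if (annotations$start[1] != 0 ||
      annotations$end[nrow(annotations)] != ncol(signal)) {
    abort("annotations must cover exactly the signal duration.")
  }
  structure(
    list(signal = signal, fs = fs, annotations = annotations,
         subject_id = subject_id, session = session),
    class = "emg_session"
  )
}

#' @export
print.emg_session <- function(x, ...) {
  cat(sprintf(
    "<emg_session> subject %s session %s: %d ch x %d samples (%.1f s @ %g Hz), %d annotations\n",
    format(x$subject_id), format(x$session), nrow(x$signal), ncol(x$signal),
    ncol(x$signal) / x$fs, x$fs, nrow(x$annotations)
  ))
  invisible(x)
}

#' Active-contraction intervals of a session
#'
#' Collapses consecutive ramp/hold/ramp annotations of one active class into a
#' single `(start, end, class_id)` contraction interval.
#'
#' @param session An `emg_session` (or its annotations tibble).
#' @return Tibble with one row per active contraction.
#' @export
contraction_intervals <- function(session) {
  ann <- if (inherits(session, "emg_session")) session$annotations else session
  act <- ann[ann$phase != "rest", , drop = FALSE]
  if (nrow(act) == 0) {
    return(tibble(start = integer(), end = integer(), class_id = integer()))
  }
  grp <- cumsum(c(TRUE, act$start[-1] != act$end[-nrow(act)] |
                    act$class_id[-1] != act$class_id[-nrow(act)]))
  act |>
    mutate(.grp = grp) |>
    group_by(.data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              class_id = .data$class_id[1], .groups = "drop") |>
    select(-dplyr::any_of(".grp"))
}

#' Generate a complete multi-subject dataset
#'
#' Draws `n_subjects` subject models with seeds derived reproducibly from
#' `master_seed` and generates `n_sessions` recording sessions for each.
#'
#' @param protocol An [emg_protocol()].
#' @param n_subjects Number of subjects (default 8).
#' @param master_seed Integer master seed; the whole dataset is a
#'   deterministic function of `(protocol, n_subjects, master_seed)`.
#' @return A list with one element per subject, each a list of `subject`
#'   (an `emg_subject`) and `sessions` (list of `emg_session`).
#' @export
generate_dataset <- function(protocol, n_subjects = 8, master_seed = 1) {
  stopifnot(inherits(protocol, "emg_protocol"))
  n_subjects <- assert_count(n_subjects, "n_subjects")
  subj_seeds <- derive_seeds(master_seed, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    subject <- make_subject(protocol, seed = subj_seeds[i], id = i)
    ses_seeds <- derive_seeds(subj_seeds[i], protocol$n_sessions)
    sessions <- lapply(seq_len(protocol$n_sessions), function(k) {
      generate_session(subject, protocol, k, seed = ses_seeds[k])
    })
    list(subject = subject, sessions = sessions)
  })
}
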