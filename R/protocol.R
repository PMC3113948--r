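#' Recording protocol specification
#'
#' Describes the structure of one recording study: number of motion classes
#' (the last class is rest / "no motion"), number of bipolar channels,
#' sampling rate, repetitions per session, number of sessions, and the
#' temporal layout of each contraction. Under the defaults every contraction
#' lasts 10 s: a 3 s rest-to-target ramp, a 4 s static hold at the target,
#' and a 3 s target-to-rest ramp, with 3 s of rest between contractions.
#'
#' @param n_classes Number of motion classes including rest (default 9;
#'   class `n_classes` is rest).
#' @param n_channels Number of EMG channels (default 6).
#' @param fs Sampling rate in Hz (default 1024).
#' @param reps_per_session Repetitions of each class per session (default 2).
#' @param n_sessions Recording sessions per subject (default 3).
#' @param ramp_s Duration in seconds of each dynamic ramp (default 3).
#' @param hold_s Duration in seconds of the static hold (default 4).
#' @param rest_s Rest in seconds between consecutive contractions (default 3).
#' @param band_hz Two-element pass band in Hz emulating the hardware filter
#'   (default `c(47, 440)`).
#' @param envelope Contraction envelope shape, `"cosine"` (raised-cosine
#'   ramps, default) or `"linear"`.
#' @param snr_db_range Range the per-subject signal-to-rest-noise ratio (dB)
#'   is drawn from (default `c(10, 25)`).
#' @param activity_range Range of per-class peak normalized activity
#'   (default `c(0.56, 0.92)`).
#' @param dyn_amplitude Relative EMG amplitude sustained during the dynamic
#'   ramps (default 0.9): moving a limb demands muscle activity comparable
#'   to holding the target, so the amplitude envelope stays near the hold
#'   level throughout the movement rather than tracking limb position; the
#'   envelope blends from `dyn_amplitude` to 1 as the target is approached.
#' @param onset_tau_s Duration in seconds of the rise/fall transition
#'   between rest-level and movement-level amplitude at each end of a
#'   contraction (default 0.25).
#'
#' @return An object of class `emg_protocol`.
#' @examples
#' p <- emg_protocol()
#' p$contraction_s # 10 s under the defaults
#' @export
emg_protocol <- function(n_classes = 9, n_channels = 6, fs = 1024,
                         reps_per_session = 2, n_sessions = 3,
                         ramp_s = 3, hold_s = 4, rest_s = 3,
                         band_hz = c(47, 440),
                         envelope = c("cosine", "linear"),
                         snr_db_range = c(10, 25),
                         activity_range = c(0.56, 0.92),
                         dyn_amplitude = 0.9, onset_tau_s = 0.25) {
  n_classes <- assert_count(n_classes, "n_classes", min = 2L)
  n_channels <- assert_count(n_channels, "n_channels", min = 1L)
  fs <- assert_positive(fs, "fs")
  reps_per_session <- assert_count(reps_per_session, "reps_per_session")
  n_sessions <- assert_count(n_sessions, "n_sessions")
  ramp_s <- assert_positive(ramp_s, "ramp_s")
  hold_s <- assert_positive(hold_s, "hold_s")
  rest_s <- assert_positive(rest_s, "rest_s")
  envelope <- match.arg(envelope)
  if (length(band_hz) != 2L || band_hz[1] <= 0 || band_hz[2] <= band_hz[1] ||
      band_hz[2] >= fs / 2) {
    abort("`band_hz` must be increasing and inside (0, fs/2).")
  }
  structure(
    list(
      n_classes = n_classes, n_channels = n_channels, fs = fs,
      reps_per_session = reps_per_session, n_sessions = n_sessions,
      ramp_s = ramp_s, hold_s = hold_s, rest_s = rest_s,
      band_hz = as.numeric(band_hz), envelope = envelope,
      snr_db_range = as.numeric(snr_db_range),
      activity_range = as.numeric(activity_range),
      dyn_amplitude = assert_positive(dyn_amplitude, "dyn_amplitude"),
      onset_tau_s = assert_positive(onset_tau_s, "onset_tau_s"),
      rest_class = n_classes,
      contraction_s = 2 * ramp_s + hold_s
    ),
    class = "emg_protocol"
  )
}

#' @export
print.emg_protocol <- function(x, ...) {
  cat(sprintf(
    paste0("<emg_protocol> %d classes (rest = %d), %d channels, fs = %g Hz\n",
           "  %d session(s) x %d rep(s)/class; contraction %gs ",
           "(%gs ramp / %gs hold / %gs ramp), %gs inter-rest\n"),
    x$n_classes, x$rest_class, x$n_channels, x$fs,
    x$n_sessions, x$reps_per_session, x$contraction_s,
    x$ramp_s, x$hold_s, x$ramp_s, x$rest_s
  ))
  invisible(x)
}

#' Subject model for synthetic EMG generation
#'
#' A subject is described by a class-by-channel activation matrix (relative
#' peak amplitude of each channel in each motion class, rest row all zero), a
#' signal-to-rest-noise ratio in dB, and a per-class peak normalized activity
#' level. `make_subject()` draws a random subject consistent with a protocol;
#' `emg_subject()` builds one from explicit components (useful for controlled
#' experiments, e.g. orthogonal activation patterns).
#'
#' @param protocol An [emg_protocol()].
#' @param seed Integer seed; the subject is a deterministic function of
#'   `(protocol, seed)`.
#' @param id Optional subject identifier.
#' @return An object of class `emg_subject`.
#' @examples
#' s <- make_subject(emg_protocol(), seed = 1)
#' dim(s$activation) # n_classes x n_channels
#' @export
make_subject <- function(protocol, seed, id = 1L) {
  stopifnot(inherits(protocol, "emg_protocol"))
  if (protocol$n_classes < 2 || protocol$n_channels < 1) {
    abort("invalid protocol: need n_classes >= 2 and n_channels >= 1.")
  }
  seed <- assert_count(seed, "seed", min = 0L)
  with_seed(seed, {
    n_active <- protocol$n_classes - 1L
    nc <- protocol$n_channels
    draw_patterns <- function() {
      act <- matrix(0, protocol$n_classes, nc)
      for (k in seq_len(n_active)) {
        for (try in 1:100) {
          row <- runif(nc)^1.5
          row <- row / max(row)
          if (k == 1L ||
              min(apply(act[seq_len(k - 1L), , drop = FALSE], 1,
                        function(r) max(abs(r - row)))) > 0.15) {
            break
          }
        }
        act[k, ] <- row
      }
      act
    }
    act <- draw_patterns()
    # movement-phase muscle coordination differs from the holding pattern:
    # each class gets a second pattern used during the ramps
    act_dyn <- draw_patterns()
    snr_db <- runif(1, protocol$snr_db_range[1], protocol$snr_db_range[2])
    activity <- c(
      runif(n_active, protocol$activity_range[1], protocol$activity_range[2]),
      0
    )
    emg_subject(act, snr_db, activity, activation_dyn = act_dyn,
                seed = seed, id = id)
  })
}

#' @rdname make_subject
#' @param activation `n_classes x n_channels` matrix of relative peak
#'   amplitudes in `[0, 1]`; the last (rest) row must be all zero and rows of
#'   active classes must be pairwise distinct with at least one channel above
#'   rest.
#' @param snr_db Signal-to-rest-noise ratio in dB.
#' @param activity Per-class peak normalized activity in `[0, 1]` (rest entry
#'   0).
#' @param activation_dyn Optional `n_classes x n_channels` matrix of
#'   relative channel amplitudes during the dynamic ramps; the effective
#'   pattern blends from this towards `activation` as the target position is
#'   approached. Defaults to `activation` (ramps are then pure amplitude
#'   scalings of the hold pattern).
#' @export
emg_subject <- function(activation, snr_db, activity, activation_dyn = NULL,
                        seed = NA_integer_, id = 1L) {
  activation <- as.matrix(activation)
  n_classes <- nrow(activation)
  if (any(activation < 0) || any(activation > 1)) {
    abort("`activation` entries must lie in [0, 1].")
  }
  if (any(activation[n_classes, ] != 0)) {
    abort("rest (last) row of `activation` must be all zero.")
  }
  active <- activation[-n_classes, , drop = FALSE]
  if (any(apply(active, 1, max) <= 0)) {
    abort("every active class must activate at least one channel above rest.")
  }
  if (nrow(active) > 1) {
    for (i in seq_len(nrow(active) - 1L)) {
      for (j in (i + 1L):nrow(active)) {
        if (all(active[i, ] == active[j, ])) {
          abort("active classes must have pairwise distinct activation rows.")
        }
      }
    }
  }
  if (length(activity) != n_classes || any(activity < 0) || any(activity > 1)) {
    abort("`activity` must have one value in [0, 1] per class.")
  }
  activation_dyn <- activation_dyn %||% activation
  activation_dyn <- as.matrix(activation_dyn)
  if (!identical(dim(activation_dyn), dim(activation)) ||
      any(activation_dyn < 0) || any(activation_dyn > 1)) {
    abort("`activation_dyn` must match `activation` in shape with entries in [0, 1].")
  }
  structure(
    list(activation = activation, activation_dyn = activation_dyn,
         snr_db = as.numeric(snr_db), activity = as.numeric(activity),
         seed = seed, id = id),
    class = "emg_subject"
  )
}

#' @export
print.emg_subject <- function(x, ...) {
  cat(sprintf("<emg_subject> id %s: %d classes x %d channels, SNR %.1f dB\n",
              format(x$id), nrow(x$activation), ncol(x$activation), x$snr_db))
  invisible(x)
}
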