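#' Analysis window specification
#'
#' Fixed-length overlapping windows: window `k` (0-based) starts at sample
#' `k * step_samples`. The defaults (128 samples at 1024 Hz, step 32) give
#' 125 ms windows with 96 samples of overlap between consecutive windows.
#'
#' @param length_samples Window length in samples (default 128).
#' @param step_samples Hop between consecutive window starts (default 32);
#'   must satisfy `0 < step_samples <= length_samples`.
#' @param fs Sampling rate in Hz (default 1024).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(length_samples = 128, step_samples = 32, fs = 1024) {
  length_samples <- assert_count(length_samples, "length_samples")
  step_samples <- assert_count(step_samples, "step_samples")
  fs <- assert_positive(fs, "fs")
  if (step_samples > length_samples) {
    abort("`step_samples` must be <= `length_samples`.")
  }
  structure(
    list(length_samples = length_samples, step_samples = step_samples,
         fs = fs, length_ms = 1000 * length_samples / fs),
    class = "window_spec"
  )
}

#' @export
print.window_spec <- function(x, ...) {
  cat(sprintf("<window_spec> %d samples (%g ms) @ %g Hz, step %d (overlap %d)\n",
              x$length_samples, x$length_ms, x$fs, x$step_samples,
              x$length_samples - x$step_samples))
  invisible(x)
}

#' Time span covered by a fused decision
#'
#' A majority vote over the `n_votes` most recent windows uses
#' `length_samples + (n_votes - 1) * step_samples` samples of signal. Under
#' the default window specification and 6 votes this is 281.25 ms.
#'
#' @param spec A [window_spec()].
#' @param n_votes Number of window decisions entering the vote.
#' @return Span in milliseconds.
#' @examples
#' decision_span_ms(window_spec(), 6) # 281.25
#' @export
decision_span_ms <- function(spec, n_votes) {
  stopifnot(inherits(spec, "window_spec"))
  n_votes <- assert_count(n_votes, "n_votes")
  1000 * (spec$length_samples + (n_votes - 1) * spec$step_samples) / spec$fs
}

#' Segment a session into overlapping windows
#'
#' Produces `floor((n_samples - length_samples) / step_samples) + 1` windows;
#' trailing samples that do not fill a final window are dropped. Each window
#' is labelled with the class and phase of the annotation covering the
#' majority of its samples; ties go to the later-starting annotation.
#'
#' @param session An [emg_session()].
#' @param spec A [window_spec()]; its `fs` must match the session.
#' @return An object of class `emg_windows`: list with `spec`, `starts`
#'   (0-based window start samples), `labels` (tibble `window`,
#'   `start_sample`, `class_id`, `phase`), and the originating `session`.
#' @export
segment <- function(session, spec = window_spec()) {
  stopifnot(inherits(session, "emg_session"), inherits(spec, "window_spec"))
  if (!isTRUE(all.equal(spec$fs, session$fs))) {
    abort("window spec and session sampling rates differ.")
  }
  n <- ncol(session$signal)
  len <- spec$length_samples
  if (n < len) {
    abort("signal is shorter than one window; nothing to segment.",
          class = "emgdyn_empty_series")
  }
  starts <- seq.int(0L, n - len, by = spec$step_samples)
  lab <- window_labels(session$annotations, starts, len)
  structure(
    list(spec = spec, starts = starts,
         labels = tibble(window = seq_along(starts), start_sample = starts,
                         class_id = lab$class_id, phase = lab$phase),
         session = session),
    class = "emg_windows"
  )
}

# Majority-of-samples labelling with later-annotation tie-break.
window_labels <- function(ann, starts, len) {
  s_idx <- findInterval(starts, ann$start)
  e_idx <- findInterval(starts + len - 1L, ann$start)
  class_id <- ann$class_id[s_idx]
  phase <- ann$phase[s_idx]
  straddle <- which(e_idx > s_idx)
  for (w in straddle) {
    best <- s_idx[w]
    best_ov <- -1L
    for (a in s_idx[w]:e_idx[w]) {
      ov <- min(ann$end[a], starts[w] + len) - max(ann$start[a], starts[w])
      if (ov >= best_ov) { # >= so later annotations win ties
        best_ov <- ov
        best <- a
      }
    }
    class_id[w] <- ann$class_id[best]
    phase[w] <- ann$phase[best]
  }
  list(class_id = class_id, phase = phase)
}

#' @export
print.emg_windows <- function(x, ...) {
  cat(sprintf("<emg_windows> %d windows of %d samples (step %d) over %d channels\n",
              length(x$starts), x$spec$length_samples, x$spec$step_samples,
              nrow(x$session$signal)))
  invisible(x)
}

#' Extract one channel's windows as a matrix
#'
#' @param windows An [segment()] result.
#' @param channel Channel index.
#' @param subset Optional window indices (default all).
#' @return `length_samples x n_windows` matrix, one window per column.
#' @export
window_matrix <- function(windows, channel, subset = NULL) {
  stopifnot(inherits(windows, "emg_windows"))
  starts <- windows$starts
  if (!is.null(subset)) starts <- starts[subset]
  len <- windows$spec$length_samples
  idx <- outer(seq_len(len), starts, `+`) # starts are 0-based
  matrix(windows$session$signal[channel, idx], nrow = len)
}
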