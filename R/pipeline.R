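# Decision pipeline: training-section selection, threshold gating,
# classification, and causal majority-vote fusion.

#' Training sections
#'
#' The five temporal training-set compositions evaluated by the pipeline,
#' as fractions of each contraction centered on its midpoint: the static
#' hold only (`static_4s`), the hold plus one third (`dynamic1_6s`) or two
#' thirds (`dynamic2_8s`) of each ramp, the entire contraction (`all_10s`),
#' and a data-driven section keeping only windows whose activity crosses the
#' calibrated threshold (`threshold_based`). Under the default protocol
#' (3 s ramps, 4 s hold) the time-based sections span 4, 6, 8 and 10 s.
#'
#' @return Character vector of section names.
#' @export
training_sections <- function() {
  c("static_4s", "dynamic1_6s", "dynamic2_8s", "all_10s", "threshold_based")
}

section_ramp_fraction <- c(static_4s = 0, dynamic1_6s = 1 / 3,
                           dynamic2_8s = 2 / 3, all_10s = 1)

#' Select training windows for a section
#'
#' Time-based sections keep windows lying fully inside the interval centered
#' on each contraction's midpoint (`static_4s` \\eqn{\\subset}
#' `dynamic1_6s` \\eqn{\\subset} `dynamic2_8s` \\eqn{\\subset} `all_10s`);
#' the threshold-based section keeps contraction windows whose activity
#' crosses the calibrated threshold. Only active-class contractions
#' contribute (rest is handled by the gate at decision time).
#'
#' @param windows An [segment()] result.
#' @param section One of [training_sections()].
#' @param threshold A [calibrate_threshold()] model (required for
#'   `threshold_based`).
#' @param section_s Optional explicit section length in seconds overriding
#'   the protocol-relative default; it is an error for it to exceed the
#'   contraction duration.
#' @return Integer vector of selected window indices.
#' @export
select_training_windows <- function(windows, section, threshold = NULL,
                                    section_s = NULL) {
  stopifnot(inherits(windows, "emg_windows"))
  section <- match.arg(section, training_sections())
  contr <- contraction_intervals(windows$session)
  if (nrow(contr) == 0) return(integer())
  fs <- windows$spec$fs
  len <- windows$spec$length_samples
  starts <- windows$starts

  if (section == "threshold_based") {
    if (is.null(threshold)) {
      abort("`threshold_based` selection requires a calibrated threshold model.")
    }
    in_contr <- rep(FALSE, length(starts))
    for (i in seq_len(nrow(contr))) {
      in_contr <- in_contr |
        (starts >= contr$start[i] & starts + len <= contr$end[i])
    }
    act <- is_active(activity_matrix(windows), threshold)
    return(which(in_contr & act))
  }

  hold_len <- {
    hold_ann <- windows$session$annotations
    hold_ann <- hold_ann[hold_ann$phase == "hold", , drop = FALSE]
    if (nrow(hold_ann) == 0) abort("session has no hold-phase annotations.")
    stats::median(hold_ann$end - hold_ann$start)
  }
  keep <- rep(FALSE, length(starts))
  for (i in seq_len(nrow(contr))) {
    c_len <- contr$end[i] - contr$start[i]
    span <- if (is.null(section_s)) {
      hold_len + section_ramp_fraction[[section]] * (c_len - hold_len)
    } else {
      round(section_s * fs)
    }
    if (span > c_len) {
      abort("training section is longer than the contraction.")
    }
    mid <- (contr$start[i] + contr$end[i]) / 2
    lo <- mid - span / 2
    hi <- mid + span / 2
    keep <- keep | (starts >= lo & starts + len <= hi)
  }
  which(keep)
}

#' Causal majority vote over recent decisions
#'
#' The fused label at position `k` is the most frequent label among the
#' `depth` most recent raw labels (fewer at the start of the stream). Ties
#' are broken in favour of the most recently observed label among the tied
#' candidates.
#'
#' @param labels Factor (or vector) of raw window labels in stream order.
#' @param depth Vote depth (default 6).
#' @return Factor of fused labels, same length and levels as `labels`.
#' @examples
#' majority_vote(factor(c("A", "A", "A", "B", "B", "A")), depth = 6) # ends A
#' @export
majority_vote <- function(labels, depth = 6) {
  depth <- assert_count(depth, "depth")
  labels <- as.factor(labels)
  n <- length(labels)
  if (n == 0) return(labels)
  li <- as.integer(labels)
  k <- nlevels(labels)
  # windowed counts via cumulative sums of one-hot indicators
  counts <- matrix(0L, n, k)
  for (cl in seq_len(k)) {
    cs <- cumsum(li == cl)
    lag <- c(rep(0L, min(depth, n)), cs[seq_len(max(n - depth, 0))])
    counts[, cl] <- cs - lag
  }
  best <- max.col(counts, ties.method = "first")
  maxc <- counts[cbind(seq_len(n), best)]
  tied_rows <- which(rowSums(counts == maxc) > 1L)
  for (i in tied_rows) {
    tied <- which(counts[i, ] == maxc[i])
    for (j in i:max(1L, i - depth + 1L)) { # scan backwards for most recent
      if (li[j] %in% tied) {
        best[i] <- li[j]
        break
      }
    }
  }
  factor(levels(labels)[best], levels = levels(labels))
}

#' Run the gated classification pipeline over a window stream
#'
#' Each window is labelled rest unless its activity crosses the calibrated
#' threshold, in which case the classifier assigns one of the active
#' classes; the fused decision is the causal majority vote over the most
#' recent `vote_depth` raw labels. With `gate = FALSE` every window is
#' classified (no rest gating), which reproduces the ungated error profile.
#'
#' @param windows The held-out session's [segment()] result.
#' @param threshold A calibrated [calibrate_threshold()] model.
#' @param model A fitted [fit_classifier()] model over the active classes.
#' @param features The matching [extract_features()] result for `windows`
#'   (computed externally so it can be cached across pipeline runs).
#' @param vote_depth Majority-vote depth (default 6).
#' @param gate Apply the activity gate (default `TRUE`).
#' @param rest_class Rest label (default: max class id in the annotations).
#' @return An object of class `emg_decisions`: tibble with `window`,
#'   `start_sample`, `truth`, `active`, `raw`, and `fused` columns.
#' @export
classify_stream <- function(windows, threshold, model, features,
                            vote_depth = 6, gate = TRUE, rest_class = NULL) {
  stopifnot(inherits(windows, "emg_windows"),
            inherits(model, "emg_classifier"),
            inherits(features, "emg_features"))
  if (nrow(features$X) != length(windows$starts)) {
    abort("features do not match the window series.")
  }
  rest_class <- rest_class %||% max(windows$session$annotations$class_id)
  lvls <- unique(c(model$classes, as.character(rest_class),
                   as.character(sort(unique(windows$labels$class_id)))))

  active <- if (gate) {
    is_active(activity_matrix(windows), threshold)
  } else {
    rep(TRUE, length(windows$starts))
  }
  raw <- factor(rep(as.character(rest_class), length(active)), levels = lvls)
  if (any(active)) {
    pred <- predict(model, features$X[active, , drop = FALSE])
    raw[active] <- factor(as.character(pred), levels = lvls)
  }
  fused <- majority_vote(raw, vote_depth)
  out <- tibble(
    window = windows$labels$window,
    start_sample = windows$labels$start_sample,
    truth = factor(as.character(windows$labels$class_id), levels = lvls),
    active = active,
    raw = raw,
    fused = fused
  )
  class(out) <- c("emg_decisions", class(out))
  attr(out, "vote_depth") <- vote_depth
  attr(out, "gate") <- gate
  out
}
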