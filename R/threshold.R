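# Teager-Kaiser energy-based onset detection and per-subject threshold
# calibration.

#' Teager-Kaiser energy operator
#'
#' Computes `y[n] = x[n]^2 - x[n-1] * x[n+1]` for the interior samples of
#' `x`; the output is two samples shorter than the input. For a sinusoid
#' `A * sin(w n)` the operator returns the constant `A^2 * sin(w)^2`.
#'
#' @param x Numeric vector, length >= 3.
#' @return Numeric vector of length `length(x) - 2`.
#' @examples
#' tkeo(c(1, 2, 3)) # 2^2 - 1 * 3 = 1
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3) abort("`x` must have at least 3 samples.")
  x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
}

#' Per-channel activity of one window
#'
#' The activity statistic is the mean absolute Teager-Kaiser energy of the
#' window, computed per channel. Being quadratic in amplitude, doubling the
#' signal quadruples the activity.
#'
#' @param window `n_channels x n_samples` matrix (>= 3 samples).
#' @return Numeric vector of per-channel activities.
#' @export
window_activity <- function(window) {
  window <- as.matrix(window)
  if (ncol(window) < 3) abort("window must have at least 3 samples.")
  apply(window, 1, function(x) mean(abs(tkeo(x))))
}

# Activities of every window in a series: n_windows x n_channels matrix.
# Cached on the windows object by cache_activities().
activity_matrix <- function(windows) {
  stopifnot(inherits(windows, "emg_windows"))
  if (!is.null(windows$activities)) return(windows$activities)
  n_ch <- nrow(windows$session$signal)
  out <- matrix(0, length(windows$starts), n_ch)
  for (ch in seq_len(n_ch)) {
    M <- window_matrix(windows, ch)
    l <- nrow(M)
    tk <- M[2:(l - 1), , drop = FALSE]^2 -
      M[1:(l - 2), , drop = FALSE] * M[3:l, , drop = FALSE]
    out[, ch] <- colMeans(abs(tk))
  }
  out
}

# Precompute and attach the activity matrix (idempotent).
cache_activities <- function(windows) {
  windows$activities <- activity_matrix(windows)
  windows
}

#' Log-spaced calibration grid for the threshold coefficient
#'
#' @param from,to Grid end points (defaults `1e-1` and `1e3`).
#' @param n Number of grid points (default 400).
#' @return Increasing numeric vector.
#' @export
threshold_grid <- function(from = 1e-1, to = 1e3, n = 400) {
  10^seq(log10(from), log10(to), length.out = n)
}

#' Calibrate the onset-detection threshold
#'
#' The threshold model compares each channel's window activity against
#' `coefficient * rest_activity[channel]`; a window is active if at least one
#' channel crosses its threshold (strict inequality). The per-channel rest
#' reference is the mean activity over rest-phase windows of the training
#' data, and the coefficient is the largest grid value for which (a) strictly
#' more than `overall_min` of all static (hold-phase) windows of active
#' classes are detected active, and (b) at least `class_min` of each
#' individual class's hold windows are detected active. The detected-active
#' set shrinks monotonically as the coefficient grows, so a grid scan finds
#' the exact maximizer at grid resolution.
#'
#' @param windows An `emg_windows` object or list of them (the training
#'   sessions); calibration uses only their hold-phase and rest-phase
#'   windows.
#' @param overall_min Minimum overall fraction of active-class hold windows
#'   detected active, exceeded strictly (default 0.97).
#' @param class_min Minimum per-class fraction, met weakly (default 0.85).
#' @param grid Candidate coefficients, see [threshold_grid()].
#' @param rest_class Rest class id (default: maximum class id present).
#' @return An object of class `threshold_model`: `rest_activity`
#'   (per channel), `coefficient`, `constraints`, and achieved `coverage`.
#' @export
calibrate_threshold <- function(windows, overall_min = 0.97, class_min = 0.85,
                                grid = threshold_grid(), rest_class = NULL) {
  if (inherits(windows, "emg_windows")) windows <- list(windows)
  stopifnot(all(vapply(windows, inherits, TRUE, "emg_windows")))
  grid <- sort(grid)
  if (any(grid <= 0)) abort("`grid` values must be positive.")

  acts <- lapply(windows, activity_matrix)
  labels <- lapply(windows, function(w) w$labels)
  act <- do.call(rbind, acts)
  lab <- dplyr::bind_rows(labels)
  rest_class <- rest_class %||% max(lab$class_id)

  rest_rows <- lab$phase == "rest"
  hold_rows <- lab$phase == "hold" & lab$class_id != rest_class
  if (!any(rest_rows)) abort("no rest-phase windows available for calibration.")
  if (!any(hold_rows)) abort("no hold-phase training windows available.")

  rest_activity <- colMeans(act[rest_rows, , drop = FALSE])
  if (any(rest_activity <= 0)) {
    abort("rest activity must be positive on every channel.")
  }

  # max over channels of activity relative to rest: window active iff
  # coefficient < ratio, so feasibility is monotone in the coefficient.
  ratio <- apply(
    act[hold_rows, , drop = FALSE] /
      matrix(rest_activity, sum(hold_rows), length(rest_activity), byrow = TRUE),
    1, max
  )
  cls <- lab$class_id[hold_rows]

  feasible <- vapply(grid, function(co) {
    active <- ratio > co
    (overall_min <= 0 || mean(active) > overall_min) &&
      all(vapply(split(active, cls), mean, 0) >= class_min)
  }, logical(1))

  if (!any(feasible)) {
    best <- vapply(grid, function(co) mean(ratio > co), 0)
    abort(sprintf(
      paste0("no feasible threshold coefficient on the grid; best overall ",
             "hold coverage %.3f at coefficient %.4g."),
      max(best), grid[which.max(best)]
    ), class = "emgdyn_infeasible_calibration")
  }
  coefficient <- max(grid[feasible])

  active <- ratio > coefficient
  structure(
    list(
      rest_activity = rest_activity,
      coefficient = coefficient,
      constraints = c(overall_min = overall_min, class_min = class_min),
      coverage = list(overall = mean(active),
                      per_class = vapply(split(active, cls), mean, 0)),
      grid_range = range(grid)
    ),
    class = "threshold_model"
  )
}

#' Activity gate: is a window active?
#'
#' @param activity Per-channel activity vector (from [window_activity()]) or
#'   an `n_windows x n_channels` matrix of activities.
#' @param model A calibrated [calibrate_threshold()] model.
#' @return Logical (scalar or per-window vector): `TRUE` when at least one
#'   channel's activity strictly exceeds `coefficient * rest_activity`.
#' @export
is_active <- function(activity, model) {
  stopifnot(inherits(model, "threshold_model"))
  thr <- model$coefficient * model$rest_activity
  if (is.matrix(activity)) {
    rowSums(activity > matrix(thr, nrow(activity), length(thr), byrow = TRUE)) > 0
  } else {
    any(activity > thr)
  }
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf(
    "<threshold_model> coefficient %.4g; hold coverage %.3f (constraints >%g overall, >=%g per class)\n",
    x$coefficient, x$coverage$overall,
    x$constraints["overall_min"], x$constraints["class_min"]
  ))
  invisible(x)
}

#' @describeIn calibrate_threshold Per-channel rest reference activities as a
#'   tibble.
#' @param x A `threshold_model`.
#' @param ... Unused.
#' @method tidy threshold_model
#' @export
tidy.threshold_model <- function(x, ...) {
  tibble(channel = seq_along(x$rest_activity),
         rest_activity = unname(x$rest_activity),
         threshold = unname(x$coefficient * x$rest_activity))
}

#' @describeIn calibrate_threshold One-row model summary.
#' @method glance threshold_model
#' @export
glance.threshold_model <- function(x, ...) {
  tibble(coefficient = x$coefficient,
         overall_coverage = x$coverage$overall,
         min_class_coverage = min(x$coverage$per_class),
         n_channels = length(x$rest_activity))
}
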