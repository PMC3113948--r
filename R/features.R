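# Per-window feature extraction: the time-domain + autoregressive set (TD+AR)
# and wavelet-marginal set (WT), computed per channel and concatenated across
# channels.

#' Time-domain features of one window
#'
#' The classic four-feature time-domain set: mean absolute value (MAV),
#' zero-crossing count (ZC), slope-sign-change count (SSC), and waveform
#' length (WL). ZC and SSC use a deadzone threshold `eps` for noise
#' robustness: a zero crossing is counted when consecutive samples have
#' opposite (nonzero) signs and differ by at least `eps`; a slope sign change
#' is counted when `(x[i] - x[i-1]) * (x[i] - x[i+1]) > eps_ssc`, where
#' `eps_ssc = eps^2` (the product has squared-amplitude units).
#'
#' @param x Numeric vector (one window, one channel), length >= 2.
#' @param eps Deadzone threshold (default 0).
#' @return Named numeric vector `c(mav, zc, ssc, wl)`.
#' @examples
#' td_features(c(1, -1, 1, -1)) # mav 1, zc 3, ssc 2, wl 6
#' @export
td_features <- function(x, eps = 0) {
  if (length(x) < 2) abort("window must have at least 2 samples.")
  drop(td_features_matrix(matrix(x, ncol = 1L), eps = eps))
}

# Vectorized over windows: X is length x n_windows; eps scalar or per-window.
td_features_matrix <- function(X, eps = 0) {
  l <- nrow(X)
  d <- X[-1L, , drop = FALSE] - X[-l, , drop = FALSE]
  eps <- rep_len(eps, ncol(X))
  epsm <- matrix(eps, l - 1L, ncol(X), byrow = TRUE)
  mav <- colMeans(abs(X))
  wl <- colSums(abs(d))
  zc <- colSums((X[-l, , drop = FALSE] * X[-1L, , drop = FALSE] < 0) &
                  (abs(d) >= epsm))
  ssc <- if (l >= 3) {
    prod2 <- -(d[-(l - 1L), , drop = FALSE] * d[-1L, , drop = FALSE])
    colSums(prod2 > epsm[-1L, , drop = FALSE]^2)
  } else {
    rep(0, ncol(X))
  }
  rbind(mav = mav, zc = zc, ssc = ssc, wl = wl)
}

#' Autoregressive coefficients by Burg's method
#'
#' Fits an AR(`order`) model by Burg's recursion in the convention
#' `x[t] = a1 x[t-1] + ... + ap x[t-p] + e[t]`, so for an AR(1) process with
#' coefficient 0.9 the first returned coefficient is close to +0.9. A
#' zero-variance input yields all-zero coefficients (flagged with a warning).
#'
#' @param x Numeric vector, length > `order`.
#' @param order Model order (default 6).
#' @return Numeric vector of `order` coefficients.
#' @examples
#' x <- as.numeric(arima.sim(list(ar = 0.9), 4096))
#' ar_burg(x, 2)[1] # approximately 0.9
#' @export
ar_burg <- function(x, order = 6) {
  order <- assert_count(order, "order")
  if (length(x) <= order) abort("need more samples than the AR order.")
  drop(burg_matrix(matrix(x, ncol = 1L), order))
}

# Burg recursion vectorized over windows (columns of X). Zero-variance
# windows get all-zero coefficients as a defined fallback.
burg_matrix <- function(X, order = 6) {
  X <- as.matrix(X)
  w <- ncol(X)
  zv <- col_sds(X) == 0
  if (any(zv)) {
    warn("zero-variance window(s): returning all-zero AR coefficients.",
         class = "emgdyn_zero_variance")
  }
  f <- X # forward prediction errors
  b <- X # backward prediction errors
  A <- matrix(0, order, w)
  for (m in seq_len(order)) {
    fp <- f[-1L, , drop = FALSE]
    bp <- b[-nrow(b), , drop = FALSE]
    num <- 2 * colSums(fp * bp)
    den <- colSums(fp^2) + colSums(bp^2)
    k <- ifelse(den > 0, num / den, 0)
    if (m > 1L) {
      prev <- A[seq_len(m - 1L), , drop = FALSE]
      A[seq_len(m - 1L), ] <- prev -
        prev[rev(seq_len(m - 1L)), , drop = FALSE] *
          matrix(k, m - 1L, w, byrow = TRUE)
    }
    A[m, ] <- k
    km <- matrix(k, nrow(fp), w, byrow = TRUE)
    f <- fp - km * bp
    b <- bp - km * fp
  }
  A[, zv] <- 0
  A
}

col_sds <- function(X) {
  mu <- colMeans(X)
  sqrt(pmax(colMeans(X^2) - mu^2, 0))
}

#' Wavelet-marginal features of one window
#'
#' Decomposes the window with a periodized orthogonal DWT and returns the
#' marginal of each band: the sum of absolute coefficient values of every
#' detail band and of the final approximation band (`levels + 1` values).
#'
#' @param x Numeric vector whose length is a multiple of `2^levels`.
#' @param wavelet Mother wavelet (default `"coif4"`).
#' @param levels Decomposition depth (default 4).
#' @return Named numeric vector `c(d1, ..., d<levels>, a<levels>)`.
#' @examples
#' wt_marginals(rep(0, 128)) # all zero
#' @export
wt_marginals <- function(x, wavelet = "coif4", levels = 4) {
  drop(wt_marginals_matrix(matrix(x, ncol = 1L), wavelet, levels))
}

wt_marginals_matrix <- function(X, wavelet = "coif4", levels = 4) {
  co <- dwt_periodic(X, wavelet, levels)
  out <- do.call(rbind, lapply(co, function(b) colSums(abs(b))))
  rownames(out) <- names(co)
  out
}

#' Extract a feature matrix from a window series
#'
#' Computes per-channel features for every window and concatenates them
#' across channels. Under the defaults the TD+AR set yields
#' `n_channels * (4 + ar_order)` features (60 for 6 channels, order 6) and
#' the WT set `n_channels * (levels + 1)` features (30 for 6 channels,
#' 4 levels).
#'
#' @param windows An [segment()] result.
#' @param feature_set `"td_ar"` or `"wt"`.
#' @param ar_order AR model order for the TD+AR set (default 6).
#' @param wavelet,levels Wavelet configuration for the WT set.
#' @param zc_eps Deadzone for ZC/SSC: a number, or `"adaptive"` for
#'   `0.01 * RMS` of each window (default `0`).
#' @return An object of class `emg_features`: list with `X`
#'   (`n_windows x n_features` matrix with named columns), `feature_set`, and
#'   `meta` (the window label tibble).
#' @export
extract_features <- function(windows, feature_set = c("td_ar", "wt"),
                             ar_order = 6, wavelet = "coif4", levels = 4,
                             zc_eps = 0) {
  stopifnot(inherits(windows, "emg_windows"))
  feature_set <- match.arg(feature_set)
  n_ch <- nrow(windows$session$signal)
  blocks <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    M <- window_matrix(windows, ch)
    F <- if (feature_set == "td_ar") {
      eps <- if (identical(zc_eps, "adaptive")) {
        0.01 * sqrt(colMeans(M^2))
      } else {
        zc_eps
      }
      td <- td_features_matrix(M, eps = eps)
      ar <- burg_matrix(M, ar_order)
      rownames(ar) <- paste0("ar", seq_len(ar_order))
      rbind(td, ar)
    } else {
      wt_marginals_matrix(M, wavelet, levels)
    }
    rownames(F) <- paste0("ch", ch, "_", rownames(F))
    blocks[[ch]] <- t(F)
  }
  X <- do.call(cbind, blocks)
  if (any(!is.finite(X))) abort("non-finite feature values produced.")
  structure(
    list(X = X, feature_set = feature_set, meta = windows$labels,
         config = list(ar_order = ar_order, wavelet = wavelet,
                       levels = levels, zc_eps = zc_eps)),
    class = "emg_features"
  )
}

#' @export
print.emg_features <- function(x, ...) {
  cat(sprintf("<emg_features> %s: %d windows x %d features\n",
              x$feature_set, nrow(x$X), ncol(x$X)))
  invisible(x)
}

#' @method as_tibble emg_features
#' @export
as_tibble.emg_features <- function(x, ...) {
  dplyr::bind_cols(x$meta, as_tibble(x$X, .name_repair = "minimal"))
}
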