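# Periodized orthogonal discrete wavelet transform.
#
# The decomposition uses circular (periodic) boundary extension so that
# coefficient counts halve exactly at every level and the transform is
# orthogonal: sum of squared coefficients equals sum of squared samples
# (Parseval), which the tests use as a correctness oracle. Analysis filters
# are the standard published orthogonal filter banks.

# Low-pass decomposition filters (scaling coefficients).
wavelet_filters <- list(
  haar = c(0.7071067811865476, 0.7071067811865476),
  db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965),
  sym4 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
           0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
           -0.012603967262037833, 0.0322231006040427),
  coif4 = c(-1.7849909144933469e-06, -3.259647940030751e-06,
            3.1229861599195265e-05, 6.233885431278719e-05,
            -0.0002599743371222568, -0.0005890202246332165,
            0.0012665610789256603, 0.0037514346971460866,
            -0.0056582838001308835, -0.015211728187697211,
            0.02508225333794961, 0.03933442260558915,
            -0.09622042453595264, -0.06662747236681717,
            0.43438603311435653, 0.7822389344242826,
            0.41530842700068227, -0.05607731960356926,
            -0.08126671024919373, 0.02668230466960483,
            0.01606894713157503, -0.007346167936268051,
            -0.001629492425226786, 0.000892313902537003)
)

get_wavelet <- function(wavelet) {
  lo <- wavelet_filters[[wavelet]]
  if (is.null(lo)) {
    abort(sprintf("unsupported wavelet '%s'; available: %s.", wavelet,
                  paste(names(wavelet_filters), collapse = ", ")),
          class = "emgdyn_config_error")
  }
  L <- length(lo)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L) # quadrature mirror filter
  list(lo = lo, hi = hi, L = L)
}

.dwt_cache <- new.env(parent = emptyenv())

# One-level analysis matrices (n/2 x n) under periodic extension:
# a[k] = sum_j rev(lo)[j] x[(2k + j - (L/2 - 1)) mod n], 0-based.
dwt_matrices <- function(n, wavelet) {
  key <- paste(wavelet, n, sep = ":")
  hit <- .dwt_cache[[key]]
  if (!is.null(hit)) return(hit)
  flt <- get_wavelet(wavelet)
  if (n %% 2L != 0L) abort("DWT level requires an even input length.")
  lo_r <- rev(flt$lo)
  hi_r <- rev(flt$hi)
  off <- flt$L / 2 - 1L
  W_lo <- matrix(0, n / 2L, n)
  W_hi <- matrix(0, n / 2L, n)
  for (k in 0:(n / 2L - 1L)) {
    for (j in 0:(flt$L - 1L)) {
      col <- ((2L * k + j - off) %% n) + 1L
      W_lo[k + 1L, col] <- W_lo[k + 1L, col] + lo_r[j + 1L]
      W_hi[k + 1L, col] <- W_hi[k + 1L, col] + hi_r[j + 1L]
    }
  }
  out <- list(lo = W_lo, hi = W_hi)
  .dwt_cache[[key]] <- out
  out
}

#' Periodized discrete wavelet decomposition
#'
#' Multi-level DWT with periodic boundary handling. Accepts a vector or a
#' matrix whose columns are independent signals (all transformed at once).
#'
#' @param x Numeric vector, or matrix with one signal per column; the length
#'   must be divisible by `2^levels`.
#' @param wavelet Analysis wavelet: `"coif4"` (default), `"db4"`, `"sym4"`,
#'   or `"haar"`.
#' @param levels Decomposition depth (default 4).
#' @return A list of coefficient blocks `d1, ..., d<levels>, a<levels>`
#'   (finest detail first); each block is a vector or matrix matching the
#'   input shape.
#' @examples
#' co <- dwt_periodic(sin(2 * pi * (0:127) / 16), "coif4", 4)
#' names(co)
#' @export
dwt_periodic <- function(x, wavelet = "coif4", levels = 4) {
  levels <- assert_count(levels, "levels")
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else as.matrix(x)
  n <- nrow(X)
  if (n %% (2^levels) != 0L) {
    abort("input length must be a multiple of 2^levels.")
  }
  out <- vector("list", levels + 1L)
  names(out) <- c(paste0("d", seq_len(levels)), paste0("a", levels))
  A <- X
  for (lev in seq_len(levels)) {
    W <- dwt_matrices(nrow(A), wavelet)
    out[[lev]] <- W$hi %*% A
    A <- W$lo %*% A
  }
  out[[levels + 1L]] <- A
  if (vec) out <- lapply(out, drop)
  out
}
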