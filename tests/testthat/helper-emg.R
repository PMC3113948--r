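# Small protocols and fixtures shared across tests. Everything is generated
# in code; the tiny protocol keeps unit tests fast while exercising every
# code path (the acceptance tests use the full default protocol).

tiny_protocol <- function(...) {
  emg_protocol(n_classes = 4, n_channels = 3, fs = 256,
               reps_per_session = 1, n_sessions = 3,
               ramp_s = 1, hold_s = 1.5, rest_s = 1,
               band_hz = c(30, 110), ...)
}

tiny_wspec <- function() window_spec(64, 16, fs = 256)

tiny_sessions <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      p <- tiny_protocol()
      s <- make_subject(p, seed = 11)
      cache <<- list(
        protocol = p, subject = s,
        sessions = lapply(1:3, function(k) {
          generate_session(s, p, k, seed = 500 + k)
        })
      )
    }
    cache
  }
})

# Minimal windows object with prescribed activities and labels, for
# controlled threshold-calibration tests.
fake_windows <- function(activities, class_id, phase, n_channels = ncol(activities)) {
  n <- nrow(activities)
  ann <- tibble::tibble(start = 0L, end = n * 16L + 48L,
                        class_id = max(class_id), phase = "rest")
  structure(
    list(
      spec = window_spec(64, 16, fs = 256),
      starts = seq.int(0L, by = 16L, length.out = n),
      labels = tibble::tibble(window = seq_len(n),
                              start_sample = seq.int(0L, by = 16L,
                                                     length.out = n),
                              class_id = class_id, phase = phase),
      session = list(signal = matrix(0, n_channels, n * 16L + 48L),
                     annotations = ann),
      activities = activities
    ),
    class = "emg_windows"
  )
}

# Well-separated Gaussian blobs for classifier tests.
make_blobs <- function(n_per_class, centers, sd = 0.3, seed = 1) {
  withr::with_seed(seed, {
    k <- nrow(centers)
    X <- do.call(rbind, lapply(seq_len(k), function(c) {
      matrix(rnorm(n_per_class * ncol(centers), sd = sd),
             n_per_class) + matrix(centers[c, ], n_per_class,
                                   ncol(centers), byrow = TRUE)
    }))
    list(X = X, y = factor(rep(seq_len(k), each = n_per_class)))
  })
}

# Brute-force majority vote used as the independent oracle: direct count
# over the trailing history with the same most-recent tie-break.
brute_vote <- function(labels, depth) {
  lv <- levels(labels)
  out <- character(length(labels))
  for (k in seq_along(labels)) {
    hist <- labels[max(1, k - depth + 1):k]
    tab <- table(hist)
    tied <- names(tab)[tab == max(tab)]
    if (length(tied) == 1) {
      out[k] <- tied
    } else {
      for (j in length(hist):1) {
        if (as.character(hist[j]) %in% tied) {
          out[k] <- as.character(hist[j])
          break
        }
      }
    }
  }
  factor(out, levels = lv)
}
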