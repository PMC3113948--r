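test_that("subject models are deterministic in the seed and structurally valid", {
  p <- emg_protocol()
  s1 <- make_subject(p, seed = 1)
  s2 <- make_subject(p, seed = 1)
  s3 <- make_subject(p, seed = 2)
  expect_identical(s1$activation, s2$activation)
  expect_identical(s1$snr_db, s2$snr_db)
  expect_false(identical(s1$activation, s3$activation))

  expect_equal(dim(s1$activation), c(9, 6))
  expect_true(all(s1$activation[9, ] == 0)) # rest row silent
  # pairwise distinct active rows
  act <- s1$activation[1:8, ]
  d <- as.matrix(dist(act, method = "maximum"))
  expect_true(all(d[upper.tri(d)] > 0))
  expect_true(all(s1$activity[1:8] >= 0.56 & s1$activity[1:8] <= 0.92))
  expect_true(s1$snr_db >= 10 && s1$snr_db <= 25)
})

test_that("invalid protocols and subjects are rejected", {
  expect_error(emg_protocol(n_classes = 1), "n_classes")
  expect_error(emg_protocol(n_channels = 0), "n_channels")
  expect_error(emg_protocol(band_hz = c(47, 600)), "band_hz")
  expect_error(emg_subject(matrix(1, 3, 2), 15, c(1, 1, 0)), "rest")
  bad <- rbind(c(1, 0), c(1, 0), c(0, 0))
  expect_error(emg_subject(bad, 15, c(0.7, 0.7, 0)), "distinct")
})

test_that("sessions are annotated exactly, zero-mean, and seed-deterministic", {
  tp <- tiny_sessions()
  ses <- tp$sessions[[1]]
  ann <- ses$annotations
  # annotations tile the signal with half-open intervals
  expect_identical(ann$start[1], 0L)
  expect_identical(max(ann$end), ncol(ses$signal))
  expect_true(all(ann$start[-1] == ann$end[-nrow(ann)]))
  expect_equal(sum(ann$end - ann$start), ncol(ses$signal))
  expect_lt(max(abs(rowMeans(ses$signal))), 1e-12)

  # reps_per_session occurrences of each active class
  ci <- contraction_intervals(ses)
  expect_equal(nrow(ci), 3) # (n_classes - 1) * reps
  expect_setequal(ci$class_id, 1:3)

  again <- generate_session(tp$subject, tp$protocol, 1, seed = 501)
  expect_identical(again$signal, ses$signal)
  other <- generate_session(tp$subject, tp$protocol, 1, seed = 999)
  expect_false(identical(other$signal, ses$signal))
})

test_that("contraction envelope hits the rest level at the ends and peak at the hold", {
  for (shape in c("cosine", "linear")) {
    env <- emgdyn:::contraction_envelope(256, 384, shape)
    expect_equal(env[256 + 192], 1) # hold midpoint
    expect_lt(env[1], 0.01)
    expect_lt(env[length(env)], 0.01)
    expect_equal(max(env), 1)
  }
})

test_that("rest segments carry band-limited noise", {
  tp <- tiny_sessions()
  ses <- tp$sessions[[1]]
  rest <- ses$signal[1, 1:256]
  sp <- stats::spec.pgram(rest, plot = FALSE, taper = 0)
  f <- sp$freq * tp$protocol$fs
  in_band <- sum(sp$spec[f >= 30 & f <= 110]) / sum(sp$spec)
  expect_gt(in_band, 0.9)
})

test_that("amplitude rises monotonically through the contraction onset", {
  # through the onset transition the rectified amplitude grows on average;
  # deeper into the ramp the coordination blend redistributes amplitude
  # across channels, so monotonicity is asserted over the onset and the
  # whole ramp is asserted to sit far above the rest level
  tp <- tiny_sessions()
  fs <- tp$protocol$fs
  n_on <- round(tp$protocol$onset_tau_s * fs) # onset skirt samples
  onset_bins <- NULL
  ramp_amp <- c()
  rest_amp <- c()
  for (ses in tp$sessions) {
    ann <- ses$annotations
    ups <- ann[ann$phase == "ramp_up", ]
    rests <- ann[ann$phase == "rest", ]
    rest_amp <- c(rest_amp,
                  max(rowMeans(abs(ses$signal[, (rests$start[1] + 1):rests$end[1],
                                              drop = FALSE]))))
    for (i in seq_len(nrow(ups))) {
      on_idx <- ups$start[i] + seq_len(n_on)
      x <- colMeans(abs(ses$signal[, on_idx, drop = FALSE]))
      onset_bins <- rbind(onset_bins,
                          vapply(split(x, cut(seq_along(x), 4, labels = FALSE)),
                                 mean, 0))
      ramp_idx <- (ups$start[i] + n_on + 1):ups$end[i]
      ramp_amp <- c(ramp_amp,
                    max(rowMeans(abs(ses$signal[, ramp_idx, drop = FALSE]))))
    }
  }
  avg <- colMeans(onset_bins)
  expect_true(all(diff(avg) > 0))
  expect_gt(min(ramp_amp), 2 * mean(rest_amp))
})

test_that("controlled orthogonal subjects are separable by channel RMS centroids", {
  p <- emg_protocol(n_classes = 7, n_channels = 6, fs = 512,
                    reps_per_session = 2, n_sessions = 2,
                    ramp_s = 1, hold_s = 2, rest_s = 1,
                    band_hz = c(47, 200), snr_db_range = c(30, 30))
  act <- rbind(diag(6), rep(0, 6))
  subj <- emg_subject(act, snr_db = 30,
                      activity = c(rep(0.9, 6), 0), id = 99)
  s1 <- generate_session(subj, p, 1, seed = 1)
  s2 <- generate_session(subj, p, 2, seed = 2)
  ws <- window_spec(128, 64, fs = 512)
  hold_rms <- function(ses) {
    w <- segment(ses, ws)
    hold <- which(w$labels$phase == "hold")
    t(vapply(hold, function(i) {
      idx <- w$starts[i] + seq_len(128)
      sqrt(rowMeans(ses$signal[, idx, drop = FALSE]^2))
    }, numeric(6))) |>
      (\(m) list(X = m, y = w$labels$class_id[hold]))()
  }
  tr <- hold_rms(s1)
  te <- hold_rms(s2)
  centroids <- t(vapply(sort(unique(tr$y)), function(c) {
    colMeans(tr$X[tr$y == c, , drop = FALSE])
  }, numeric(6)))
  pred <- sort(unique(tr$y))[apply(te$X, 1, function(x) {
    which.min(colSums((t(centroids) - x)^2))
  })]
  expect_equal(mean(pred != te$y), 0)
})

test_that("datasets are reproducible and sized n_subjects x n_sessions", {
  p <- tiny_protocol()
  d1 <- generate_dataset(p, n_subjects = 2, master_seed = 7)
  d2 <- generate_dataset(p, n_subjects = 2, master_seed = 7)
  expect_length(d1, 2)
  expect_length(d1[[1]]$sessions, 3)
  expect_identical(d1[[1]]$sessions[[2]]$signal, d2[[1]]$sessions[[2]]$signal)
  expect_identical(d1[[2]]$subject$activation, d2[[2]]$subject$activation)
  # one subject model shared across that subject's sessions
  expect_identical(d1[[1]]$sessions[[1]]$subject_id,
                   d1[[1]]$sessions[[3]]$subject_id)
})
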