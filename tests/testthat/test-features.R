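test_that("time-domain features match hand computations", {
  f <- td_features(c(1, -1, 1, -1))
  expect_equal(unname(f), c(1, 3, 2, 6)) # mav, zc, ssc, wl

  for (c0 in c(-2.5, 0.3)) {
    fc <- td_features(rep(c0, 10))
    expect_equal(unname(fc), c(abs(c0), 0, 0, 0))
  }

  expect_equal(td_features(c(0, 1, 0, 1))[["wl"]], 3)
  expect_equal(td_features(c(0, 1, 0, 1))[["zc"]], 0) # zero samples never cross
})

test_that("MAV and WL scale linearly; ZC and SSC are amplitude-invariant at eps 0", {
  withr::with_seed(3, {
    x <- rnorm(128)
    f1 <- td_features(x)
    f5 <- td_features(5 * x)
    expect_equal(f5[["mav"]], 5 * f1[["mav"]])
    expect_equal(f5[["wl"]], 5 * f1[["wl"]])
    expect_equal(f5[["zc"]], f1[["zc"]])
    expect_equal(f5[["ssc"]], f1[["ssc"]])
  })
})

test_that("the deadzone suppresses small crossings", {
  x <- c(0.1, -0.1, 5, -5)
  expect_equal(td_features(x, eps = 0)[["zc"]], 3)
  expect_equal(td_features(x, eps = 1)[["zc"]], 2)
})

test_that("Burg coefficients agree with the reference implementation", {
  withr::with_seed(10, {
    for (i in 1:5) {
      x <- rnorm(256)
      mine <- ar_burg(x, 6)
      ref <- stats::ar.burg(x, aic = FALSE, order.max = 6,
                            demean = FALSE)$ar
      expect_equal(mine, unname(ref), tolerance = 1e-10)
    }
  })
})

test_that("Burg recovers AR(1) and AR(2) parameters", {
  withr::with_seed(11, {
    x1 <- as.numeric(arima.sim(list(ar = 0.9), 4096))
    expect_equal(ar_burg(x1, 1)[1], 0.9, tolerance = 0.05)

    x2 <- as.numeric(arima.sim(list(ar = c(0.75, -0.5)), 4096))
    expect_equal(ar_burg(x2, 2), c(0.75, -0.5), tolerance = 0.05)
  })
})

test_that("white-noise AR coefficients vanish on average", {
  withr::with_seed(12, {
    X <- matrix(rnorm(128 * 1000), 128)
    A <- emgdyn:::burg_matrix(X, 6)
    expect_lt(max(abs(rowMeans(A))), 0.05)
  })
})

test_that("zero-variance input falls back to zero coefficients with a warning", {
  expect_warning(a <- ar_burg(rep(0, 64), 6),
                 class = "emgdyn_zero_variance")
  expect_equal(a, rep(0, 6))
})

test_that("wavelet marginals are homogeneous and vanish on silence", {
  expect_equal(unname(wt_marginals(rep(0, 128))), rep(0, 5))
  withr::with_seed(13, {
    x <- rnorm(128)
    m1 <- wt_marginals(x)
    m3 <- wt_marginals(3 * x)
    expect_equal(m3, 3 * m1)
  })
})

test_that("the periodized DWT is orthogonal (Parseval) for every wavelet", {
  withr::with_seed(14, {
    x <- rnorm(128)
    for (wv in c("coif4", "db4", "sym4", "haar")) {
      co <- dwt_periodic(x, wv, 4)
      expect_equal(sum(unlist(co)^2), sum(x^2), tolerance = 1e-8)
      expect_equal(vapply(co, length, 0L),
                   c(d1 = 64L, d2 = 32L, d3 = 16L, d4 = 8L, a4 = 8L))
    }
  })
})

test_that("Coiflet-4 marginals match an independent DWT implementation", {
  # frozen from PyWavelets wavedec(mode = "periodization", level = 4) on the
  # same deterministic two-tone input
  n <- 0:127
  x <- sin(2 * pi * 7 * n / 128) + 0.5 * cos(2 * pi * 31 * n / 128)
  m <- wt_marginals(x, "coif4", 4)
  expect_equal(
    unname(m[c("a4", "d4", "d3", "d2", "d1")]),
    c(0.0023140114255200987, 17.99431208257726, 13.229767087409801,
      15.531867751383249, 18.673330114332636),
    tolerance = 1e-9
  )
})

test_that("wavelet configuration errors are reported", {
  expect_error(wt_marginals(rnorm(128), wavelet = "nope"),
               class = "emgdyn_config_error")
  expect_error(dwt_periodic(rnorm(100), "coif4", 4), "multiple")
})

test_that("feature extraction has the documented shape and is deterministic", {
  tp <- tiny_sessions()
  w <- segment(tp$sessions[[1]], tiny_wspec())
  fa <- extract_features(w, "td_ar")
  fb <- extract_features(w, "td_ar")
  expect_identical(fa$X, fb$X)
  expect_equal(ncol(fa$X), 3 * 10) # channels x (4 TD + 6 AR)
  expect_equal(nrow(fa$X), length(w$starts))
  expect_false(any(!is.finite(fa$X)))

  fw <- extract_features(w, "wt", levels = 4)
  expect_equal(ncol(fw$X), 3 * 5)
  expect_equal(nrow(fw$X), length(w$starts))

  tb <- tibble::as_tibble(fa)
  expect_equal(nrow(tb), nrow(fa$X))
  expect_true(all(c("class_id", "phase", "ch1_mav") %in% names(tb)))
})
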