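test_that("the energy operator matches hand and closed-form values", {
  expect_equal(tkeo(c(1, 2, 3)), 1) # 2^2 - 1*3
  expect_equal(tkeo(rep(4, 10)), rep(0, 8))
  expect_error(tkeo(c(1, 2)), "3 samples")

  n <- 0:199
  for (A in c(1, 2.5)) {
    for (w in c(0.1, 0.5)) {
      y <- tkeo(A * sin(w * n))
      expect_equal(y, rep(A^2 * sin(w)^2, length(y)), tolerance = 1e-6)
    }
  }
})

test_that("window activity is quadratic in amplitude and zero on silence", {
  expect_equal(window_activity(matrix(0, 2, 50)), c(0, 0))
  withr::with_seed(21, {
    w <- matrix(rnorm(2 * 128), 2)
    expect_equal(window_activity(2 * w), 4 * window_activity(w))
  })
})

test_that("hold windows dwarf rest windows in activity on synthetic data", {
  p <- tiny_protocol(snr_db_range = c(20, 25))
  s <- make_subject(p, seed = 12)
  w <- segment(generate_session(s, p, 1, seed = 600), tiny_wspec())
  act <- emgdyn:::activity_matrix(w)
  hold <- w$labels$phase == "hold"
  rest <- w$labels$phase == "rest"
  ratio <- mean(apply(act[hold, , drop = FALSE], 1, max)) /
    mean(apply(act[rest, , drop = FALSE], 1, max))
  expect_gt(ratio, 10)
})

test_that("the gate fires when any channel crosses its threshold", {
  model <- structure(
    list(rest_activity = c(1, 1, 1), coefficient = 2,
         constraints = c(overall_min = 0.97, class_min = 0.85),
         coverage = list(overall = 1, per_class = 1)),
    class = "threshold_model"
  )
  expect_false(is_active(c(1.5, 1.9, 2.0), model)) # strict inequality
  expect_true(is_active(c(0.1, 0.1, 2.1), model)) # single hot channel
  tiny <- model
  tiny$coefficient <- 1e-12
  expect_true(is_active(c(0.01, 0.01, 0.01), tiny)) # coefficient -> 0+
  # matrix form
  A <- rbind(c(3, 0, 0), c(0.5, 0.5, 0.5))
  expect_equal(is_active(A, model), c(TRUE, FALSE))
})

test_that("calibration picks the largest feasible coefficient on the grid", {
  # 40 hold windows at activity 10, 20 rest windows at 1 on both channels
  act <- rbind(matrix(10, 40, 2), matrix(1, 20, 2))
  lab_class <- c(rep(1:2, each = 20), rep(9L, 20))
  lab_phase <- c(rep("hold", 40), rep("rest", 20))
  w <- fake_windows(act, lab_class, lab_phase)
  m <- calibrate_threshold(w, rest_class = 9)
  grid <- threshold_grid()
  expect_equal(m$coefficient, max(grid[grid < 10]))
  expect_equal(unname(m$rest_activity), c(1, 1))
  expect_equal(m$coverage$overall, 1)
})

test_that("calibration agrees with an independent linear-scan oracle", {
  grid <- threshold_grid(n = 120)
  withr::with_seed(22, {
    for (rep in 1:10) {
      n_hold <- 150
      cls <- sample(1:3, n_hold, replace = TRUE)
      act <- cbind(exp(rnorm(n_hold, 3, 1.5)), exp(rnorm(n_hold, 2.5, 1.5)))
      rest <- matrix(exp(rnorm(60, 0, 0.1)), 30, 2)
      w <- fake_windows(rbind(act, rest),
                        c(cls, rep(9L, 30)),
                        c(rep("hold", n_hold), rep("rest", 30)))
      rest_ref <- colMeans(rest)
      ratio <- apply(sweep(act, 2, rest_ref, `/`), 1, max)
      # brute-force scan, highest feasible grid value
      oracle <- NA_real_
      for (co in grid) {
        ok <- ratio > co
        if (mean(ok) > 0.97 &&
            all(tapply(ok, cls, mean) >= 0.85)) {
          oracle <- co
        }
      }
      if (is.na(oracle)) {
        expect_error(calibrate_threshold(w, grid = grid, rest_class = 9),
                     class = "emgdyn_infeasible_calibration")
      } else {
        m <- calibrate_threshold(w, grid = grid, rest_class = 9)
        expect_equal(m$coefficient, oracle)
      }
    }
  })
})

test_that("calibration corner cases behave as specified", {
  act <- rbind(matrix(0.05, 30, 2), matrix(1, 20, 2))
  w <- fake_windows(act, c(rep(1:2, 15), rep(9L, 20)),
                    c(rep("hold", 30), rep("rest", 20)))
  # active windows far below the rest level -> infeasible everywhere on grid
  expect_error(calibrate_threshold(w, rest_class = 9),
               class = "emgdyn_infeasible_calibration")
  # vacuous constraints -> grid maximum
  m0 <- calibrate_threshold(w, overall_min = 0, class_min = 0, rest_class = 9)
  expect_equal(m0$coefficient, max(threshold_grid()))
})

test_that("the active set shrinks as the coefficient grows", {
  withr::with_seed(23, {
    act <- matrix(exp(rnorm(200)), 100, 2)
    model <- structure(
      list(rest_activity = c(0.5, 0.5), coefficient = 1,
           constraints = c(overall_min = 0, class_min = 0),
           coverage = list()),
      class = "threshold_model"
    )
    prev <- rep(TRUE, 100)
    for (co in c(0.1, 0.5, 1, 2, 5, 20)) {
      model$coefficient <- co
      cur <- is_active(act, model)
      expect_true(all(cur <= prev)) # weakly nested
      prev <- cur
    }
  })
})

test_that("threshold models tidy and glance into tibbles", {
  act <- rbind(matrix(10, 40, 2), matrix(1, 20, 2))
  w <- fake_windows(act, c(rep(1:2, 20), rep(9L, 20)),
                    c(rep("hold", 40), rep("rest", 20)))
  m <- calibrate_threshold(w, rest_class = 9)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  expect_equal(td$threshold, m$coefficient * unname(m$rest_activity))
  gl <- glance(m)
  expect_equal(gl$coefficient, m$coefficient)
  expect_equal(gl$overall_coverage, 1)
})
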