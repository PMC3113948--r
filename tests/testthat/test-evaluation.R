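test_that("ability index and normalized errors follow the defining arithmetic", {
  expect_equal(ability_index(rep(0.10, 5)), 0.10)
  e <- c(0.05, 0.10, 0.10, 0.10, 0.15)
  expect_equal(ability_index(e), 0.10)
  expect_equal(e / ability_index(e), c(0.5, 1, 1, 1, 1.5))
  expect_error(ability_index(c(0.1, NA)), "present")

  # mean of normalized errors is identically 1 for any error vector
  withr::with_seed(41, {
    for (i in 1:20) {
      v <- runif(5)
      expect_equal(mean(v / ability_index(v)), 1, tolerance = 1e-12)
    }
  })
})

fake_results <- function() {
  grid <- tidyr::expand_grid(subject = 1:3, fold = 1:3,
                             feature_set = "td_ar", classifier = "lda",
                             section = training_sections())
  withr::with_seed(42, {
    res <- dplyr::mutate(grid,
                         error = runif(nrow(grid), 0.05, 0.3),
                         error_raw = error + 0.01,
                         n_windows = 1000L)
  })
  class(res) <- c("emg_experiment", class(res))
  res
}

test_that("normalized errors average to one per subject on real result tables", {
  res <- fake_results()
  ne <- normalized_errors(res)
  per_subj <- dplyr::summarise(
    dplyr::group_by(ne, subject),
    m = mean(normalized), .groups = "drop"
  )
  expect_equal(per_subj$m, rep(1, 3), tolerance = 1e-12)
  # hand check one cell: error / mean(section errors)
  s1 <- dplyr::filter(ne, subject == 1)
  expect_equal(s1$normalized, s1$error / mean(s1$error))
})

test_that("summaries aggregate subjects after averaging folds", {
  res <- fake_results()
  tab <- summarize_results(res)
  expect_equal(nrow(tab), 5)
  manual <- res |>
    dplyr::filter(section == "all_10s") |>
    dplyr::group_by(subject) |>
    dplyr::summarise(e = mean(error)) |>
    dplyr::pull(e)
  row <- dplyr::filter(tab, section == "all_10s")
  expect_equal(row$mean_error, mean(manual))
  expect_equal(row$sd_error, sd(manual))

  # identical per-subject errors have zero SD
  const <- dplyr::mutate(fake_results(), error = 0.1)
  class(const) <- class(res)
  expect_true(all(summarize_results(const)$sd_error == 0))

  wide <- summarize_results(res, wide = TRUE)
  expect_equal(dim(wide), c(5, 2)) # section + single cell
})

test_that("glance and tidy views of experiments are consistent", {
  res <- fake_results()
  gl <- glance(res)
  expect_equal(gl$n_subjects, 3)
  expect_equal(gl$n_cells, 5)
  td <- tidy(res)
  expect_s3_class(td$section, "factor")
})

test_that("the cross-validated experiment runs end to end on a tiny dataset", {
  p <- tiny_protocol()
  dataset <- generate_dataset(p, n_subjects = 1, master_seed = 5)
  cells <- study_cells("td_ar", "lda", c("static_4s", "all_10s"))
  res <- run_experiment(dataset, cells = cells, wspec = tiny_wspec(),
                        train_stride = 2, seed = 5)
  expect_equal(nrow(res), 1 * 3 * 2) # subjects x folds x cells
  expect_true(all(res$error >= 0 & res$error <= 1))
  expect_true(all(res$n_windows > 0))

  # reproducible end to end
  res2 <- run_experiment(dataset, cells = cells, wspec = tiny_wspec(),
                         train_stride = 2, seed = 5)
  expect_identical(res$error, res2$error)
})

test_that("boundary profiles report both gate settings per fold", {
  p <- tiny_protocol()
  dataset <- generate_dataset(p, n_subjects = 1, master_seed = 5)
  bp <- boundary_error_profile(dataset, wspec = tiny_wspec(),
                               section = "all_10s", train_stride = 2,
                               seed = 5)
  expect_equal(nrow(bp), 1 * 3 * 2) # subject x fold x gate
  expect_setequal(bp$gate, c(TRUE, FALSE))
  expect_true(all(bp$boundary_error >= 0 & bp$boundary_error <= 1))
})
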