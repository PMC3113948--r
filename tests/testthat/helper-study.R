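# The full-protocol synthetic study (8 subjects, default recording protocol,
# fixed master seed) shared by the acceptance tests. Computed lazily, once.

study_env <- new.env(parent = emptyenv())

acceptance_study <- function() {
  if (!is.null(study_env$study)) {
    return(study_env$study)
  }
  protocol <- emg_protocol()
  dataset <- generate_dataset(protocol, n_subjects = 8, master_seed = 101)

  contr_len <- round(protocol$contraction_s * protocol$fs)
  per_session <- lapply(dataset[[1]]$sessions, function(ses) {
    ci <- contraction_intervals(ses)
    ann <- ses$annotations
    rest_slots <- sum(ann$phase == "rest" & (ann$end - ann$start) == contr_len)
    list(active = nrow(ci), rest_slots = rest_slots, classes = ci$class_id)
  })
  counts <- list(
    n_sessions = sum(vapply(dataset, function(s) length(s$sessions), 0L)),
    slots_per_subject = sum(vapply(per_session, function(x) {
      x$active + x$rest_slots
    }, 0)),
    active_per_class = table(unlist(lapply(per_session, `[[`, "classes"))),
    rest_slots_per_subject = sum(vapply(per_session, `[[`, 0, "rest_slots")),
    fold_slots = sum(vapply(per_session[1:2], function(x) {
      x$active + x$rest_slots
    }, 0)),
    fold_active_per_class = table(unlist(lapply(per_session[1:2], `[[`,
                                                "classes")))
  )

  results <- run_experiment(dataset, cells = emgdyn:::key_study_cells(),
                            seed = 101)
  boundary <- boundary_error_profile(dataset, seed = 101)
  normalized <- normalized_errors(
    dplyr::filter(results, classifier != "svm_ovr")
  )
  study_env$study <- list(protocol = protocol, counts = counts,
                          results = results, boundary = boundary,
                          normalized = normalized)
  study_env$study
}

# subject-level section means (folds averaged), then the across-subject mean
section_means <- function(results, fs, clf) {
  results |>
    dplyr::filter(feature_set == fs, classifier == clf) |>
    dplyr::group_by(subject, section) |>
    dplyr::summarise(error = mean(error), .groups = "drop") |>
    dplyr::group_by(section) |>
    dplyr::summarise(error = mean(error), .groups = "drop") |>
    (\(d) stats::setNames(d$error, d$section))()
}
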