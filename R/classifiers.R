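# Window classifiers: LDA and Gaussian-kernel SVM in one-vs-one and
# one-vs-rest decompositions. Features are z-scored with statistics from the
# training fold only; both decompositions are built on libsvm (e1071) binary
# machines with the voting / arg-max rules implemented here so tie-breaking
# is explicit.

#' Classifier specification
#'
#' @param kind `"lda"`, `"svm_ovo"` (one-vs-one) or `"svm_ovr"`
#'   (one-vs-rest); SVMs use a Gaussian (RBF) kernel.
#' @param cost,gamma SVM hyperparameters; `NULL` means resolve them by
#'   `tune`.
#' @param tune Hyperparameter policy when `cost`/`gamma` are `NULL`:
#'   `"heuristic"` (default) sets `gamma` to the inverse median squared
#'   pairwise distance of a training subsample and `cost = 10`; `"cv"` runs
#'   an internal 5-fold cross-validated grid search on the training fold
#'   (cost in `10^(-1..3)`, gamma scaled `10^(-1..1)` around the heuristic).
#' @param seed Integer seed controlling subsampling and CV folds.
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("lda", "svm_ovo", "svm_ovr"),
                            cost = NULL, gamma = NULL,
                            tune = c("heuristic", "cv"), seed = 1L) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind, cost = cost, gamma = gamma, tune = match.arg(tune),
         seed = as.integer(seed)),
    class = "classifier_spec"
  )
}

scale_fit <- function(X) {
  center <- colMeans(X)
  scale <- col_sds(X)
  scale[scale == 0] <- 1
  list(center = center, scale = scale)
}

scale_apply <- function(X, sc) {
  sweep(sweep(X, 2, sc$center), 2, sc$scale, `/`)
}

gamma_heuristic <- function(X, max_rows = 400L) {
  n <- nrow(X)
  idx <- if (n > max_rows) sample.int(n, max_rows) else seq_len(n)
  d2 <- as.numeric(stats::dist(X[idx, , drop = FALSE]))^2
  med <- median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) 1 / ncol(X) else 1 / med
}

resolve_hyperparams <- function(X, y, spec) {
  if (!is.null(spec$cost) && !is.null(spec$gamma)) {
    return(list(cost = spec$cost, gamma = spec$gamma))
  }
  g0 <- gamma_heuristic(X)
  if (spec$tune == "heuristic") {
    return(list(cost = spec$cost %||% 10, gamma = spec$gamma %||% g0))
  }
  grid <- expand.grid(cost = 10^(-1:3), gamma = g0 * 10^(-1:1))
  n <- nrow(X)
  folds <- sample(rep_len(1:5, n))
  errs <- vapply(seq_len(nrow(grid)), function(i) {
    mean(vapply(1:5, function(f) {
      tr <- folds != f
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = grid$cost[i], gamma = grid$gamma[i],
                      scale = FALSE)
      mean(predict(m, X[!tr, , drop = FALSE]) != y[!tr])
    }, 0))
  }, 0)
  list(cost = grid$cost[which.min(errs)], gamma = grid$gamma[which.min(errs)])
}

#' Train a window classifier
#'
#' Features are standardized with training-fold statistics; the fitted scaler
#' travels with the model and is applied at prediction time. The model only
#' ever predicts labels seen during training (rest is handled upstream by the
#' activity gate).
#'
#' @param X Numeric feature matrix (or an `emg_features` object).
#' @param y Class labels (coerced to factor).
#' @param spec A [classifier_spec()].
#' @return An object of class `emg_classifier`.
#' @export
fit_classifier <- function(X, y, spec = classifier_spec()) {
  if (inherits(X, "emg_features")) X <- X$X
  X <- as.matrix(X)
  if (any(!is.finite(X))) abort("feature matrix contains non-finite values.")
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) {
    abort("training data must contain at least 2 classes.",
          class = "emgdyn_degenerate_training")
  }
  y <- droplevels(y)
  sc <- scale_fit(X)
  Xs <- scale_apply(X, sc)
  fit <- with_seed(spec$seed, {
    switch(spec$kind,
      lda = list(lda = MASS::lda(Xs, grouping = y)),
      svm_ovo = {
        hp <- resolve_hyperparams(Xs, y, spec)
        list(svm = e1071::svm(Xs, y, kernel = "radial", cost = hp$cost,
                              gamma = hp$gamma, scale = FALSE),
             hyper = hp)
      },
      svm_ovr = {
        hp <- resolve_hyperparams(Xs, y, spec)
        machines <- lapply(levels(y), function(cl) {
          yb <- factor(ifelse(y == cl, "target", "rest_of"),
                       levels = c("target", "rest_of"))
          m <- e1071::svm(Xs, yb, kernel = "radial", cost = hp$cost,
                          gamma = hp$gamma, scale = FALSE)
          # normalize the libsvm decision-value sign so that positive
          # always means "target"
          dv <- attr(predict(m, Xs[y == cl, , drop = FALSE][1, , drop = FALSE],
                             decision.values = TRUE), "decision.values")
          flip <- if (colnames(dv)[1] == "target/rest_of") 1 else -1
          list(svm = m, flip = flip)
        })
        list(machines = machines, hyper = hp)
      }
    )
  })
  structure(
    list(spec = spec, scaler = sc, classes = levels(y), fit = fit,
         n_features = ncol(X)),
    class = "emg_classifier"
  )
}

#' @export
print.emg_classifier <- function(x, ...) {
  cat(sprintf("<emg_classifier> %s: %d classes, %d features\n",
              x$spec$kind, length(x$classes), x$n_features))
  invisible(x)
}

#' Predict window classes
#'
#' One-vs-one prediction counts pairwise votes; ties are broken by the
#' highest aggregate decision value and then by the lowest class index.
#' One-vs-rest selects the class maximizing the (sign-normalized) decision
#' value.
#'
#' @param object A fitted [fit_classifier()] model.
#' @param newdata Feature matrix with the training feature count.
#' @param ... Unused.
#' @return Factor of predicted labels with the training class levels.
#' @export
predict.emg_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "emg_features")) newdata <- newdata$X
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features) {
    abort(sprintf("expected %d features, got %d.", object$n_features,
                  ncol(newdata)))
  }
  if (nrow(newdata) == 0) {
    return(factor(character(), levels = object$classes))
  }
  Xs <- scale_apply(newdata, object$scaler)
  classes <- object$classes
  k <- length(classes)
  switch(object$spec$kind,
    lda = {
      p <- predict(object$fit$lda, Xs)
      factor(as.character(p$class), levels = classes)
    },
    svm_ovo = {
      pr <- predict(object$fit$svm, Xs, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      votes <- matrix(0L, nrow(Xs), k, dimnames = list(NULL, classes))
      score <- matrix(0, nrow(Xs), k, dimnames = list(NULL, classes))
      for (j in seq_len(ncol(dv))) {
        pair <- strsplit(colnames(dv)[j], "/", fixed = TRUE)[[1]]
        pos <- dv[, j] > 0
        votes[, pair[1]] <- votes[, pair[1]] + pos
        votes[, pair[2]] <- votes[, pair[2]] + !pos
        score[, pair[1]] <- score[, pair[1]] + dv[, j]
        score[, pair[2]] <- score[, pair[2]] - dv[, j]
      }
      # arg-max votes; ties by aggregate decision value, then lowest index
      win <- vapply(seq_len(nrow(votes)), function(i) {
        tied <- which(votes[i, ] == max(votes[i, ]))
        if (length(tied) > 1L) tied <- tied[which.max(score[i, tied])]
        tied[1]
      }, 0L)
      factor(classes[win], levels = classes)
    },
    svm_ovr = {
      dec <- vapply(object$fit$machines, function(m) {
        dv <- attr(predict(m$svm, Xs, decision.values = TRUE),
                   "decision.values")
        m$flip * dv[, 1]
      }, numeric(nrow(Xs)))
      dec <- matrix(dec, nrow = nrow(Xs))
      factor(classes[max.col(dec, ties.method = "first")], levels = classes)
    }
  )
}
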