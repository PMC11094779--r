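# Model layer: k-fold cross-validated scoring, bottom-up greedy forward
# feature selection on Pearson's r, tree-ensemble training and mutation
# ranking. Four algorithms are supported, all with 300 trees and otherwise
# backend-default hyperparameters:
#   random_forest, extra_trees            -> ranger
#   gradient_boosting                      -> xgboost, classic-GBM settings
#   extreme_gradient_boosting              -> xgboost defaults

GS_ALGORITHMS <- c("random_forest", "extra_trees",
                   "gradient_boosting", "extreme_gradient_boosting")

fit_ensemble <- function(x, y, algorithm, n_estimators = 300L, seed = 42L) {
  if (!algorithm %in% GS_ALGORITHMS) {
    gs_error("gs_config_error",
             sprintf("unknown algorithm '%s' (choose from %s)",
                     algorithm, paste(GS_ALGORITHMS, collapse = ", ")))
  }
  if (ncol(x) == 0L) gs_error("gs_config_error", "empty feature list")
  if (algorithm %in% c("random_forest", "extra_trees")) {
    m <- ranger::ranger(
      x = x, y = y, num.trees = n_estimators, num.threads = 1L,
      seed = seed, oob.error = FALSE,
      splitrule = if (algorithm == "extra_trees") "extratrees" else "variance",
      replace = algorithm == "random_forest",
      sample.fraction = if (algorithm == "extra_trees") 1 else 1)
    structure(list(backend = "ranger", fit = m), class = "gs_fit")
  } else {
    params <- if (algorithm == "gradient_boosting") {
      # classic gradient boosting: shallow trees, 0.1 learning rate
      list(eta = 0.1, max_depth = 3, subsample = 1, lambda = 0,
           min_child_weight = 1, tree_method = "exact", nthread = 1)
    } else {
      list(nthread = 1)
    }
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    m <- xgboost::xgb.train(params = c(params, list(seed = seed)),
                            data = dtrain, nrounds = n_estimators, verbose = 0)
    structure(list(backend = "xgboost", fit = m, features = colnames(x)),
              class = "gs_fit")
  }
}

predict_ensemble <- function(fit, x) {
  if (fit$backend == "ranger") {
    ranger::predictions(stats::predict(fit$fit, x, num.threads = 1L))
  } else {
    stats::predict(fit$fit, xgboost::xgb.DMatrix(x, nthread = 1))
  }
}

#' Cross-validated score of a feature subset
#'
#' Splits the rows into `k` folds by a seeded shuffle (the same partition
#' for every candidate of a selection run), fits the ensemble on each
#' training side and pools the out-of-fold predictions; Pearson's r and MSE
#' are computed on the pooled vector. If the pooled predictions are
#' constant, Pearson is undefined and `NaN` is returned (treated as -Inf by
#' the selection).
#'
#' @param x Numeric feature matrix with column names.
#' @param y Numeric label vector.
#' @param features Character vector of columns to use.
#' @param algorithm One of the four ensemble algorithms.
#' @param k Number of folds.
#' @param seed Integer seed for the fold shuffle and the fits.
#' @param folds Optional pre-computed fold assignment (overrides `seed`).
#' @param n_estimators Trees per ensemble.
#' @return Named numeric vector `c(pearson =, mse =)`.
#' @export
cv_score <- function(x, y, features, algorithm = "random_forest", k = 10L,
                     seed = 42L, folds = NULL, n_estimators = 300L) {
  n <- length(y)
  if (k < 2L || n < k) gs_error("gs_config_error", "need k >= 2 and nrow >= k")
  if (is.null(folds)) folds <- make_folds(n, k, seed)
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    fit <- fit_ensemble(x[tr, features, drop = FALSE], y[tr], algorithm,
                        n_estimators, seed)
    pred[!tr] <- predict_ensemble(fit, x[!tr, features, drop = FALSE])
  }
  r <- if (stats::sd(pred) == 0 || stats::sd(y) == 0) NaN else stats::cor(pred, y)
  c(pearson = r, mse = mean((pred - y)^2))
}

make_folds <- function(n, k, seed) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' Bottom-up greedy forward feature selection
#'
#' Starts from the empty set; each round scores every remaining candidate
#' joined to the current set with [cv_score()] (one fixed fold partition for
#' the whole run, so candidate scores are comparable) and fixes the
#' candidate with the best pooled Pearson's r. Stops as soon as no candidate
#' strictly improves Pearson's r. Ties are broken by candidate column order.
#' MSE is recorded at every step but never drives the selection.
#'
#' @inheritParams cv_score
#' @param candidates Candidate feature names; defaults to all columns.
#' @return A `gs_selection_trace`: data frame `steps` (feature, cv_pearson,
#'   cv_mse) and character vector `selected`.
#' @export
greedy_forward_selection <- function(x, y, algorithm = "random_forest",
                                     k = 10L, seed = 42L,
                                     candidates = colnames(x),
                                     n_estimators = 300L) {
  if (length(candidates) < 1L) gs_error("gs_config_error", "no candidate features")
  folds <- make_folds(length(y), k, seed)
  selected <- character(0)
  best <- -Inf
  steps <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (!length(remaining)) break
    scores <- vapply(remaining, function(f) {
      cv_score(x, y, c(selected, f), algorithm, k, seed, folds, n_estimators)
    }, numeric(2))
    pearson <- scores["pearson", ]
    pearson[is.na(pearson)] <- -Inf
    j <- which.max(pearson)             # which.max takes the first maximum: tie -> candidate order
    if (pearson[j] > best) {
      best <- pearson[j]
      selected <- c(selected, remaining[j])
      steps[[length(steps) + 1L]] <- data.frame(
        feature = remaining[j], cv_pearson = pearson[j],
        cv_mse = scores["mse", j], stringsAsFactors = FALSE)
    } else break
  }
  structure(list(steps = do.call(rbind, steps), selected = selected,
                 algorithm = algorithm, k = k, seed = seed),
            class = "gs_selection_trace")
}

#' @export
print.gs_selection_trace <- function(x, ...) {
  cat(sprintf("<gs_selection_trace> %s, %d-fold CV, %d features selected\n",
              x$algorithm, x$k, length(x$selected)))
  if (!is.null(x$steps)) print(x$steps)
  invisible(x)
}

#' Train a tree-ensemble dTm regressor
#'
#' @inheritParams cv_score
#' @param features Feature columns the model may use, in order.
#' @return A `gs_model` carrying the fitted ensemble, the feature list and
#'   the training configuration.
#' @export
train_model <- function(x, y, features, algorithm = "random_forest",
                        n_estimators = 300L, seed = 42L) {
  if (length(features) == 0L) gs_error("gs_config_error", "empty feature list")
  missing <- setdiff(features, colnames(x))
  if (length(missing)) {
    gs_error("gs_schema_error",
             sprintf("features not in matrix: %s", paste(missing, collapse = ", ")))
  }
  if (length(y) < 2L) gs_error("gs_insufficient_data_error", "need >= 2 training rows")
  fit <- fit_ensemble(x[, features, drop = FALSE], y, algorithm, n_estimators, seed)
  structure(list(algorithm = algorithm, n_estimators = n_estimators,
                 features = features, seed = seed, fit = fit),
            class = "gs_model")
}

#' @export
print.gs_model <- function(x, ...) {
  cat(sprintf("<gs_model> %s, %d trees, %d features\n",
              x$algorithm, x$n_estimators, length(x$features)))
  invisible(x)
}

#' Predict dTm for featurised mutations
#'
#' @param model A `gs_model`.
#' @param x Feature matrix containing at least the model's features.
#' @return Numeric vector of predicted dTm (degrees C).
#' @export
predict_dtm <- function(model, x) {
  stopifnot(inherits(model, "gs_model"))
  missing <- setdiff(model$features, colnames(x))
  if (length(missing)) {
    gs_error("gs_schema_error",
             sprintf("feature matrix lacks model features: %s",
                     paste(missing, collapse = ", ")))
  }
  predict_ensemble(model$fit, x[, model$features, drop = FALSE])
}

#' Rank mutations by predicted stabilisation
#'
#' Predictions are sorted in descending order of predicted dTm (stable
#' sort: ties keep input order). Positive values are interpreted as
#' stabilising.
#'
#' @param model A `gs_model`.
#' @param fm A `gs_feature_matrix` (prediction rows).
#' @return Data frame: `mutation`, `chain`, `predicted_dTm`, `rank`, `flag`
#'   (stabilizing/destabilizing), ordered by rank.
#' @export
predict_and_rank <- function(model, fm) {
  stopifnot(inherits(fm, "gs_feature_matrix"))
  pred <- predict_dtm(model, fm$x)
  ord <- order(-pred)                       # order() is stable: ties keep input order
  rec <- fm$records[ord, , drop = FALSE]
  data.frame(
    mutation = paste0(rec$wt_aa, rec$position, rec$mt_aa),
    chain = rec$chain,
    predicted_dTm = pred[ord],
    rank = seq_along(ord),
    flag = ifelse(pred[ord] > 0, "stabilizing", "destabilizing"),
    stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' The model is stored as an RDS bundle next to a JSON sidecar recording
#' the algorithm, feature list, seeds and package version.
#'
#' @param model A `gs_model`.
#' @param path Output `.rds` path; the sidecar gets the extension `.json`.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gs_model"))
  if (model$fit$backend == "xgboost") {
    raw <- xgboost::xgb.save.raw(model$fit$fit)
    model$fit$fit <- NULL
    model$fit$raw <- raw
  }
  saveRDS(model, path)
  sidecar <- list(algorithm = model$algorithm, n_estimators = model$n_estimators,
                  features = model$features, seed = model$seed,
                  package_version = as.character(utils::packageVersion("gpcrstab")))
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "gs_model")) gs_error("gs_format_error", "not a gs_model bundle")
  if (model$fit$backend == "xgboost" && !is.null(model$fit$raw)) {
    model$fit$fit <- xgboost::xgb.load.raw(model$fit$raw)
    model$fit$raw <- NULL
  }
  model
}

#' Permutation feature importance
#'
#' Attribution hook for trained models: mean increase in out-of-sample MSE
#' when one feature column is permuted (repeated and averaged). A pluggable
#' stand-in for heavier attribution engines.
#'
#' @param model A `gs_model`.
#' @param x Feature matrix.
#' @param y Labels aligned with `x`.
#' @param n_rep Permutations per feature.
#' @param seed Seed for the permutations.
#' @return Named numeric vector of importances (one per model feature).
#' @export
feature_importance <- function(model, x, y, n_rep = 10L, seed = 42L) {
  old <- .Random.seed_get(); on.exit(.Random.seed_set(old))
  set.seed(seed)
  base <- mean((predict_dtm(model, x) - y)^2)
  imp <- vapply(model$features, function(f) {
    mean(vapply(seq_len(n_rep), function(r) {
      xp <- x
      xp[, f] <- sample(xp[, f])
      mean((predict_dtm(model, xp) - y)^2)
    }, numeric(1))) - base
  }, numeric(1))
  imp
}
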