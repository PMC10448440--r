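#' Compound-disjoint train/test split
#'
#' Ionization-efficiency datasets contain the same chemical measured under
#' several eluent conditions, so datapoint-level splitting would leak
#' compounds across the split. Compounds (canonical ids) are therefore
#' partitioned at the requested ratio and every datapoint follows its
#' compound.
#'
#' @param compound_ids character vector, one id per datapoint.
#' @param ratio fraction of compounds assigned to the training side,
#'   in (0, 1).
#' @param seed integer seed controlling the partition.
#' @return a list of class `split_result` with `train_idx`/`test_idx`
#'   (datapoint indices), `train_compounds`/`test_compounds`, and
#'   `disjoint` (always checked `TRUE`).
#' @export
split_by_compound <- function(compound_ids, ratio = 0.8, seed = 1) {
  if (ratio <= 0 || ratio >= 1) {
    ie_stop("iequant_domain_error", "split ratio must lie in (0, 1)")
  }
  compounds <- unique(compound_ids)
  if (length(compounds) < 2) {
    ie_stop("iequant_domain_error", "need at least 2 distinct compounds")
  }
  n_train <- max(1, min(length(compounds) - 1,
                        round(ratio * length(compounds))))
  train_compounds <- with_seed(seed, sample(compounds, n_train))
  test_compounds <- setdiff(compounds, train_compounds)
  res <- list(train_idx = which(compound_ids %in% train_compounds),
              test_idx = which(compound_ids %in% test_compounds),
              train_compounds = train_compounds,
              test_compounds = test_compounds)
  res$disjoint <- length(intersect(train_compounds, test_compounds)) == 0
  stopifnot(res$disjoint)
  class(res) <- "split_result"
  res
}

# Evaluate code under a temporary RNG state so generators are pure
# functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Default hyperparameter grid for the boosted-tree log IE model
#'
#' A compact search space over the usual gradient-boosting knobs. Pass a
#' custom data.frame with the same columns to widen or shrink the search.
#'
#' @return data.frame with columns `nrounds`, `max_depth`, `eta`,
#'   `subsample`, `colsample_bytree`, `min_child_weight`.
#' @export
default_hyper_grid <- function() {
  expand.grid(nrounds = c(150, 400), max_depth = c(3, 6),
              eta = c(0.05, 0.2), subsample = 0.75,
              colsample_bytree = 0.8, min_child_weight = 1)
}

#' Train the gradient-boosted log IE regressor
#'
#' Grid-searches a tree-booster (xgboost) over `hyper_grid`, scoring each
#' candidate by resampled RMSE, then refits the best candidate on all
#' training points. Resampling is either bootstrap (`method = "boot"`:
#' `folds` bootstrap resamples scored on their out-of-bag points) or
#' k-fold cross-validation (`method = "cv"`); the scheme used is recorded
#' in the diagnostics.
#'
#' @param x numeric feature matrix (already preprocessed; one row per
#'   datapoint, named columns).
#' @param y numeric vector of log10 IE labels.
#' @param hyper_grid data.frame of candidates, see [default_hyper_grid()].
#' @param cv list with `method` (`"boot"` or `"cv"`) and `folds`.
#' @param seed integer seed for resampling and the booster.
#' @param nthread threads for xgboost (1 keeps runs bit-reproducible).
#' @return an object of class `ie_model`: the fitted booster plus selected
#'   hyperparameters, feature names, the resampling table and training
#'   diagnostics. Attach a preprocessing manifest via `model$manifest` to
#'   make prediction-time alignment automatic.
#' @export
train_ie_model <- function(x, y, hyper_grid = default_hyper_grid(),
                           cv = list(method = "boot", folds = 5),
                           seed = 1, nthread = 1) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  if (any(!is.finite(y))) {
    ie_stop("iequant_data_error", "non-finite log IE labels")
  }
  hyper_grid <- as.data.frame(hyper_grid)
  folds <- resample_indices(nrow(x), cv, seed)
  cv_rmse <- matrix(NA_real_, nrow(hyper_grid), length(folds))
  for (g in seq_len(nrow(hyper_grid))) {
    hp <- hyper_grid[g, ]
    for (f in seq_along(folds)) {
      tr <- folds[[f]]$train; ho <- folds[[f]]$holdout
      fit <- xgb_fit(x[tr, , drop = FALSE], y[tr], hp, seed, nthread)
      pred <- predict(fit, x[ho, , drop = FALSE])
      cv_rmse[g, f] <- sqrt(mean((pred - y[ho])^2))
    }
  }
  mean_rmse <- rowMeans(cv_rmse)
  best <- which.min(mean_rmse)   # ties resolve to the earlier grid row
  booster <- xgb_fit(x, y, hyper_grid[best, ], seed, nthread)
  train_pred <- predict(booster, x)
  model <- list(
    booster_raw = xgboost::xgb.save.raw(booster),
    best_params = as.list(hyper_grid[best, ]),
    feature_names = colnames(x),
    cv_results = cbind(hyper_grid, mean_cv_rmse = mean_rmse),
    resampling = list(method = cv$method, folds = length(folds), seed = seed),
    diagnostics = list(
      n_train = nrow(x),
      train_rmse = sqrt(mean((train_pred - y)^2)),
      train_rmse_fold = 10^sqrt(mean((train_pred - y)^2))),
    manifest = NULL)
  class(model) <- "ie_model"
  model
}

resample_indices <- function(n, cv, seed) {
  method <- match.arg(cv$method, c("boot", "cv"))
  k <- cv$folds
  with_seed(seed + 1L, {
    if (method == "boot") {
      lapply(seq_len(k), function(i) {
        tr <- sample.int(n, n, replace = TRUE)
        list(train = tr, holdout = setdiff(seq_len(n), unique(tr)))
      })
    } else {
      fold <- sample(rep_len(seq_len(k), n))
      lapply(seq_len(k), function(i) {
        list(train = which(fold != i), holdout = which(fold == i))
      })
    }
  })
}

xgb_fit <- function(x, y, hp, seed, nthread) {
  dm <- xgboost::xgb.DMatrix(x, label = y)
  xgboost::xgb.train(
    # exact splits place thresholds at value midpoints, so binary-trained
    # bits generalize sensibly to fractional MS2 probabilities (a 0.9
    # probability follows the presence branch, not the absence branch)
    params = list(objective = "reg:squarederror", tree_method = "exact",
                  eta = hp$eta,
                  max_depth = hp$max_depth, subsample = hp$subsample,
                  colsample_bytree = hp$colsample_bytree,
                  min_child_weight = hp$min_child_weight,
                  nthread = nthread, seed = seed),
    data = dm, nrounds = hp$nrounds, verbose = 0)
}

booster_of <- function(model) xgboost::xgb.load.raw(model$booster_raw)

#' @export
predict.ie_model <- function(object, newdata, ...) {
  if (!is.null(object$manifest)) {
    newdata <- apply_manifest(newdata, object$manifest)
  } else {
    newdata <- align_to_model_features(newdata, object$feature_names)
  }
  predict(booster_of(object), newdata, ...)
}

#' @export
print.ie_model <- function(x, ...) {
  cat("Boosted-tree log IE model:", length(x$feature_names), "features,",
      x$diagnostics$n_train, "training points\n")
  cat("  best hyperparameters:",
      paste(names(x$best_params), unlist(x$best_params),
            sep = "=", collapse = " "), "\n")
  cat(sprintf("  training RMSE %.3f log units (%.1fx)\n",
              x$diagnostics$train_rmse, x$diagnostics$train_rmse_fold))
  invisible(x)
}

#' Predict log IE for one feature
#'
#' Convenience wrapper building the feature row from a fingerprint vector
#' and an eluent condition, then predicting through the model (respecting
#' its preprocessing manifest).
#'
#' @param model an `ie_model`.
#' @param fingerprint named fingerprint vector (values in \[0, 1\]).
#' @param eluent one-row data.frame from [compute_eluent_descriptors()],
#'   or a named vector covering the eluent descriptor columns.
#' @return predicted log10 IE (finite scalar).
#' @export
predict_log_ie <- function(model, fingerprint, eluent) {
  el <- unlist(as.data.frame(eluent)[1, , drop = TRUE])
  row <- c(as.numeric(fingerprint), as.numeric(el))
  m <- matrix(row, nrow = 1,
              dimnames = list(NULL, c(names(fingerprint), names(el))))
  as.numeric(predict(model, m))
}

#' y-randomization analysis
#'
#' Permutes the training labels, retrains with the model's selected
#' hyperparameters, and reports train/test RMSE and R-squared per repeat
#' next to the unpermuted baseline. A real model must beat its permuted
#' counterparts; comparable errors indicate the model learned nothing
#' beyond chance.
#'
#' @param model a fitted `ie_model` (source of the hyperparameters).
#' @param x_train,y_train,x_test,y_test the split the model was fitted on.
#' @param n_repeats number of label permutations.
#' @param seed integer seed.
#' @return data.frame with one `baseline` row and `n_repeats` permuted
#'   rows; columns `run`, `train_rmse`, `test_rmse`, `test_r2`.
#' @export
y_randomization <- function(model, x_train, y_train, x_test, y_test,
                            n_repeats = 5, seed = 1) {
  hp <- as.data.frame(model$best_params)
  eval_fit <- function(y_tr, tag) {
    fit <- xgb_fit(x_train, y_tr, hp, seed, 1)
    ptr <- predict(fit, x_train); pte <- predict(fit, x_test)
    data.frame(run = tag,
               train_rmse = sqrt(mean((ptr - y_tr)^2)),
               test_rmse = sqrt(mean((pte - y_test)^2)),
               test_r2 = cor(pte, y_test)^2)
  }
  out <- eval_fit(y_train, "baseline")
  for (r in seq_len(n_repeats)) {
    y_perm <- with_seed(seed + r, sample(y_train))
    out <- rbind(out, eval_fit(y_perm, paste0("permuted_", r)))
  }
  rownames(out) <- NULL
  out
}

#' Feature importance and signed contributions
#'
#' Gain-based importance from the tree ensemble, normalized so the
#' importances of all model features sum to 100 %, together with
#' SHAP-style signed marginal contributions averaged over a background
#' set. Features never used by any tree get importance 0.
#'
#' @param model an `ie_model`.
#' @param background feature matrix (model feature space) over which the
#'   signed contributions are averaged; `NULL` skips the SHAP summary.
#' @param top_k how many top-ranked features to return (`Inf` for all).
#' @return data.frame ranked by importance with columns `feature`,
#'   `importance_pct`, and (with background) `mean_shap`, `mean_abs_shap`.
#' @export
feature_importance <- function(model, background = NULL, top_k = 10) {
  booster <- booster_of(model)
  imp <- xgboost::xgb.importance(model = booster)
  gain <- setNames(rep(0, length(model$feature_names)), model$feature_names)
  gain[imp$Feature] <- imp$Gain
  out <- data.frame(feature = names(gain),
                    importance_pct = 100 * gain / sum(gain),
                    row.names = NULL)
  if (!is.null(background)) {
    bg <- if (!is.null(model$manifest)) apply_manifest(background, model$manifest)
          else align_to_model_features(background, model$feature_names)
    contrib <- predict(booster, bg, predcontrib = TRUE)
    contrib <- contrib[, model$feature_names, drop = FALSE]
    out$mean_shap <- colMeans(contrib)[out$feature]
    out$mean_abs_shap <- colMeans(abs(contrib))[out$feature]
  }
  out <- out[order(-out$importance_pct), ]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

## ---- model bundle persistence -----------------------------------------

#' Save / load a model bundle
#'
#' The bundle is a directory holding the serialized booster
#' (`booster.ubj`), and a JSON manifest (`bundle.json`) with the selected
#' hyperparameters, feature schema (retained feature names), preprocessing
#' manifest and diagnostics, so `predict-ie` runs can reproduce training
#' -time filtering exactly.
#'
#' @param model an `ie_model`.
#' @param dir bundle directory (created if needed).
#' @export
save_ie_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(booster_of(model), file.path(dir, "booster.ubj"))
  meta <- list(best_params = model$best_params,
               feature_names = model$feature_names,
               cv_results = model$cv_results,
               resampling = model$resampling,
               diagnostics = model$diagnostics,
               manifest = if (!is.null(model$manifest))
                 manifest_to_list(model$manifest),
               iequant_version =
                 as.character(utils::packageVersion("iequant")))
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname save_ie_model
#' @export
load_ie_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  booster <- xgboost::xgb.load(file.path(dir, "booster.ubj"))
  model <- list(booster_raw = xgboost::xgb.save.raw(booster),
                best_params = as.list(meta$best_params),
                feature_names = meta$feature_names,
                cv_results = meta$cv_results,
                resampling = meta$resampling,
                diagnostics = meta$diagnostics,
                manifest = if (!is.null(meta$manifest))
                  manifest_from_list(meta$manifest))
  class(model) <- "ie_model"
  model
}
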