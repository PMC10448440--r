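#' Assemble the model feature matrix
#'
#' Joins per-compound fingerprint values with the five eluent descriptors
#' computed for each datapoint's mobile-phase condition.
#'
#' @param points data.frame of datapoints (`compound_id`,
#'   `organic_modifier`, `organic_fraction`, `aqueous_pH`, ...).
#' @param fingerprints numeric matrix, rownames = compound ids.
#' @return numeric matrix, one row per datapoint: fingerprint bit columns
#'   followed by the eluent descriptor columns.
#' @export
build_feature_matrix <- function(points, fingerprints) {
  missing <- setdiff(unique(points$compound_id), rownames(fingerprints))
  if (length(missing)) {
    ie_stop("iequant_missing_feature_error",
            "no fingerprints for compound(s): ",
            paste(utils::head(missing, 5), collapse = ", "))
  }
  el <- compute_eluent_descriptors_vec(points$organic_modifier,
                                       points$organic_fraction,
                                       points$aqueous_pH)
  x <- cbind(fingerprints[points$compound_id, , drop = FALSE],
             as.matrix(el[eluent_feature_names()]))
  rownames(x) <- NULL
  x
}

#' End-to-end log IE model training
#'
#' The full training pipeline on an IE dataset: feature assembly,
#' the three-stage filtering cascade, a compound-disjoint 80/20 split,
#' grid-searched boosted-tree training, and held-out evaluation. The
#' preprocessing manifest is attached to the returned model so later
#' predictions are filtered identically.
#'
#' @param points datapoint table (see [build_feature_matrix()]) with a
#'   `log_ie` column.
#' @param fingerprints per-compound fingerprint matrix.
#' @param split_ratio fraction of compounds in the training side.
#' @param hyper_grid,cv,seed passed to [train_ie_model()].
#' @return list of class `ie_workflow`: `model` (with manifest), `split`,
#'   `test_summary` (a [summarize_errors()] battery on the held-out
#'   compounds), `x`/`y` accessors for downstream analyses.
#' @export
train_ie_workflow <- function(points, fingerprints, split_ratio = 0.8,
                              hyper_grid = default_hyper_grid(),
                              cv = list(method = "boot", folds = 5),
                              seed = 1) {
  x_raw <- build_feature_matrix(points, fingerprints)
  y <- points$log_ie
  split <- split_by_compound(points$compound_id, split_ratio, seed)
  pp <- preprocess_features(x_raw[split$train_idx, , drop = FALSE])
  model <- train_ie_model(pp$matrix, y[split$train_idx],
                          hyper_grid = hyper_grid, cv = cv, seed = seed)
  model$manifest <- pp$manifest
  x_test <- apply_manifest(x_raw[split$test_idx, , drop = FALSE],
                           pp$manifest)
  pred_test <- predict(booster_of(model), x_test)
  test_summary <- summarize_errors(pred_test, y[split$test_idx],
                                   scale = "log")
  model$diagnostics$test_rmse <- test_summary$rmse_log
  model$diagnostics$test_rmse_fold <- test_summary$rmse_fold
  out <- list(model = model, split = split, test_summary = test_summary,
              x_raw = x_raw, y = y)
  class(out) <- "ie_workflow"
  out
}

#' @export
print.ie_workflow <- function(x, ...) {
  print(x$model)
  cat(sprintf("  held-out RMSE %.3f log units (%.1fx) on %d datapoints\n",
              x$test_summary$rmse_log, x$test_summary$rmse_fold,
              length(x$split$test_idx)))
  invisible(x)
}
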