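test_that("splitting partitions compounds, not datapoints", {
  ids <- rep(sprintf("cmp%02d", 1:10), each = 2)
  sp <- split_by_compound(ids, ratio = 0.8, seed = 3)
  expect_length(sp$train_compounds, 8)
  expect_length(sp$test_compounds, 2)
  expect_length(sp$train_idx, 16)
  expect_length(sp$test_idx, 4)
  expect_error(split_by_compound(ids, ratio = 1.2),
               class = "iequant_domain_error")
  expect_error(split_by_compound(rep("one", 5)),
               class = "iequant_domain_error")
})

test_that("train/test compound sets are disjoint for any seed", {
  set.seed(42)
  ids <- sample(sprintf("cmp%03d", 1:50), 200, replace = TRUE)
  for (seed in 1:20) {
    sp <- split_by_compound(ids, 0.8, seed)
    expect_length(intersect(sp$train_compounds, sp$test_compounds), 0)
    expect_setequal(c(sp$train_idx, sp$test_idx), seq_along(ids))
    # identical seed reproduces the identical split
    sp2 <- split_by_compound(ids, 0.8, seed)
    expect_identical(sp$train_idx, sp2$train_idx)
  }
})

test_that("an 80/20 compound split of the full-scale dataset lands near 4654/1395", {
  w <- synthetic_world(seed = 8)   # 1191 compounds / 6049 datapoints
  ds <- generate_ie_dataset(w)
  expect_equal(nrow(ds$points), 6049)
  expect_equal(length(unique(ds$points$compound_id)), 1191)
  sp <- split_by_compound(ds$points$compound_id, 0.8, seed = 8)
  expect_length(sp$train_compounds, round(0.8 * 1191))
  # datapoint counts are seed-dependent; they scatter around 4839/1210
  # (datapoints are near-uniform across compounds here)
  expect_gt(length(sp$train_idx), 4500)
  expect_lt(length(sp$train_idx), 5100)
  expect_equal(length(sp$train_idx) + length(sp$test_idx), 6049)
})

test_that("zero-noise additive signal is recovered almost exactly", {
  # additive signal over 5 bits: 160 training compounds cover the 32 bit
  # combinations, so a boosted tree can recover the function exactly;
  # zero baseline keeps the signal clear of the log IE ceiling
  w <- exact_world(seed = 2, n_compounds = 200, n_datapoints = 400,
                   coef_polarity = 0, coef_pH = 0, intercept0 = 0,
                   bit_prevalence = 0.4, n_informative = 5)
  ds <- generate_ie_dataset(w)
  wf <- train_ie_workflow(ds$points, ds$fingerprints,
                          hyper_grid = data.frame(
                            nrounds = 500, max_depth = 4, eta = 0.1,
                            subsample = 1, colsample_bytree = 1,
                            min_child_weight = 1),
                          seed = 2)
  expect_lt(wf$test_summary$rmse_log, 0.1)
  # interpolation on fitted training data is tighter still
  x_train <- wf$x_raw[wf$split$train_idx, ]
  pred <- predict(wf$model, x_train)
  expect_lt(max(abs(pred - wf$y[wf$split$train_idx])), 0.05)
})

test_that("constant labels are predicted as that constant", {
  x <- random_matrix(60, 8, seed = 5)
  y <- rep(2.5, 60)
  model <- train_ie_model(x, y, hyper_grid = tiny_grid(), seed = 1)
  expect_equal(unname(predict(model, x)), rep(2.5, 60), tolerance = 1e-6)
  expect_error(train_ie_model(x, c(rep(1, 59), NA), hyper_grid = tiny_grid()),
               class = "iequant_data_error")
})

test_that("prediction is a pure, reproducible function of its inputs", {
  x <- random_matrix(80, 10, seed = 6)
  y <- x[, 1] * 2 + rnorm(80, sd = 0.1)
  m1 <- train_ie_model(x, y, hyper_grid = tiny_grid(), seed = 7)
  m2 <- train_ie_model(x, y, hyper_grid = tiny_grid(), seed = 7)
  expect_identical(predict(m1, x), predict(m2, x))
  expect_identical(predict(m1, x), predict(m1, x))
})

test_that("probabilistic fingerprints track their binarized version", {
  # confident MS2 probabilities (all >= 0.9 or <= 0.1) should predict close
  # to the hard-bit prediction
  w <- tiny_world(seed = 3, sigma = 0.1)
  ds <- generate_ie_dataset(w)
  wf <- train_ie_workflow(ds$points, ds$fingerprints,
                          hyper_grid = tiny_grid(), seed = 3)
  el <- compute_eluent_descriptors("methanol", 0.5, 7)
  bits <- ds$fingerprints[1, ]
  soft <- abs(bits - 0.08)   # 1 -> 0.92, 0 -> 0.08
  p_hard <- predict_log_ie(wf$model, bits, el)
  p_soft <- predict_log_ie(wf$model, soft, el)
  expect_lt(abs(p_hard - p_soft), 0.3)
})

test_that("y-randomization destroys a genuine signal but not pure noise", {
  w <- tiny_world(seed = 4, sigma = 0.1)
  ds <- generate_ie_dataset(w)
  wf <- train_ie_workflow(ds$points, ds$fingerprints,
                          hyper_grid = tiny_grid(), seed = 4)
  xtr <- wf$x_raw[wf$split$train_idx, ]; ytr <- wf$y[wf$split$train_idx]
  xte <- wf$x_raw[wf$split$test_idx, ]; yte <- wf$y[wf$split$test_idx]
  yr <- y_randomization(wf$model, xtr, ytr, xte, yte, n_repeats = 3,
                        seed = 4)
  base <- yr$test_rmse[yr$run == "baseline"]
  expect_true(all(yr$test_rmse[yr$run != "baseline"] > base))

  # pure-noise labels: permutation changes nothing systematically
  y_noise <- rnorm(length(ytr))
  m0 <- train_ie_model(xtr, y_noise, hyper_grid = tiny_grid(), seed = 4)
  yr0 <- y_randomization(m0, xtr, y_noise, xte, rnorm(length(yte)),
                         n_repeats = 3, seed = 4)
  rng <- range(yr0$test_rmse)
  expect_lt(diff(rng) / mean(yr0$test_rmse), 0.5)
})

test_that("feature importances are normalized and rank planted signal first", {
  set.seed(10)
  x <- matrix(rbinom(300 * 12, 1, 0.5), 300, 12,
              dimnames = list(NULL, sprintf("b%02d", 1:12)))
  y <- 3 * x[, "b05"] + 0.2 * x[, "b01"] + rnorm(300, sd = 0.05)
  model <- train_ie_model(x, y, hyper_grid = tiny_grid(), seed = 2)
  imp <- feature_importance(model, background = x, top_k = Inf)
  expect_equal(imp$feature[1], "b05")
  expect_equal(sum(imp$importance_pct), 100)
  expect_gt(imp$mean_abs_shap[imp$feature == "b05"],
            imp$mean_abs_shap[imp$feature == "b02"])
  # a feature the trees never used carries zero importance
  x2 <- cbind(x, dead = 0)
  m2 <- train_ie_model(x2, y, hyper_grid = tiny_grid(), seed = 2)
  imp2 <- feature_importance(m2, top_k = Inf)
  expect_equal(imp2$importance_pct[imp2$feature == "dead"], 0)
})

test_that("model bundles round-trip through disk", {
  w <- tiny_world(seed = 6)
  ds <- generate_ie_dataset(w)
  wf <- train_ie_workflow(ds$points, ds$fingerprints,
                          hyper_grid = tiny_grid(), seed = 6)
  dir <- withr::local_tempdir()
  save_ie_model(wf$model, dir)
  back <- load_ie_model(dir)
  x <- wf$x_raw[1:10, ]
  expect_equal(predict(back, x), predict(wf$model, x), tolerance = 1e-7)
  expect_equal(back$manifest$retained, wf$model$manifest$retained)
})
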