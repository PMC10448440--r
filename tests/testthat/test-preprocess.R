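test_that("sparse filter applies the strictly-more-than rule", {
  m <- random_matrix(100, 5, seed = 2)
  out <- drop_sparse_features(m)
  expect_identical(out$matrix, m)
  expect_length(out$removed, 0)

  m[1:11, "c01"] <- NA   # 11 missing -> removed
  m[1:10, "c02"] <- NA   # exactly 10 -> kept
  out <- drop_sparse_features(m, max_missing = 10)
  expect_equal(out$removed, "c01")
  expect_true("c02" %in% colnames(out$matrix))

  all_bad <- m; all_bad[1:20, ] <- NA
  expect_warning(out <- drop_sparse_features(all_bad), "all columns")
  expect_equal(ncol(out$matrix), 0)
})

test_that("near-zero-variance filter implements the two-condition rule", {
  m <- cbind(balanced = rep(c(0, 1), 50),
             skewed = c(rep(1, 81), rep(0, 19)),
             constant = rep(3, 100),
             at_ratio = c(rep(1, 80), rep(0, 20)))
  out <- drop_near_zero_variance(m, freq_cut = 80 / 20, unique_cut = 10)
  expect_setequal(out$removed, c("skewed", "constant"))  # 81/19 > 4; single value
  expect_true(all(c("balanced", "at_ratio") %in% colnames(out$matrix)))

  # many distinct values: ratio may exceed the cutoff but percent-unique
  # blocks removal
  v <- c(rep(0, 90), 1:10)
  m2 <- cbind(nearly_const_but_diverse = v, other = seq_len(100))
  out2 <- drop_near_zero_variance(m2)
  expect_length(out2$removed, 0)
})

test_that("near-zero-variance agrees with a brute-force oracle on random data", {
  brute_nzv <- function(m, freq_cut = 4, unique_cut = 10) {
    colnames(m)[vapply(seq_len(ncol(m)), function(j) {
      x <- m[!is.na(m[, j]), j]
      tab <- sort(table(x), decreasing = TRUE)
      if (length(tab) < 2) return(TRUE)
      (tab[[1]] / tab[[2]] > freq_cut) &&
        (100 * length(tab) / nrow(m) < unique_cut)
    }, logical(1))]
  }
  for (seed in 1:5) {
    set.seed(seed)
    m <- cbind(matrix(rbinom(200 * 20, 1, runif(20, 0.02, 0.5)),
                      nrow = 200), matrix(rnorm(200 * 5), nrow = 200))
    colnames(m) <- sprintf("f%02d", seq_len(ncol(m)))
    expect_setequal(drop_near_zero_variance(m)$removed, brute_nzv(m))
  }
})

test_that("correlation filter removes one of two identical columns", {
  set.seed(9)
  base <- rnorm(50)
  m <- cbind(a = base, b = base, c = rnorm(50))
  out <- drop_correlated(m, 0.75)
  expect_length(out$removed, 1)
  expect_true(out$removed %in% c("a", "b"))
  expect_true("c" %in% colnames(out$matrix))
})

test_that("independent noise columns survive the correlation filter", {
  m <- random_matrix(1000, 15, seed = 4)
  out <- drop_correlated(m, 0.75)
  expect_length(out$removed, 0)
})

test_that("no retained pair exceeds the correlation cutoff (exhaustive check)", {
  for (seed in 1:5) {
    set.seed(seed)
    latent <- matrix(rnorm(200 * 5), 200, 5)
    mix <- latent[, sample(5, 50, replace = TRUE)] +
      matrix(rnorm(200 * 50, sd = runif(50, 0.1, 2)), 200, 50)
    colnames(mix) <- sprintf("f%02d", 1:50)
    kept <- drop_correlated(mix, 0.75)$matrix
    cm <- abs(cor(kept)); diag(cm) <- 0
    expect_lte(max(cm), 0.75)
  }
})

test_that("correlation filter is deterministic under column permutation", {
  m <- random_matrix(100, 10, seed = 11)
  m[, 2] <- m[, 1] + rnorm(100, sd = 0.1)
  m[, 5] <- m[, 4] + rnorm(100, sd = 0.1)
  ref <- sort(colnames(drop_correlated(m, 0.75)$matrix))
  for (s in 1:3) {
    set.seed(s)
    perm <- m[, sample(ncol(m))]
    expect_equal(sort(colnames(drop_correlated(perm, 0.75)$matrix)), ref)
  }
})

test_that("cascade builds a manifest that reproduces itself and projects", {
  m <- random_matrix(80, 12, seed = 7, missing = 30)
  colnames(m)[11:12] <- c("polarity_index", "aqueous_pH")
  pp <- preprocess_features(m, max_missing = 5)
  # idempotence: re-applying the manifest to the input gives the output
  expect_equal(apply_manifest(m, pp$manifest), pp$matrix)
  # stage bookkeeping: retained + removed partition the input columns
  removed <- unlist(lapply(pp$manifest$stages, `[[`, "removed"))
  expect_setequal(c(colnames(pp$matrix), removed), colnames(m))
  expect_equal(pp$manifest$stages[[1]]$stage, "sparse")
  expect_equal(pp$manifest$stages[[2]]$stage, "near_zero_variance")
  expect_equal(pp$manifest$stages[[3]]$stage, "correlation")

  # prediction row with extra columns: extras dropped silently
  extra <- cbind(m, junk = rnorm(80))
  expect_message(out <- apply_manifest(extra, pp$manifest), "dropping")
  expect_equal(out, pp$matrix)
  # missing retained feature errors with ids
  short <- m[, -match(pp$manifest$retained[1], colnames(m))]
  expect_error(apply_manifest(short, pp$manifest),
               class = "iequant_missing_feature_error")
})

test_that("empty manifest leaves any matrix unchanged", {
  manifest <- structure(list(stages = list(), retained = character(),
                             impute = list()),
                        class = "preprocess_manifest")
  m <- random_matrix(10, 3)
  expect_identical(apply_manifest(m, manifest), m)
})

test_that("eluent descriptors are spared only as the last one standing", {
  set.seed(21)
  base <- rnorm(200)
  m <- cbind(polarity_index = base,
             surface_tension = base + rnorm(200, sd = 0.05),
             bit_a = rnorm(200))
  out <- drop_correlated(m, 0.75,
                         protect = c("polarity_index", "surface_tension"))
  # one of two protected columns may fall, but never the last one
  expect_true(any(c("polarity_index", "surface_tension") %in%
                    colnames(out$matrix)))
  # protected column with the largest mean correlation would normally be
  # the removal target; the filter must spare it when it is the last one
  m2 <- cbind(polarity_index = base,
              c1 = base + rnorm(200, sd = 0.3),
              c2 = base + rnorm(200, sd = 0.3))
  stopifnot(min(abs(cor(m2))) > 0.75)
  expect_message(
    out2 <- drop_correlated(m2, 0.75, protect = "polarity_index"),
    "sparing")
  expect_true("polarity_index" %in% colnames(out2$matrix))
})

test_that("binary bits impute to 0 and continuous columns to their median", {
  m <- cbind(bit = c(1, NA, 0, 1), polarity_index = c(5, 7, NA, 9))
  rownames(m) <- paste0("r", 1:4)
  pp <- preprocess_features(m, max_missing = 10, freq_cut = 100,
                            cutoff = 0.99)
  expect_equal(pp$matrix[2, "bit"], 0)
  expect_equal(pp$matrix[3, "polarity_index"], 7)
  expect_equal(pp$manifest$impute$polarity_index, 7)
})
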