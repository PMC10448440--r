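#' Descriptor filtering cascade
#'
#' Training feature matrices pass through three filters, in this fixed
#' order: (1) columns with more than `max_missing` missing values are
#' dropped; (2) near-zero-variance columns are dropped under the canonical
#' two-condition rule (frequency ratio of the two most common values above
#' `freq_cut` AND percent-unique below `unique_cut`; single-valued columns
#' always go); (3) pairwise correlations are reduced by repeatedly finding
#' the pair with the highest absolute Pearson correlation above `cutoff`
#' and removing the member with the larger mean absolute correlation
#' against all remaining columns. Remaining missing values are imputed
#' (0 for binary fingerprint bits, column median for continuous
#' descriptors) and the whole recipe is recorded in a manifest so
#' prediction-time inputs are filtered identically, with no re-fitting.
#'
#' @name preprocess
NULL

#' @describeIn preprocess Drop columns with more than `max_missing` missing
#'   values (a column with exactly `max_missing` is kept).
#' @param matrix numeric matrix with unique row/column names; `NA` marks
#'   missing values.
#' @param max_missing missing-count threshold per column.
#' @return a list with elements `matrix` (the filtered matrix) and
#'   `removed` (character vector of dropped column ids).
#' @export
drop_sparse_features <- function(matrix, max_missing = 10) {
  stopifnot(is.matrix(matrix), nrow(matrix) > 0)
  n_miss <- colSums(is.na(matrix))
  removed <- colnames(matrix)[n_miss > max_missing]
  if (length(removed) == ncol(matrix)) {
    warning("all columns exceeded the missing-value threshold")
  }
  list(matrix = matrix[, setdiff(colnames(matrix), removed), drop = FALSE],
       removed = removed)
}

#' @describeIn preprocess Drop near-zero-variance columns.
#' @param freq_cut cutoff for the ratio of the most common to the second
#'   most common value (default 80/20 = 4).
#' @param unique_cut percent-unique cutoff (distinct values / rows * 100).
#' @export
drop_near_zero_variance <- function(matrix, freq_cut = 80 / 20,
                                    unique_cut = 10) {
  stopifnot(is.matrix(matrix))
  flag <- vapply(seq_len(ncol(matrix)), function(j) {
    x <- matrix[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0) return(TRUE)
    tab <- sort(table(x), decreasing = TRUE)
    if (length(tab) == 1) return(TRUE)
    ratio <- tab[[1]] / tab[[2]]
    pct_unique <- 100 * length(tab) / nrow(matrix)
    ratio > freq_cut && pct_unique < unique_cut
  }, logical(1))
  removed <- colnames(matrix)[flag]
  list(matrix = matrix[, !flag, drop = FALSE], removed = removed)
}

#' @describeIn preprocess Reduce pairwise correlations above `cutoff`.
#'   Ties in mean absolute correlation are broken by retaining the
#'   earlier column. Columns named in `protect` are exempt from removal
#'   only when removing one would leave no protected column; such
#'   exemptions are logged.
#' @param cutoff absolute Pearson correlation threshold.
#' @param protect character vector of column ids (e.g. the eluent
#'   descriptors) that may not be removed down to zero.
#' @export
drop_correlated <- function(matrix, cutoff = 0.75, protect = character()) {
  stopifnot(is.matrix(matrix))
  if (ncol(matrix) < 2) return(list(matrix = matrix, removed = character()))
  cm <- abs(cor(matrix, use = "pairwise.complete.obs"))
  diag(cm) <- 0
  cm[is.na(cm)] <- 0
  keep <- colnames(matrix)
  removed <- character()
  repeat {
    sub <- cm[keep, keep, drop = FALSE]
    if (max(sub) <= cutoff) break
    idx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    a <- keep[idx[1]]; b <- keep[idx[2]]
    mean_a <- mean(sub[a, setdiff(keep, a)])
    mean_b <- mean(sub[b, setdiff(keep, b)])
    # remove the member with larger mean |r|; on ties keep the earlier column
    drop_id <- if (mean_a > mean_b) a
      else if (mean_b > mean_a) b
      else keep[max(idx)]
    if (drop_id %in% protect &&
        sum(keep %in% protect) <= 1) {
      other <- if (drop_id == a) b else a
      ie_log("correlation filter: sparing last protected feature '",
             drop_id, "', removing '", other, "' instead")
      drop_id <- other
    }
    removed <- c(removed, drop_id)
    keep <- setdiff(keep, drop_id)
    if (length(keep) < 2) break
  }
  list(matrix = matrix[, keep, drop = FALSE], removed = removed)
}

#' @describeIn preprocess Run the full cascade and build the manifest.
#' @param continuous character vector of column ids treated as continuous
#'   (median-imputed); all other columns are binary bits (zero-imputed).
#' @param protect_eluent protect the eluent descriptor columns from being
#'   eliminated entirely by the correlation filter.
#' @export
preprocess_features <- function(matrix, max_missing = 10, freq_cut = 80 / 20,
                                unique_cut = 10, cutoff = 0.75,
                                continuous = intersect(eluent_feature_names(),
                                                       colnames(matrix)),
                                protect_eluent = TRUE) {
  s1 <- drop_sparse_features(matrix, max_missing)
  # impute straight after the sparse filter so later stages see complete data
  imp <- impute_values(s1$matrix, continuous)
  m_imp <- impute_apply(s1$matrix, imp)
  s2 <- drop_near_zero_variance(m_imp, freq_cut, unique_cut)
  prot <- if (protect_eluent) intersect(continuous, colnames(s2$matrix))
          else character()
  s3 <- drop_correlated(s2$matrix, cutoff, protect = prot)
  manifest <- list(
    stages = list(
      list(stage = "sparse", rule = list(max_missing = max_missing),
           removed = s1$removed),
      list(stage = "near_zero_variance",
           rule = list(freq_cut = freq_cut, unique_cut = unique_cut),
           removed = s2$removed),
      list(stage = "correlation", rule = list(cutoff = cutoff),
           removed = s3$removed)
    ),
    retained = colnames(s3$matrix),
    impute = imp[names(imp) %in% colnames(s3$matrix)],
    continuous = continuous
  )
  class(manifest) <- "preprocess_manifest"
  list(matrix = s3$matrix, manifest = manifest)
}

impute_values <- function(matrix, continuous) {
  vals <- lapply(colnames(matrix), function(cn) {
    if (cn %in% continuous) {
      v <- median(matrix[, cn], na.rm = TRUE)
      if (is.na(v)) 0 else v
    } else 0
  })
  setNames(vals, colnames(matrix))
}

impute_apply <- function(matrix, imp) {
  for (cn in colnames(matrix)) {
    miss <- is.na(matrix[, cn])
    if (any(miss)) matrix[miss, cn] <- imp[[cn]]
  }
  matrix
}

#' Apply a preprocessing manifest to new data
#'
#' Projects a feature matrix onto the manifest's retained features, in
#' order, imputing missing values with the recorded training-time policy.
#' Nothing is re-fitted; extra columns are dropped (and logged).
#'
#' @param matrix numeric matrix containing at least the retained features.
#' @param manifest a `preprocess_manifest` from [preprocess_features()].
#' @return the projected matrix.
#' @export
apply_manifest <- function(matrix, manifest) {
  retained <- manifest$retained
  if (length(retained) == 0) return(matrix)
  missing <- setdiff(retained, colnames(matrix))
  if (length(missing)) {
    ie_stop("iequant_missing_feature_error",
            "retained feature(s) absent from input: ",
            paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  }
  extra <- setdiff(colnames(matrix), retained)
  if (length(extra)) {
    ie_log("apply_manifest: dropping ", length(extra),
           " column(s) not retained by the model")
  }
  out <- matrix[, retained, drop = FALSE]
  impute_apply(out, manifest$impute)
}

#' @export
print.preprocess_manifest <- function(x, ...) {
  cat("Preprocessing manifest:", length(x$retained), "features retained\n")
  for (st in x$stages) {
    cat(sprintf("  %-20s removed %d\n", st$stage, length(st$removed)))
  }
  invisible(x)
}

manifest_to_list <- function(manifest) unclass(manifest)

manifest_from_list <- function(x) {
  x$retained <- as.character(x$retained)
  x$impute <- as.list(setNames(unlist(x$impute), names(x$impute)))
  class(x) <- "preprocess_manifest"
  x
}
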