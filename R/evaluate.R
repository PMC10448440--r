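#' Fold error
#'
#' The multiplicative prediction error of a pair of values on the same
#' scale: `10^|log10(predicted) - log10(true)|`, i.e. `max(p/t, t/p)` on
#' the linear scale. Always >= 1, symmetric in its arguments and invariant
#' to rescaling both by a common factor. Pass `scale = "log"` when the
#' inputs are already log10 quantities (e.g. log IE), in which case the
#' fold error is `10^|predicted - true|`.
#'
#' @param predicted,true numeric vectors on a common scale.
#' @param scale `"linear"` (default; both must be > 0) or `"log"`.
#' @return fold errors, >= 1.
#' @export
#' @examples
#' fold_error(10, 1)            # 10
#' fold_error(0.55, 0, "log")   # 3.55x, the fold equivalent of 0.55 log units
fold_error <- function(predicted, true, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  if (anyNA(predicted) || anyNA(true)) {
    ie_stop("iequant_domain_error", "missing values in predicted/true pairs")
  }
  if (scale == "linear") {
    if (any(predicted <= 0) || any(true <= 0)) {
      ie_stop("iequant_domain_error",
              "linear-scale values must be > 0 (use scale = \"log\" for log values)")
    }
    predicted <- log10(predicted); true <- log10(true)
  }
  if (any(!is.finite(predicted)) || any(!is.finite(true))) {
    ie_stop("iequant_domain_error", "non-finite values")
  }
  10^abs(predicted - true)
}

#' Fold-error summary battery
#'
#' The full metric battery for a set of (predicted, true) pairs: RMSE on
#' the log10 scale with its fold equivalent (`10^rmse_log`), R-squared
#' (squared Pearson correlation of the log10 values), and the fold-error
#' distribution (arithmetic mean, geometric mean, and the 25/50/75/90/100 %
#' quantiles, linear-interpolation type 7). Identical whether the pairs are
#' supplied on the linear or the log10 scale.
#'
#' @inheritParams fold_error
#' @return object of class `fold_error_summary`: a one-row data.frame with
#'   columns `rmse_log`, `rmse_fold`, `r_squared`, `mean_fold`,
#'   `geom_mean_fold`, `q25`, `q50_median`, `q75`, `q90`, `q100_max`, `n`.
#' @export
summarize_errors <- function(predicted, true, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  folds <- fold_error(predicted, true, scale)
  if (scale == "linear") {
    predicted <- log10(predicted); true <- log10(true)
  }
  d <- predicted - true
  q <- quantile(folds, c(0.25, 0.5, 0.75, 0.9, 1), type = 7, names = FALSE)
  out <- data.frame(
    rmse_log = sqrt(mean(d^2)),
    rmse_fold = 10^sqrt(mean(d^2)),
    r_squared = if (length(d) > 1 && sd(predicted) > 0 && sd(true) > 0) {
      cor(predicted, true)^2
    } else NA_real_,
    mean_fold = mean(folds),
    geom_mean_fold = 10^mean(abs(d)),
    q25 = q[1], q50_median = q[2], q75 = q[3], q90 = q[4], q100_max = q[5],
    n = length(folds))
  class(out) <- c("fold_error_summary", "data.frame")
  out
}

#' @export
print.fold_error_summary <- function(x, ...) {
  cat(sprintf("Fold-error summary (n = %d)\n", x$n))
  cat(sprintf("  RMSE          %.2f log units (%.1fx)\n", x$rmse_log, x$rmse_fold))
  if (!is.na(x$r_squared)) cat(sprintf("  R2            %.2f\n", x$r_squared))
  cat(sprintf("  Mean          %.2fx\n", x$mean_fold))
  cat(sprintf("  Geom. mean    %.2fx\n", x$geom_mean_fold))
  cat(sprintf("  Q25           %.2fx\n", x$q25))
  cat(sprintf("  Q50 (Median)  %.2fx\n", x$q50_median))
  cat(sprintf("  Q75           %.2fx\n", x$q75))
  cat(sprintf("  Q90           %.2fx\n", x$q90))
  cat(sprintf("  Q100 (Max)    %.2fx\n", x$q100_max))
  invisible(x)
}

#' Per-group geometric mean fold errors
#'
#' Aggregates prediction errors hierarchically: the geometric mean fold
#' error is computed per unique compound first, then the distribution of
#' those per-compound values is summarised within each group (e.g. a
#' compound class). Groups with fewer than `min_members` unique compounds
#' are flagged for exclusion from plots.
#'
#' @inheritParams fold_error
#' @param compound compound identifier per pair.
#' @param group group label per pair.
#' @param min_members minimum unique compounds for a group to be reported
#'   unflagged.
#' @return list with `per_compound` (compound, group, geometric mean fold)
#'   and `per_group` (group, n_compounds, median/geometric-mean folds,
#'   `excluded` flag), the latter in descending order of median fold error.
#' @export
summarize_by_group <- function(predicted, true, compound, group,
                               scale = c("linear", "log"), min_members = 3) {
  folds <- fold_error(predicted, true, scale)
  per_compound <- do.call(rbind, lapply(split(seq_along(folds), compound),
    function(idx) data.frame(
      compound = compound[idx[1]], group = group[idx[1]],
      geom_mean_fold = 10^mean(abs(log10(folds[idx]))))))
  per_group <- do.call(rbind, lapply(split(per_compound, per_compound$group),
    function(g) data.frame(
      group = g$group[1], n_compounds = nrow(g),
      median_fold = median(g$geom_mean_fold),
      geom_mean_fold = 10^mean(log10(g$geom_mean_fold)),
      excluded = nrow(g) < min_members)))
  per_group <- per_group[order(-per_group$median_fold), ]
  rownames(per_compound) <- rownames(per_group) <- NULL
  list(per_compound = per_compound, per_group = per_group)
}

#' Overprediction rate
#'
#' Fraction of pairs whose prediction exceeds the true value -- a bias
#' check (unbiased noise gives ~0.5).
#'
#' @param predicted,true numeric vectors on a common scale.
#' @return fraction in \[0, 1\].
#' @export
overprediction_rate <- function(predicted, true) {
  if (length(predicted) < 1) ie_stop("iequant_domain_error", "empty input")
  mean(predicted > true)
}
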