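#' Read a log IE training table
#'
#' Reads a UTF-8 CSV (header row, decimal point) of unified log IE
#' datapoints. Rows whose SMILES does not parse or whose `log_ie` is
#' missing are dropped with a logged count; a missing mandatory column is
#' a schema error naming the column. A `canonical_id` column is added
#' (canonical SMILES) so the same chemical never splits across train/test.
#'
#' @param path CSV with columns `compound_id`, `smiles`, `log_ie`,
#'   `organic_modifier`, `organic_fraction`, `aqueous_pH`, `dataset_id`.
#' @return data.frame of datapoints.
#' @export
read_training_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "smiles", "log_ie", "organic_modifier",
            "organic_fraction", "aqueous_pH", "dataset_id")
  check_columns(tab, need, "training table")
  n0 <- nrow(tab)
  drop_na <- is.na(tab$log_ie) | !is.finite(tab$log_ie)
  tab <- tab[!drop_na, , drop = FALSE]
  can <- canonicalize_smiles(tab$smiles)
  bad <- is.na(can)
  if (sum(drop_na) + sum(bad) > 0) {
    ie_log("read_training_table: dropped ", sum(drop_na),
           " row(s) with missing log IE and ", sum(bad),
           " row(s) with unparseable SMILES (", n0, " read)")
  }
  tab <- tab[!bad, , drop = FALSE]
  tab$canonical_id <- can[!bad]
  rownames(tab) <- NULL
  tab
}

#' @rdname read_training_table
#' @param points datapoint data.frame to write.
#' @export
write_training_table <- function(points, path) {
  write.csv(points, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_columns <- function(tab, need, what) {
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    ie_stop("iequant_schema_error", what, " lacks mandatory column(s): ",
            paste(missing, collapse = ", "))
  }
}

#' Read a fingerprint (probability) table
#'
#' Accepts either wide format (a `feature_id` column plus one column per
#' bit) or long format (exactly `feature_id`, `bit_id`, `probability`),
#' auto-detected from the header. Values must lie in \[0, 1\]
#' (probabilities from an MS2 fingerprint predictor, or 0/1 for
#' structure-derived bits); a violation is reported with its row and
#' column. Columns are matched to the schema by bit id; schema bits absent
#' from the file are filled with `NA` (the missing marker, later handled
#' by the preprocessing manifest's imputation policy); file columns not in
#' the schema are dropped. No overlap at all is a schema mismatch.
#'
#' @param path CSV path.
#' @param schema an `fp_schema` defining bit ids and their order.
#' @return numeric matrix: rows = feature ids, columns = schema bits.
#' @export
read_fingerprint_probability_table <- function(path, schema) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(tab, "feature_id", "fingerprint table")
  long <- setequal(names(tab), c("feature_id", "bit_id", "probability"))
  if (long) {
    feats <- unique(tab$feature_id)
    m <- matrix(NA_real_, length(feats), nrow(schema),
                dimnames = list(feats, schema$bit_id))
    known <- tab$bit_id %in% schema$bit_id
    if (!any(known)) {
      ie_stop("iequant_schema_mismatch_error",
              "no bit_id in the file matches the schema")
    }
    validate_unit_interval(tab$probability, tab$feature_id, tab$bit_id)
    m[cbind(tab$feature_id[known], tab$bit_id[known])] <-
      tab$probability[known]
    return(m)
  }
  bit_cols <- setdiff(names(tab), "feature_id")
  overlap <- intersect(bit_cols, schema$bit_id)
  if (length(overlap) == 0) {
    ie_stop("iequant_schema_mismatch_error",
            "no column of the file matches a schema bit id")
  }
  vals <- as.matrix(tab[overlap])
  for (j in seq_along(overlap)) {
    validate_unit_interval(vals[, j], tab$feature_id, overlap[j])
  }
  m <- matrix(NA_real_, nrow(tab), nrow(schema),
              dimnames = list(tab$feature_id, schema$bit_id))
  m[, overlap] <- vals
  dropped <- setdiff(bit_cols, schema$bit_id)
  if (length(dropped)) {
    ie_log("fingerprint table: ignoring ", length(dropped),
           " column(s) not in the schema")
  }
  m
}

validate_unit_interval <- function(x, row_ids, col_ids) {
  bad <- which(!is.na(x) & (x < 0 | x > 1))
  if (length(bad)) {
    ie_stop("iequant_validation_error",
            "fingerprint value outside [0, 1] at feature '",
            row_ids[bad[1]], "', bit '",
            if (length(col_ids) > 1) col_ids[bad[1]] else col_ids,
            "' (value ", format(x[bad[1]]), ")")
  }
}

#' @rdname read_fingerprint_probability_table
#' @param fingerprints matrix to write (rownames = feature ids).
#' @export
write_fingerprint_table <- function(fingerprints, path) {
  tab <- data.frame(feature_id = rownames(fingerprints),
                    fingerprints, check.names = FALSE)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibrant table
#'
#' Either a direct form (`compound_id`, `smiles`, `rf`) or a
#' concentration/area series (`compound_id`, `smiles`, `concentration`,
#' `peak_area`) from which each compound's response factor is fit as the
#' slope of the through-origin regression of area on concentration.
#'
#' @param path CSV path.
#' @return data.frame with columns `compound_id`, `smiles`, `rf`.
#' @export
read_calibrant_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("compound_id", "smiles"), "calibrant table")
  if (!"rf" %in% names(tab)) {
    check_columns(tab, c("concentration", "peak_area"), "calibrant table")
    tab <- do.call(rbind, lapply(split(tab, tab$compound_id), function(g) {
      data.frame(compound_id = g$compound_id[1], smiles = g$smiles[1],
                 rf = sum(g$peak_area * g$concentration) /
                   sum(g$concentration^2))
    }))
    rownames(tab) <- NULL
  }
  if (any(!is.finite(tab$rf)) || any(tab$rf <= 0)) {
    ie_stop("iequant_domain_error", "calibrant response factors must be > 0")
  }
  if (nrow(tab) < 2) {
    ie_stop("iequant_insufficient_data_error",
            "need at least 2 distinct calibrants")
  }
  if (nrow(tab) < 5) warning("fewer than 5 calibrants")
  tab
}

#' Read a suspect table
#'
#' @param path CSV with columns `feature_id`, `peak_area` and optionally
#'   `retention_time`, `smiles`, `ion_ok`.
#' @return data.frame, `feature_id` unique and `peak_area > 0` enforced.
#' @export
read_suspect_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, c("feature_id", "peak_area"), "suspect table")
  if (anyDuplicated(tab$feature_id)) {
    ie_stop("iequant_domain_error", "duplicate feature_id in suspect table")
  }
  if (any(tab$peak_area <= 0)) {
    ie_stop("iequant_domain_error", "peak_area must be > 0")
  }
  tab
}

#' Run configuration
#'
#' Builds and validates the run configuration, optionally from a YAML
#' file. The gradient program is either a fixed organic fraction
#' (`organic_fraction`) or a list of `(time, fraction)` breakpoints
#' (`gradient_program`).
#'
#' @param path YAML file; fields mirror the arguments below.
#' @param ... overrides: `organic_modifier`, `aqueous_pH`,
#'   `organic_fraction` or `gradient_program`, `column_dead_time`,
#'   `random_seed`, `split_ratio`, `output_dir`.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(organic_modifier = "methanol", aqueous_pH = 7.0,
              organic_fraction = 0.5, gradient_program = NULL,
              column_dead_time = 0, random_seed = 1L, split_ratio = 0.8,
              output_dir = ".")
  if (!is.null(path)) {
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, list(...))
  match_modifier(cfg$organic_modifier)
  if (cfg$split_ratio <= 0 || cfg$split_ratio >= 1) {
    ie_stop("iequant_domain_error", "split_ratio must lie in (0, 1)")
  }
  if (!is.null(cfg$gradient_program)) {
    gp <- as.data.frame(do.call(rbind, lapply(cfg$gradient_program, unlist)))
    names(gp) <- c("time", "fraction")
    if (any(gp$fraction < 0 | gp$fraction > 1)) {
      ie_stop("iequant_domain_error",
              "gradient fractions must lie in [0, 1]")
    }
    if (nrow(gp) > 1 && any(diff(gp$time) <= 0)) {
      ie_stop("iequant_domain_error",
              "gradient times must be strictly increasing")
    }
    cfg$gradient_program <- gp
  } else if (cfg$organic_fraction < 0 || cfg$organic_fraction > 1) {
    ie_stop("iequant_domain_error", "organic_fraction must lie in [0, 1]")
  }
  class(cfg) <- "run_config"
  cfg
}

config_eluent <- function(cfg) {
  prog <- cfg$gradient_program %||%
    data.frame(time = 0, fraction = cfg$organic_fraction)
  list(gradient_program = prog, organic_modifier = cfg$organic_modifier,
       aqueous_pH = cfg$aqueous_pH, column_dead_time = cfg$column_dead_time)
}

#' Table-1-style evaluation report
#'
#' Renames a [summarize_errors()] battery to the conventional report rows.
#'
#' @param summary a `fold_error_summary`.
#' @return named list: `RMSE`, `R2`, `Mean`, `Geom. mean`, `Q25`,
#'   `Q50 (Median)`, `Q75`, `Q90`, `Q100 (Max)`, `n`.
#' @export
as_metric_report <- function(summary) {
  list("RMSE" = summary$rmse_fold, "R2" = summary$r_squared,
       "Mean" = summary$mean_fold, "Geom. mean" = summary$geom_mean_fold,
       "Q25" = summary$q25, "Q50 (Median)" = summary$q50_median,
       "Q75" = summary$q75, "Q90" = summary$q90,
       "Q100 (Max)" = summary$q100_max, "n" = summary$n)
}
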