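#' Calibration: anchoring predicted log IE to response factors
#'
#' Predicted ionization efficiencies live on a unified, instrument-agnostic
#' scale. A set of calibrants with known response factors (RF, peak area
#' per mol/L) measured in the same run anchors that scale to the
#' instrument: an ordinary least-squares line is fit in log-log space,
#' `log10(RF) = slope * log10(IE_pred) + intercept`.
#'
#' @param rf measured response factors of the calibrants (area per mol/L,
#'   strictly positive).
#' @param log_ie predicted log10 IE of the same calibrants.
#' @return object of class `calibration_model` with `slope`, `intercept`,
#'   `r_squared`, `residual_se` (log10 units), `slope_p_value`,
#'   `n_calibrants` and the underlying `lm` fit.
#' @export
#' @examples
#' cal <- fit_calibration(rf = c(1e4, 1e5, 3e5), log_ie = c(1, 2, 2.5))
#' cal$slope
fit_calibration <- function(rf, log_ie) {
  if (length(rf) != length(log_ie)) {
    ie_stop("iequant_domain_error", "rf and log_ie lengths differ")
  }
  ok <- is.finite(rf) & is.finite(log_ie)
  if (any(rf[ok] <= 0)) {
    ie_stop("iequant_domain_error", "response factors must be > 0")
  }
  if (sum(ok) < 2) {
    ie_stop("iequant_insufficient_data_error",
            "need at least 2 calibrants, got ", sum(ok))
  }
  if (sum(ok) < 5) {
    warning("fewer than 5 calibrants; calibration will be unstable")
  }
  fit <- lm(log10(rf[ok]) ~ log_ie[ok])
  sm <- summary(fit)
  res <- list(slope = unname(coef(fit)[2]),
              intercept = unname(coef(fit)[1]),
              r_squared = sm$r.squared,
              residual_se = if (fit$df.residual > 0) sm$sigma else 0,
              slope_p_value = if (nrow(sm$coefficients) > 1)
                sm$coefficients[2, 4] else NA_real_,
              n_calibrants = sum(ok),
              fit = fit)
  class(res) <- "calibration_model"
  res
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Calibration (n = %d): log10 RF = %.3f * log10 IE + %.3f\n",
    x$n_calibrants, x$slope, x$intercept))
  cat(sprintf("  R2 = %.3f, residual SE = %.3f log units\n",
              x$r_squared, x$residual_se))
  invisible(x)
}

#' Predicted response factor from predicted log IE
#'
#' `RF = 10^(slope * log_ie + intercept)`; strictly positive, and monotone
#' increasing in log IE when the calibration slope is positive.
#'
#' @param calibration a `calibration_model`.
#' @param log_ie predicted log10 IE (vectorised).
#' @return predicted response factor(s), area per mol/L.
#' @export
predict_response_factor <- function(calibration, log_ie) {
  10^(calibration$slope * log_ie + calibration$intercept)
}

#' Concentration from peak area and response factor
#'
#' @param peak_area integrated peak area (> 0).
#' @param rf response factor, area per mol/L (> 0).
#' @return concentration in mol/L (`peak_area / rf`).
#' @export
estimate_concentration <- function(peak_area, rf) {
  if (any(peak_area <= 0) || any(rf <= 0)) {
    ie_stop("iequant_domain_error", "peak_area and rf must be > 0")
  }
  peak_area / rf
}

#' Quantify suspect features
#'
#' Runs the full prediction chain for a suspect table: resolve each
#' feature to a fingerprint vector (from SMILES, or from a supplied
#' MS2-probability matrix), predict log IE, convert to a response factor
#' through the calibration, and divide the peak area by it. Features that
#' cannot be resolved are skipped with a logged reason, not fatal; features
#' flagged as neither protonated nor permanently charged (an optional
#' logical `ion_ok` column, declared upstream by adduct assignment) are
#' excluded the same way. Suspects that are also calibrants can be flagged
#' via `calibrant_ids`.
#'
#' @param model a fitted `ie_model`.
#' @param calibration a `calibration_model`.
#' @param suspects data.frame with columns `feature_id`, `peak_area`,
#'   optionally `smiles`, `retention_time`, `ion_ok`.
#' @param fingerprints optional numeric matrix of MS2-predicted fingerprint
#'   probabilities, rownames = feature ids, values in \[0, 1\].
#' @param eluent either a one-row eluent descriptor data.frame applied to
#'   all features, or a gradient specification list with elements
#'   `gradient_program`, `organic_modifier`, `aqueous_pH` and optionally
#'   `column_dead_time` (requires `retention_time` per feature).
#' @param schema fingerprint schema for the SMILES path.
#' @param prefer `"ms2"` or `"structure"`: which path to use when a feature
#'   has both.
#' @param calibrant_ids feature ids that also appear among the calibrants.
#' @return data.frame (one row per quantified feature): `feature_id`,
#'   `provenance`, `log_ie_pred`, `rf_pred`, `peak_area`, `conc_pred_M`,
#'   `is_calibrant`; skipped features are reported via messages.
#' @export
quantify_suspects <- function(model, calibration, suspects,
                              fingerprints = NULL, eluent,
                              schema = NULL, prefer = c("ms2", "structure"),
                              calibrant_ids = character()) {
  prefer <- match.arg(prefer)
  if (nrow(suspects) == 0) {
    return(data.frame(feature_id = character(), provenance = character(),
                      log_ie_pred = numeric(), rf_pred = numeric(),
                      peak_area = numeric(), conc_pred_M = numeric(),
                      is_calibrant = logical()))
  }
  if (anyDuplicated(suspects$feature_id)) {
    ie_stop("iequant_domain_error", "feature_id must be unique")
  }
  rows <- vector("list", nrow(suspects))
  for (i in seq_len(nrow(suspects))) {
    s <- suspects[i, ]
    if (!is.null(s$ion_ok) && !is.na(s$ion_ok) && !s$ion_ok) {
      ie_log("skipping ", s$feature_id,
             ": not protonated or permanently charged")
      next
    }
    has_ms2 <- !is.null(fingerprints) && s$feature_id %in% rownames(fingerprints)
    has_smiles <- !is.null(s$smiles) && !is.na(s$smiles) && nzchar(s$smiles)
    use <- if (prefer == "ms2" && has_ms2) "ms2"
      else if (prefer == "structure" && has_smiles) "structure"
      else if (has_ms2) "ms2" else if (has_smiles) "structure" else NA
    if (is.na(use)) {
      ie_log("skipping ", s$feature_id, ": no SMILES and no fingerprint row")
      next
    }
    fp <- if (use == "ms2") fingerprints[s$feature_id, ]
      else tryCatch(
        fingerprint_from_smiles(s$smiles,
                                schema %||% build_default_schema()),
        error = function(e) NULL)
    if (is.null(fp)) {
      ie_log("skipping ", s$feature_id, ": unparseable SMILES")
      next
    }
    el <- resolve_eluent(eluent, s$retention_time)
    log_ie <- predict_log_ie(model, fp, el)
    rf <- predict_response_factor(calibration, log_ie)
    rows[[i]] <- data.frame(
      feature_id = s$feature_id, provenance = use, log_ie_pred = log_ie,
      rf_pred = rf, peak_area = s$peak_area,
      conc_pred_M = estimate_concentration(s$peak_area, rf),
      is_calibrant = s$feature_id %in% calibrant_ids)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

resolve_eluent <- function(eluent, retention_time = NULL) {
  if (is.data.frame(eluent)) return(eluent[1, , drop = FALSE])
  if (is.list(eluent) && !is.null(eluent$gradient_program)) {
    rt <- retention_time %||% 0
    if (is.null(retention_time) || is.na(rt)) rt <- 0
    frac <- organic_fraction_at(eluent$gradient_program, rt,
                                eluent$column_dead_time %||% 0)
    return(compute_eluent_descriptors(eluent$organic_modifier, frac,
                                      eluent$aqueous_pH))
  }
  ie_stop("iequant_domain_error", "cannot interpret eluent specification")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
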