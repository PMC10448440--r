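#' Synthetic world specification
#'
#' Defines the generative model behind all synthetic data: random binary
#' fingerprints; log IE as an additive function of a handful of
#' informative bits, the eluent (via the polarity index and aqueous pH),
#' a per-dataset instrument offset, and Gaussian label noise; response
#' factors log-linear in log IE with log-normal calibration scatter. The
#' defaults mirror the scale of the unified training data the model is
#' meant for (1191 compounds / 6049 datapoints across 13 instrument
#' datasets, log IE spanning roughly -1.5 to 7.5) and the validation
#' campaign design (36 calibrants, 39 suspects).
#'
#' @param seed integer seed; every generator is a pure function of the
#'   world (including this seed).
#' @param n_compounds,n_datapoints,n_bits,n_datasets dataset dimensions;
#'   `n_datapoints` defaults to the study's datapoints-per-compound ratio
#'   (6049/1191, about 5 conditions per compound).
#' @param bit_prevalence Bernoulli rate(s) of the fingerprint bits. The
#'   default `NULL` draws a heterogeneous prevalence profile emulating real
#'   substructure fingerprints, where most keys are rare (and are later
#'   removed by the near-zero-variance filter, as in the 1263-to-117
#'   descriptor cascade the preprocessing is designed for) while a minority
#'   of common substructure keys carry the signal: a fraction
#'   `rare_bit_frac` of bits get prevalence in `rare_range`, the rest in
#'   `common_range`. A scalar gives every bit that prevalence.
#' @param rare_bit_frac,rare_range,common_range the prevalence profile
#'   (see `bit_prevalence`).
#' @param n_informative number of bits that actually carry signal.
#' @param effect_min,effect_max range of informative-bit effect sizes
#'   (log10 units; effects are evenly spaced across the range).
#' @param coef_polarity,coef_pH eluent effect coefficients (log10 IE per
#'   polarity-index unit / per pH unit).
#' @param dataset_offset_sd spread of per-instrument offsets (log10 units).
#'   The emulated training table is already on a unified log IE scale, so
#'   the default is a small residual calibration-transfer error rather
#'   than raw inter-instrument spread.
#' @param sigma label noise SD (log10 units).
#' @param intercept0 baseline log10 IE; the default centers the generated
#'   distribution mid-range (around 3) once the expected bit, eluent and
#'   dataset contributions are added, so labels span the unified scale
#'   instead of piling up at the clamp boundaries.
#' @param log_ie_range generated log IE is clamped to this range.
#' @param cal_slope,cal_intercept,sigma_cal true calibration line
#'   `log10 RF = slope * log10 IE + intercept` and its scatter (log10 units).
#' @param n_calibrants,n_suspects campaign sizes.
#' @param conc_range suspect concentration range (mol/L, log-uniform).
#' @param blur,flip MS2-emulation corruption: probabilities are shrunk
#'   toward 0.5 by `blur` and flipped (p -> 1 - p) with probability `flip`.
#' @return a list of class `synthetic_world`.
#' @export
synthetic_world <- function(seed = 1,
                            n_compounds = 1191,
                            n_datapoints = round(n_compounds * 6049 / 1191),
                            n_bits = 542, n_datasets = 13,
                            bit_prevalence = NULL,
                            rare_bit_frac = 0.75,
                            rare_range = c(0.005, 0.15),
                            common_range = c(0.2, 0.6),
                            n_informative = 10,
                            effect_min = 0.3, effect_max = 1.5,
                            coef_polarity = -0.35, coef_pH = -0.12,
                            dataset_offset_sd = 0.1,
                            sigma = 0.3, intercept0 = -1.6,
                            log_ie_range = c(-1.5, 7.5),
                            cal_slope = 0.9, cal_intercept = 2.0,
                            sigma_cal = 0.2,
                            n_calibrants = 36, n_suspects = 39,
                            conc_range = c(5e-9, 5e-6),
                            blur = 0.1, flip = 0.02) {
  stopifnot(sigma >= 0, sigma_cal >= 0, blur >= 0, blur <= 1,
            flip >= 0, flip <= 1, n_informative <= n_bits)
  world <- as.list(environment())
  world[c("bit_prevalence", "informative_bits")] <- with_seed(seed * 7 + 11, {
    prev <- if (is.null(bit_prevalence)) {
      rare <- runif(n_bits) < rare_bit_frac
      ifelse(rare, runif(n_bits, rare_range[1], rare_range[2]),
             runif(n_bits, common_range[1], common_range[2]))
    } else rep_len(bit_prevalence, n_bits)
    # signal-carrying bits are common substructures: rare keys could not
    # support stable effects (nor survive the variance filter)
    eligible <- which(prev >= min(common_range))
    if (length(eligible) < n_informative) {
      eligible <- order(prev, decreasing = TRUE)[seq_len(n_informative)]
    }
    list(prev, sort(sample(eligible, n_informative)))
  })
  world$effect_sizes <- if (n_informative > 1) {
    seq(effect_min, effect_max, length.out = n_informative)
  } else effect_max
  class(world) <- "synthetic_world"
  world
}

bit_names <- function(world) sprintf("bit_%04d", seq_len(world$n_bits))

#' Synthetic schema for a world's abstract bits
#'
#' Lets synthetic fingerprint tables flow through the same schema-aware
#' readers and aligners as real data.
#'
#' @param world a `synthetic_world`.
#' @return an `fp_schema` whose bits are the world's abstract bits
#'   (family `custom`, synthetic generator tags).
#' @export
world_schema <- function(world) {
  tab <- data.frame(bit_id = bit_names(world), family = "custom",
                    definition = paste0("synthetic:", bit_names(world)),
                    min_count = 1L, stringsAsFactors = FALSE)
  class(tab) <- c("fp_schema", "data.frame")
  tab
}

# Unique, parseable placeholder SMILES: heteroatom chains over {C,N,O}.
synthetic_smiles <- function(n) {
  alphabet <- c("C", "N", "O")
  len <- max(2L, ceiling(log(n, 3)) + 1L)
  vapply(seq_len(n) - 1L, function(i) {
    digits <- integer(len)
    for (k in seq_len(len)) { digits[k] <- i %% 3L; i <- i %/% 3L }
    paste0("C", paste(alphabet[digits + 1L], collapse = ""))
  }, character(1))
}

true_log_ie <- function(world, bits, polarity, pH, dataset_offset = 0,
                        noise = 0) {
  raw <- world$intercept0 +
    as.numeric(bits[, world$informative_bits, drop = FALSE] %*%
                 world$effect_sizes) +
    world$coef_polarity * (polarity - .polarity_index[["water"]]) +
    world$coef_pH * (pH - 7) +
    dataset_offset + noise
  pmin(pmax(raw, world$log_ie_range[1]), world$log_ie_range[2])
}

#' Generate a synthetic log IE training dataset
#'
#' Draws compounds with random fingerprints and measures each under one or
#' more eluent conditions spread over the world's instrument datasets,
#' producing a training table plus the ground-truth record needed for
#' parameter-recovery tests.
#'
#' @param world a [synthetic_world()].
#' @return list of class `ie_dataset` with `points` (data.frame:
#'   `compound_id`, `smiles`, `log_ie`, `organic_modifier`,
#'   `organic_fraction`, `aqueous_pH`, `dataset_id`), `fingerprints`
#'   (compounds x bits 0/1 matrix) and `truth` (the world plus per-dataset
#'   offsets and the noiseless log IE of every datapoint).
#' @export
generate_ie_dataset <- function(world) {
  with_seed(world$seed, {
    cmp <- sprintf("CMP%05d", seq_len(world$n_compounds))
    bits <- matrix(rbinom(world$n_compounds * world$n_bits, 1,
                          rep(world$bit_prevalence,
                              each = world$n_compounds)),
                   nrow = world$n_compounds,
                   dimnames = list(cmp, bit_names(world)))
    # every compound measured at least once; remaining datapoints spread
    # randomly, emulating compounds recurring across instrument datasets
    extra <- world$n_datapoints - world$n_compounds
    stopifnot(extra >= 0)
    counts <- rep(1L, world$n_compounds) +
      tabulate(sample.int(world$n_compounds, extra, replace = TRUE),
               world$n_compounds)
    idx <- rep(seq_len(world$n_compounds), counts)
    n <- length(idx)
    ds <- sample.int(world$n_datasets, n, replace = TRUE)
    ds_offset <- rnorm(world$n_datasets, 0, world$dataset_offset_sd)
    ds_modifier <- sample(supported_modifiers(), world$n_datasets,
                          replace = TRUE)
    ds_pH <- sample(c(2.7, 3.0, 7.0, 10.0), world$n_datasets, replace = TRUE)
    frac <- round(runif(n, 0.05, 0.95), 3)
    el <- compute_eluent_descriptors_vec(ds_modifier[ds], frac, ds_pH[ds])
    noiseless <- true_log_ie(world, bits[idx, , drop = FALSE],
                             el$polarity_index, el$aqueous_pH,
                             ds_offset[ds])
    log_ie <- true_log_ie(world, bits[idx, , drop = FALSE],
                          el$polarity_index, el$aqueous_pH,
                          ds_offset[ds], rnorm(n, 0, world$sigma))
    points <- data.frame(
      compound_id = cmp[idx],
      smiles = synthetic_smiles(world$n_compounds)[idx],
      log_ie = log_ie,
      organic_modifier = ds_modifier[ds],
      organic_fraction = frac,
      aqueous_pH = ds_pH[ds],
      dataset_id = sprintf("DS%02d", ds))
    out <- list(points = points, fingerprints = bits,
                truth = list(world = world, dataset_offsets = ds_offset,
                             noiseless_log_ie = noiseless))
    class(out) <- "ie_dataset"
    out
  })
}

# per-row modifiers require splitting the interpolation by modifier
compute_eluent_descriptors_vec <- function(modifier, fraction, pH) {
  out <- data.frame(organic_fraction = fraction, aqueous_pH = pH,
                    polarity_index = NA_real_, surface_tension = NA_real_,
                    viscosity = NA_real_)
  for (m in unique(modifier)) {
    i <- modifier == m
    out[i, ] <- compute_eluent_descriptors(m, fraction[i], pH[i])
  }
  out
}

#' Generate a synthetic quantification campaign
#'
#' Emulates a validation experiment: fresh compounds are split into a
#' calibration mix (measured response factors with log-normal scatter) and
#' a suspect set (peak areas = realized RF x true concentration) eluting
#' along a gradient. MS2-style fingerprint probabilities for the suspects
#' are produced by corrupting the true bits (blur toward 0.5, random
#' flips); at zero corruption and zero calibration noise the downstream
#' pipeline must recover the true concentrations exactly.
#'
#' @param world a [synthetic_world()].
#' @param seed_offset lets several campaigns be drawn from one world.
#' @return list of class `quant_campaign`: `calibrants` (compound_id,
#'   smiles, log_ie_true, rf_measured), `suspects` (feature_id,
#'   retention_time, peak_area, smiles, ion_ok), `ms2_probabilities`
#'   (suspects x bits), `fingerprints_true` (all campaign compounds x
#'   bits), `eluent` (gradient specification) and `truth` (true
#'   concentrations, log IE, RFs and the calibration line).
#' @export
generate_quant_campaign <- function(world, seed_offset = 1000L) {
  with_seed(world$seed + seed_offset, {
    n_tot <- world$n_calibrants + world$n_suspects
    ids <- sprintf("VAL%03d", seq_len(n_tot))
    bits <- matrix(rbinom(n_tot * world$n_bits, 1,
                          rep(world$bit_prevalence, each = n_tot)),
                   nrow = n_tot, dimnames = list(ids, bit_names(world)))
    gradient <- data.frame(time = c(0, 20), fraction = c(0.05, 0.95))
    eluent <- list(gradient_program = gradient,
                   organic_modifier = "methanol", aqueous_pH = 3.0,
                   column_dead_time = 0)
    rt <- round(runif(n_tot, 1, 19), 2)
    frac <- organic_fraction_at(gradient, rt)
    el <- compute_eluent_descriptors(eluent$organic_modifier, frac,
                                     eluent$aqueous_pH)
    log_ie <- true_log_ie(world, bits, el$polarity_index, el$aqueous_pH)
    rf_true <- 10^(world$cal_slope * log_ie + world$cal_intercept)
    rf_real <- rf_true * 10^rnorm(n_tot, 0, world$sigma_cal)
    i_cal <- seq_len(world$n_calibrants)
    i_sus <- world$n_calibrants + seq_len(world$n_suspects)
    smiles <- synthetic_smiles(n_tot)
    conc <- 10^runif(world$n_suspects, log10(world$conc_range[1]),
                     log10(world$conc_range[2]))
    prob <- bits[i_sus, , drop = FALSE] * (1 - world$blur) + 0.5 * world$blur
    do_flip <- matrix(rbinom(length(prob), 1, world$flip) == 1,
                      nrow = nrow(prob))
    prob[do_flip] <- 1 - prob[do_flip]
    out <- list(
      calibrants = data.frame(compound_id = ids[i_cal],
                              smiles = smiles[i_cal],
                              log_ie_true = log_ie[i_cal],
                              rf_measured = rf_real[i_cal]),
      suspects = data.frame(feature_id = ids[i_sus],
                            retention_time = rt[i_sus],
                            peak_area = rf_real[i_sus] * conc,
                            smiles = smiles[i_sus],
                            ion_ok = TRUE),
      ms2_probabilities = prob,
      fingerprints_true = bits,
      eluent = eluent,
      truth = list(conc_true = setNames(conc, ids[i_sus]),
                   log_ie_true = setNames(log_ie, ids),
                   rf_true = setNames(rf_true, ids),
                   rf_realized = setNames(rf_real, ids),
                   cal_slope = world$cal_slope,
                   cal_intercept = world$cal_intercept))
    class(out) <- "quant_campaign"
    out
  })
}

#' Parameter-recovery report
#'
#' Compares pipeline outputs against a campaign's ground truth: the
#' fitted calibration line, the median concentration fold error, and
#' (optionally) whether the world's informative bits rank highly in the
#' model's feature importances. Failed recoveries are reported, not
#' raised.
#'
#' @param world the [synthetic_world()] the data came from.
#' @param campaign the [generate_quant_campaign()] output.
#' @param calibration the fitted `calibration_model`.
#' @param quant a [quantify_suspects()] result.
#' @param importance optional [feature_importance()] table.
#' @param tol_slope,tol_intercept,tol_median_fold,top_k tolerances.
#' @return data.frame with columns `quantity`, `true`, `estimated`,
#'   `tolerance`, `pass`.
#' @export
parameter_recovery_report <- function(world, campaign, calibration, quant,
                                      importance = NULL,
                                      tol_slope = 0.15, tol_intercept = 0.5,
                                      tol_median_fold = 3, top_k = 15) {
  conc_true <- campaign$truth$conc_true[quant$feature_id]
  med_fold <- median(fold_error(quant$conc_pred_M, conc_true))
  rows <- list(
    data.frame(quantity = "cal_slope", true = world$cal_slope,
               estimated = calibration$slope, tolerance = tol_slope,
               pass = abs(calibration$slope - world$cal_slope) <= tol_slope),
    data.frame(quantity = "cal_intercept", true = world$cal_intercept,
               estimated = calibration$intercept, tolerance = tol_intercept,
               pass = abs(calibration$intercept - world$cal_intercept) <=
                 tol_intercept),
    data.frame(quantity = "median_conc_fold_error", true = 1,
               estimated = med_fold, tolerance = tol_median_fold,
               pass = med_fold <= tol_median_fold))
  if (!is.null(importance)) {
    top <- utils::head(importance$feature, top_k)
    hits <- sum(bit_names(world)[world$informative_bits] %in% top)
    rows <- c(rows, list(data.frame(
      quantity = "informative_bits_in_top_importances",
      true = world$n_informative, estimated = hits, tolerance = 0,
      pass = hits == world$n_informative)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
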