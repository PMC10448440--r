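# Shared fixtures: small synthetic worlds and a compact hyperparameter
# grid so model-fitting tests stay fast.

tiny_grid <- function() {
  data.frame(nrounds = 150, max_depth = 4, eta = 0.15, subsample = 0.75,
             colsample_bytree = 0.8, min_child_weight = 1)
}

tiny_world <- function(seed = 1, ...) {
  # uniform bit prevalence: unit tests want every planted effect learnable
  # (the heterogeneous default would push bits into the rare pool that the
  # near-zero-variance filter rightly removes)
  args <- utils::modifyList(
    list(seed = seed, n_compounds = 60, n_datapoints = 150,
         n_bits = 40, n_datasets = 3, bit_prevalence = 0.3),
    list(...))
  do.call(synthetic_world, args)
}

# noiseless generative chain end to end
exact_world <- function(seed = 1, ...) {
  tiny_world(seed = seed, sigma = 0, sigma_cal = 0, dataset_offset_sd = 0,
             blur = 0, flip = 0, ...)
}

# a feature matrix with known structure for preprocessing tests
random_matrix <- function(n = 100, p = 20, seed = 1, missing = 0) {
  set.seed(seed)
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("r%03d", 1:n), sprintf("c%02d", 1:p)))
  if (missing > 0) m[sample(length(m), missing)] <- NA
  m
}
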