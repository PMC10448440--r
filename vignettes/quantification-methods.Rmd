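---
title: "Standard-free quantification of LC-HRMS features: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard-free quantification of LC-HRMS features: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iequant)
```

# The problem

In electrospray ionization, the response factor (RF) of a chemical — the
slope of its peak-area-vs-concentration calibration line — spans orders
of magnitude across chemicals measured under identical conditions. A
feature's intensity therefore says almost nothing about its
concentration unless its RF is known, and for the unidentified majority
of nontarget LC-HRMS features no standard exists to measure one.
`iequant` estimates concentrations anyway, in three stages: predict each
feature's ionization efficiency from structural information, convert it
to an instrument-specific RF through a small calibrant set measured in
the same run, and divide the integrated area by the predicted RF.

# The ionization efficiency model

## Features

The regressor's inputs are a structural fingerprint concatenated with
five eluent descriptors.

**Fingerprints.** The bundled schema (`build_default_schema()`, 542
bits) unites five families: OpenBabel's MACCS (166) and FP3 (55) key
sets, referenced by generator tag; a curated functional-group SMARTS set
(`substructure`); count, ring and bonded-atom-pair keys in the style of
the PubChem CACTVS sections (`pubchem_like`, where a bit fires when its
pattern matches at least `min_count` times); and ring-system /
pharmacophore motifs (`klekota_roth`). The schema is a plain definitions
table shipped with the package, so every bit's semantics are
inspectable, and its order travels with any trained model. The schema is
deliberately pluggable: externally computed fingerprint tables (any bit
vocabulary, declared via `read_fingerprint_schema()`) flow through the
same readers and aligners, so a model trained on a different toolkit's
fingerprint set can be reproduced bit-exactly by supplying its tables.

Structure-derived vectors are binary. MS²-derived vectors are per-bit
probabilities in [0, 1] from an external predictor, and they are used
*as is* — no binarization at 0.5. This preserves the predictor's
uncertainty; users who prefer hard calls can binarize upstream. To make
the pass-through meaningful, the boosted trees are grown with exact
(midpoint) split thresholds: a bit trained on {0, 1} splits at 0.5, so a
0.9 probability follows the presence branch. Histogram-binned training
would instead record the split at the bin edge (value 1), sending every
fractional probability down the absence branch — an easy-to-miss failure
mode of probability pass-through with default tree settings.

Salts and mixtures reduce to the largest covalent fragment before
matching, and SMILES are canonicalized (OpenBabel) so representation
variants of one molecule give identical vectors.

**Eluent descriptors.** Ionization efficiency depends strongly on the
mobile phase at the elution point. From the modifier type (methanol or
acetonitrile), organic volume fraction and aqueous-phase pH, the package
derives the Snyder polarity index (linear mixing of pure-component
values: water 10.2, methanol 5.1, acetonitrile 5.8), surface tension and
viscosity (interpolated on bundled literature curves for the binary
mixtures; viscosity is genuinely non-monotone, peaking near 40 %
methanol, so a tabulated curve replaces any linear rule). `aqueous_pH`
is the pH of the aqueous component before mixing, not the apparent
mixture pH. Gradient runs resolve composition at
`retention_time - column_dead_time` by linear interpolation between
program breakpoints, clamped at the ends; the dead time defaults to 0 so
gradient-delay correction is an explicit opt-in.

## Preprocessing cascade

Training matrices pass three filters in a fixed order, then the retained
set and the imputation policy are frozen into a manifest:

1. **Sparse columns**: more than 10 missing values ⇒ removed (exactly 10
   is kept). Missing values surviving this stage are imputed — 0 for
   binary bits, the column median for continuous descriptors — because
   the later stages and the booster need a defined policy; the values
   are recorded in the manifest.
2. **Near-zero variance**: the canonical two-condition rule with a
   frequency cutoff of 80/20 and a percent-unique cutoff of 10. The
   second condition is vacuous for binary bits (their percent-unique is
   always tiny), so for fingerprints this reduces to removing bits with
   prevalence below ~20 % or above ~80 %.
3. **Pairwise correlation**: repeatedly find the pair with the largest
   |Pearson r| above 0.75 and drop the member with the larger mean
   absolute correlation against all remaining columns; ties keep the
   earlier column, making the cascade deterministic up to column order.
   The eluent descriptors are exempt only at the point where a removal
   would eliminate the last one (logged when it happens) — they carry
   the mobile-phase signal the model is built around, and the polarity
   index is perfectly collinear with the organic fraction by
   construction, so unprotected filtering can strip the whole block in
   single-modifier designs.

Prediction-time inputs are projected through the manifest verbatim —
nothing is re-fitted — and a missing retained feature is an error, not
an imputation.

## Training and validation

Splitting is by compound, never by datapoint: the same chemical measured
under several eluent conditions must not straddle the train/test
boundary, or held-out error collapses into memorization. Canonical
SMILES serve as the compound key. Hyperparameters are grid-searched
(defaults: 150–400 rounds, depth 3–6, learning rate 0.05–0.2) with
bootstrap resampling — five bootstrap resamples, each scored on its
out-of-bag points; plain k-fold CV is available as an option and the
scheme used is recorded in the model's diagnostics. The winning
configuration is refit on all training points. Single-threaded exact
training makes every run bit-reproducible for a fixed seed.

Two validation probes ship with the model: **y-randomization** (permute
training labels, refit with the selected hyperparameters, compare
train/test RMSE and R² against the baseline — a real model must beat all
its permuted counterparts) and **feature importance** (ensemble gain
normalized to percentages, plus SHAP-style signed contributions averaged
over a background set). For *recovery* checks — "does every planted
signal bit rank highly?" — the SHAP magnitude ranking is the one to use:
gain systematically under-ranks weak binary effects next to continuous
descriptors, which offer many more split points and soak up gain even
when their marginal contribution is modest.

# Calibration transfer and quantification

Predicted log IE lives on a unified, instrument-agnostic scale. A set of
calibrants (warn below 5; a realistic campaign uses a few dozen spanning
several IE decades) with measured RFs anchors it per run:

$$\log_{10} \mathrm{RF} = a\,\log_{10}\mathrm{IE}_{pred} + b$$

fit by OLS, with R², residual SE (log units) and the slope p-value as
diagnostics. The forward direction — RF regressed on predicted IE — is
chosen because prediction flows that way at quantification time. Then
for every suspect: RF = 10^(a·logIE + b), c = area / RF. Two structural
invariants follow and are tested: multiplying all areas (calibrant RFs
and suspect areas) by any constant leaves concentrations unchanged, and
with a positive slope a higher predicted IE at equal area means a lower
concentration.

Features flagged as neither protonated nor permanently positively
charged are excluded (positive-mode IE training data contains only such
ions); the flag is a declared column, because adduct assignment belongs
upstream. Suspects that double as calibrants are flagged rather than
dropped. Unresolvable suspects (no SMILES, no fingerprint row, parse
failure) are skipped with a logged reason — a campaign should not die on
one bad row.

# Evaluation metrics

The per-pair fold error is $10^{|\log_{10} p - \log_{10} t|}$ —
symmetric, scale-invariant, ≥ 1; 0.55 log units ≙ 3.5×, 0.80 ≙ 6.3×. The
summary battery reports RMSE on the log scale with its fold equivalent,
R² as the squared Pearson correlation of the log values, arithmetic and
geometric mean folds and the 25/50/75/90/100 % quantiles (type-7 linear
interpolation, the standard estimator). Group summaries aggregate
hierarchically — geometric mean per unique compound first, then the
distribution across compounds within each class — and flag groups with
fewer than three unique members. The overprediction rate (fraction of
pairs with prediction above truth) is a bias check: unbiased noise gives
one half.

# The synthetic world

The generator exists so that every stage has testable ground truth
offline. Its generative model:

* **Fingerprints**: independent Bernoulli bits with a heterogeneous
  prevalence profile — by default 75 % of bits are rare (prevalence
  0.005–0.15) and the rest common (0.2–0.6). This mirrors real
  substructure fingerprints, where most keys rarely fire, and it
  exercises the preprocessing the way real data does: the near-zero
  variance filter removes the rare majority, leaving on the order of a
  hundred-odd informative candidates out of 542, comparable to the
  1263 → 117 reduction the cascade is designed around. Signal sits on 10
  common bits with effect sizes evenly spaced over 0.3–1.5 log units.
* **Labels**: log IE = baseline + Σ effects·bits + eluent term
  (coefficients on polarity index and aqueous pH) + per-dataset
  instrument offset + N(0, σ), clamped to [−1.5, 7.5]. Defaults: σ =
  0.3; dataset offsets with SD 0.1 (the emulated table is already on a
  *unified* IE scale, so offsets represent residual calibration-transfer
  error, not raw instrument spread); baseline −1.6, which centers the
  label distribution mid-range once the expected bit and eluent
  contributions (≈ +3.6 and ≈ +1.05) are added, keeping clamping below
  1 %. The default dimensions mirror the scale of the unified training
  resource the model targets: 1191 compounds, 6049 datapoints (about 5
  eluent conditions per compound), 13 instrument datasets.
* **Campaign**: 36 calibrants and 39 suspects elute along a 20-minute
  5→95 % gradient; true RFs follow log RF = 0.9·log IE + 2.0 with
  log-normal scatter σ_cal = 0.2, suspect areas are realized RF × true
  concentration (log-uniform over 5 nM–5 µM), and MS²-style
  probabilities corrupt the true bits by shrinking toward 0.5 (blur 0.1)
  plus random flips (rate 0.02). The corruption model is invented — no
  public error model of MS² fingerprint predictors exists — and both
  rates are configurable; with every noise source at zero the pipeline
  must return the true concentrations to machine precision, which is
  tested.

What the generator does *not* emulate: correlation structure between
bits (real substructure keys are heavily nested), out-of-domain
chemistry, retention-time/structure coupling, matrix effects, and any
mechanistic spectra. Passing tests on this world therefore demonstrate
the correctness of the pipeline's plumbing and statistics — recovery of
planted parameters under known noise — not field performance on real
extracts, which is known to be several-fold worse (typical median fold
errors on real validation sets are around 4×, versus under 2× here).

# Numerical choices and degenerate inputs

* Resampling, splitting and generation isolate their RNG state and
  derive entirely from explicit seeds; identical configuration ⇒
  identical outputs, byte-for-byte in the CLI.
* Grid-search ties resolve to the earlier grid row; correlation-filter
  ties keep the earlier column.
* A two-point calibration is allowed (exact fit, residual SE defined as
  0); one calibrant is an error.
* Fold errors on the linear scale require strictly positive values;
  zeros and missing pairs are domain errors rather than silent drops.
* Constant-label training degenerates gracefully (the model predicts
  the constant).
* Problem sizes in the test suite: unit fixtures use 60-compound worlds
  with uniform bit prevalence (every planted effect learnable by
  construction); the deeper recovery checks use a 500-compound world at
  the study's datapoints-per-compound ratio, which trains in about a
  minute single-threaded.

# Known limitations

* The bundled 542-bit schema emulates the five named fingerprint
  families but is not bit-for-bit identical to any external toolkit's
  1263-bit union; exact replication requires supplying the original
  fingerprint tables, which the readers support.
* Negative-mode electrospray, matrix-effect correction and retention
  modeling are out of scope.
* The MS² corruption model is a stand-in; calibrating it against a real
  predictor's error profile would make campaign-level error estimates
  transferable.
* Viscosity/surface-tension curves are tabulated at 25 °C for binary
  mixtures only; buffers and additives shift them.
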