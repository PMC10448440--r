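#' Eluent descriptors of the mobile phase
#'
#' Electrospray ionization efficiency depends strongly on the mobile phase a
#' compound elutes in. Five descriptors summarise it: the organic modifier
#' fraction, the pH of the aqueous component, and three derived physical
#' properties of the binary mixture (Snyder polarity index, surface tension,
#' viscosity). The derived properties come from a bundled constants table of
#' literature binary-mixture curves; the polarity index mixes linearly in the
#' volume fraction while surface tension and viscosity are interpolated on
#' the tabulated curves (mixture viscosity is non-monotone, passing through
#' a maximum near 40 % methanol).
#'
#' @name eluent
NULL

.eluent_env <- new.env(parent = emptyenv())

eluent_constants <- function() {
  if (is.null(.eluent_env$tab)) {
    path <- system.file("extdata", "eluent_properties.tsv", package = "iequant")
    .eluent_env$tab <- read.delim(path, comment.char = "#",
                                  stringsAsFactors = FALSE)
  }
  .eluent_env$tab
}

# Snyder polarity indices of the pure components.
.polarity_index <- c(water = 10.2, methanol = 5.1, acetonitrile = 5.8)

supported_modifiers <- function() c("methanol", "acetonitrile")

#' Organic fraction at a retention time under a gradient program
#'
#' Resolves a gradient program to the mobile-phase composition a feature
#' eluted in. The program is a two-column object of `(time, fraction)`
#' breakpoints; composition is linearly interpolated at
#' `retention_time - column_dead_time` and clamped to the first/last
#' breakpoint outside the programmed range. A single-row program encodes an
#' isocratic run.
#'
#' @param gradient_program data.frame or matrix with columns `time`
#'   (minutes, strictly increasing) and `fraction` (organic volume
#'   fraction in \[0, 1\]).
#' @param retention_time retention time in minutes, `>= 0`.
#' @param column_dead_time delay subtracted from the retention time before
#'   lookup (minutes, default 0 -- gradient-delay correction is opt-in).
#' @return organic volume fraction in \[0, 1\].
#' @export
#' @examples
#' prog <- data.frame(time = c(0, 10), fraction = c(0.1, 0.9))
#' organic_fraction_at(prog, 5)   # 0.5, midpoint of the ramp
#' organic_fraction_at(prog, 25)  # 0.9, clamped past the last breakpoint
organic_fraction_at <- function(gradient_program, retention_time,
                                column_dead_time = 0) {
  prog <- as.data.frame(gradient_program)
  if (!all(c("time", "fraction") %in% names(prog))) {
    names(prog)[1:2] <- c("time", "fraction")
  }
  if (nrow(prog) == 0) ie_stop("iequant_domain_error", "empty gradient program")
  if (any(retention_time < 0) || column_dead_time < 0) {
    ie_stop("iequant_domain_error",
            "retention_time and column_dead_time must be non-negative")
  }
  if (any(prog$fraction < 0 | prog$fraction > 1)) {
    ie_stop("iequant_domain_error", "gradient fractions must lie in [0, 1]")
  }
  if (nrow(prog) > 1 && any(diff(prog$time) <= 0)) {
    ie_stop("iequant_domain_error", "gradient times must be strictly increasing")
  }
  t_eff <- retention_time - column_dead_time
  if (nrow(prog) == 1) return(rep(prog$fraction, length.out = length(t_eff)))
  approx(prog$time, prog$fraction, xout = t_eff, rule = 2)$y
}

#' Compute the five eluent descriptors
#'
#' @param organic_modifier `"methanol"` or `"acetonitrile"`.
#' @param organic_fraction organic volume fraction in \[0, 1\] (vectorised).
#' @param aqueous_pH pH of the aqueous component before mixing.
#' @return data.frame with one row per fraction and columns
#'   `organic_fraction`, `aqueous_pH`, `polarity_index`,
#'   `surface_tension` (mN/m) and `viscosity` (mPa s).
#' @export
#' @examples
#' compute_eluent_descriptors("methanol", c(0, 0.5, 1), aqueous_pH = 7)
compute_eluent_descriptors <- function(organic_modifier, organic_fraction,
                                       aqueous_pH) {
  organic_modifier <- match_modifier(organic_modifier)
  if (any(organic_fraction < 0 | organic_fraction > 1)) {
    ie_stop("iequant_domain_error", "organic_fraction must lie in [0, 1]")
  }
  tab <- eluent_constants()
  tab <- tab[tab$modifier == organic_modifier, ]
  st <- approx(tab$fraction, tab$surface_tension, xout = organic_fraction)$y
  vi <- approx(tab$fraction, tab$viscosity, xout = organic_fraction)$y
  pi_ <- (1 - organic_fraction) * .polarity_index[["water"]] +
    organic_fraction * .polarity_index[[organic_modifier]]
  data.frame(organic_fraction = organic_fraction,
             aqueous_pH = aqueous_pH,
             polarity_index = pi_,
             surface_tension = st,
             viscosity = vi)
}

match_modifier <- function(x) {
  x <- tolower(as.character(x))
  ok <- x %in% supported_modifiers()
  if (!all(ok)) {
    ie_stop("iequant_enum_error", "unsupported organic modifier: ",
            paste(unique(x[!ok]), collapse = ", "),
            " (supported: ", paste(supported_modifiers(), collapse = ", "), ")")
  }
  x
}

# Names of the eluent descriptor columns as they appear in feature matrices.
eluent_feature_names <- function() {
  c("organic_fraction", "aqueous_pH", "polarity_index",
    "surface_tension", "viscosity")
}
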