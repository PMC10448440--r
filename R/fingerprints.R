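#' Fingerprint schema
#'
#' The model consumes a fixed, ordered set of structural fingerprint bits.
#' The bundled default schema unites five families: MACCS and FP3 keys
#' (delegated to OpenBabel's built-in pattern sets, referenced by generator
#' tag), a curated functional-group set (`substructure`), count/ring/bonded
#' atom-pair keys in the style of the PubChem CACTVS sections
#' (`pubchem_like`), and ring-system / pharmacophore motifs
#' (`klekota_roth`). Each SMARTS-defined bit fires when the pattern matches
#' at least `min_count` times. The schema is persisted as a tabular
#' definitions file so bit semantics stay inspectable, and the bit order is
#' part of any trained model.
#'
#' @return `build_default_schema()` returns the bundled schema, a
#'   data.frame of class `fp_schema` with columns `bit_id`, `family`,
#'   `definition` and `min_count`.
#' @export
#' @examples
#' sch <- build_default_schema()
#' nrow(sch)           # > 500 bits
#' table(sch$family)
build_default_schema <- function() {
  path <- system.file("extdata", "fingerprint_schema.tsv", package = "iequant")
  read_fingerprint_schema(path)
}

#' @rdname build_default_schema
#' @param path path to a tab-separated definitions file with columns
#'   `bit_id`, `family`, `definition` and optionally `min_count`.
#' @export
read_fingerprint_schema <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("bit_id", "family", "definition")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    ie_stop("iequant_schema_error", "schema file lacks column(s): ",
            paste(missing, collapse = ", "))
  }
  if (is.null(tab$min_count)) tab$min_count <- 1L
  if (anyDuplicated(tab$bit_id)) {
    ie_stop("iequant_schema_error", "duplicated bit_id in schema")
  }
  if (any(!nzchar(tab$definition))) {
    ie_stop("iequant_schema_error", "empty bit definition in schema")
  }
  class(tab) <- c("fp_schema", "data.frame")
  tab
}

#' @rdname build_default_schema
#' @param schema an `fp_schema`.
#' @export
write_fingerprint_schema <- function(schema, path) {
  write.table(as.data.frame(schema), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## ---- SMILES handling ---------------------------------------------------

#' Canonicalize SMILES
#'
#' Canonicalizes through OpenBabel after reducing salts/mixtures to their
#' largest covalent fragment (fragment with the most heavy atoms; ties keep
#' the first). Unparseable strings yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  # fast path: one OpenBabel call for the whole batch; OpenBabel stops at
  # the first unparseable line, so a full-length result means all parsed
  if (length(smiles) > 1 && !anyNA(smiles) && all(nzchar(smiles)) &&
      !any(grepl("[\n.]", smiles))) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat(
        "SMI", "CAN", paste(smiles, collapse = "\n"))),
      error = function(e) "")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    if (length(lines) == length(smiles) && all(nzchar(lines))) {
      return(sub("[\t ].*$", "", lines))
    }
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    s <- largest_fragment(s)
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) "")
    out <- sub("[\t\n ].*$", "", out)
    if (!nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

largest_fragment <- function(s) {
  frags <- strsplit(s, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (length(frags) <= 1) return(s)
  # heavy-atom count proxy: letters minus explicit hydrogens
  heavy <- vapply(frags, function(f) {
    nchar(gsub("[^A-Za-z]", "", f)) - lengths(regmatches(f, gregexpr("H", f)))
  }, numeric(1))
  frags[[which.max(heavy)]]
}

ob_mols <- function(smiles) {
  ChemmineOB::forEachMol("SMILES", paste(smiles, collapse = "\n"), identity)
}

#' Compute fingerprints from SMILES
#'
#' Binary fingerprint vector(s) for one or more molecules under a schema.
#' SMILES are canonicalized first (so stereo-stripped or non-canonical
#' duplicates of one molecule give identical vectors) and salts reduced to
#' the largest fragment. A bit defined by SMARTS is 1 iff the pattern
#' matches at least its `min_count` times; MACCS/FP3 generator bits come
#' from OpenBabel's fingerprint implementation.
#'
#' @param smiles character vector of SMILES.
#' @param schema an `fp_schema`; defaults to [build_default_schema()].
#' @return `fingerprint_from_smiles()`: a named 0/1 vector aligned to the
#'   schema, with attribute `provenance = "structure"`.
#'   `fingerprint_matrix_from_smiles()`: a 0/1 matrix, one row per molecule
#'   (rownames = input SMILES), one column per schema bit.
#' @export
#' @examples
#' sch <- build_default_schema()
#' v <- fingerprint_from_smiles("c1ccccc1", sch)
#' v["substructure:arene"]          # 1
#' v["substructure:primary_amine"]  # 0
fingerprint_from_smiles <- function(smiles, schema = build_default_schema()) {
  stopifnot(length(smiles) == 1)
  m <- fingerprint_matrix_from_smiles(smiles, schema)
  v <- m[1, ]
  attr(v, "provenance") <- "structure"
  v
}

#' @rdname fingerprint_from_smiles
#' @export
fingerprint_matrix_from_smiles <- function(smiles,
                                           schema = build_default_schema()) {
  can <- canonicalize_smiles(smiles)
  if (anyNA(can)) {
    ie_stop("iequant_parse_error", "unparseable SMILES: ",
            paste(smiles[is.na(can)], collapse = ", "))
  }
  mols <- ob_mols(can)
  n <- length(smiles)
  out <- matrix(0, nrow = n, ncol = nrow(schema),
                dimnames = list(smiles, schema$bit_id))
  gen <- grepl("^openbabel:", schema$definition)
  if (any(gen)) {
    for (fam in unique(sub("^openbabel:([^:]+):.*$", "\\1",
                           schema$definition[gen]))) {
      fam_rows <- which(gen & grepl(paste0("^openbabel:", fam, ":"),
                                    schema$definition))
      fp <- ChemmineOB::fingerprint_OB(mols, fam)
      if (is.null(dim(fp))) fp <- matrix(fp, nrow = 1)
      idx <- as.integer(sub(".*:", "", schema$definition[fam_rows]))
      out[, fam_rows] <- (fp[, idx, drop = FALSE] != 0) * 1
    }
  }
  for (j in which(!gen)) {
    cnt <- ChemmineOB::smartsSearch_OB(mols, schema$definition[j])
    out[, j] <- (cnt >= schema$min_count[j]) * 1
  }
  out
}

#' Align a fingerprint vector to a model's retained features
#'
#' Trained models retain a filtered subset of the full schema. This projects
#' a (super)set of feature values onto exactly the model's features, in
#' model order; input column order is irrelevant.
#'
#' @param vector named numeric vector, or a matrix with named columns, whose
#'   names form a superset of `model_features`.
#' @param model_features character vector of retained feature ids, in model
#'   order (also accepts an `fp_schema`, using its `bit_id` column).
#' @return the values for exactly `model_features`, in that order.
#' @export
align_to_model_features <- function(vector, model_features) {
  if (inherits(model_features, "fp_schema")) {
    model_features <- model_features$bit_id
  }
  nm <- if (is.matrix(vector)) colnames(vector) else names(vector)
  missing <- setdiff(model_features, nm)
  if (length(missing)) {
    ie_stop("iequant_missing_feature_error",
            "feature(s) absent from input: ",
            paste(utils::head(missing, 10), collapse = ", "),
            if (length(missing) > 10) sprintf(" (+%d more)", length(missing) - 10))
  }
  if (is.matrix(vector)) vector[, model_features, drop = FALSE]
  else vector[model_features]
}
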