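# Report dialects: which source columns hold each logical field, which
# modified-sequence grammar is used, and the tool-specific localization
# confidence default.

#' Logical fields of a long-format report
#'
#' Every dialect maps these logical fields to source column names:
#' `run`, `modified_sequence`, `protein_group`, `precursor_id`,
#' `fragment_id`, `intensity`, `q_value`, `localization`.
#'
#' @return Character vector of logical field names.
#' @export
long_report_fields <- function() {
  c("run", "modified_sequence", "protein_group", "precursor_id",
    "fragment_id", "intensity", "q_value", "localization")
}

# fragment_id may be absent (MS1-only export); localization may be absent
# (peptide-level reporting does not need it).
.optional_fields <- c("fragment_id", "localization")

#' Construct a report dialect
#'
#' A dialect describes how to read one tool's long-format export: the
#' column map from logical fields to source column names, the
#' modified-sequence grammar, and the tool's conventional site-localization
#' confidence threshold (0.75 for Spectronaut-style probabilities, 0.01 for
#' DIA-NN-style site confidence scores, the two being roughly equivalent
#' operating points).
#'
#' @param name Dialect name, `"spectronaut"` or `"diann"`.
#' @param column_map Named character vector mapping every logical field in
#'   [long_report_fields()] to a source column name.
#' @param mod_grammar Modified-sequence grammar: `"bracket"`
#'   (`S[Phospho (STY)]`) or `"unimod"` (`S(UniMod:21)`).
#' @param default_loc_threshold Default minimum localization confidence for
#'   class I site filtering, in `[0, 1]`.
#' @return An object of class `report_dialect`.
#' @seealso [dialect_spectronaut()], [dialect_diann()]
#' @export
dialect <- function(name, column_map, mod_grammar = c("bracket", "unimod"),
                    default_loc_threshold) {
  mod_grammar <- match.arg(mod_grammar)
  fields <- long_report_fields()
  missing_fields <- setdiff(fields, names(column_map))
  if (length(missing_fields) > 0L) {
    stop("column_map lacks logical field(s): ",
         paste(missing_fields, collapse = ", "))
  }
  stopifnot(is.numeric(default_loc_threshold),
            default_loc_threshold >= 0, default_loc_threshold <= 1)
  structure(
    list(name = name,
         column_map = column_map[fields],
         mod_grammar = mod_grammar,
         default_loc_threshold = default_loc_threshold),
    class = "report_dialect"
  )
}

#' Spectronaut fragment-level long-report dialect
#'
#' Defaults follow the Spectronaut fragment-level ("MS2 level") long export:
#' `R.FileName` for the run, `EG.ModifiedSequence` for the modified peptide,
#' `PG.ProteinGroups` for the protein group, `EG.PTMAssayProbability` for
#' site localization confidence, `F.FrgIon` / `F.PeakArea` for the fragment
#' ion and its intensity. Any column can be overridden for older or
#' customised export schemes.
#'
#' @param ... Named overrides for individual logical fields, e.g.
#'   `intensity = "F.NormalizedPeakArea"`.
#' @return A `report_dialect`.
#' @export
dialect_spectronaut <- function(...) {
  map <- c(run               = "R.FileName",
           modified_sequence = "EG.ModifiedSequence",
           protein_group     = "PG.ProteinGroups",
           precursor_id      = "EG.PrecursorId",
           fragment_id       = "F.FrgIon",
           intensity         = "F.PeakArea",
           q_value           = "EG.Qvalue",
           localization      = "EG.PTMAssayProbability")
  overrides <- c(...)
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(map))
    if (length(unknown) > 0L)
      stop("unknown logical field(s): ", paste(unknown, collapse = ", "))
    map[names(overrides)] <- overrides
  }
  dialect("spectronaut", map, "bracket", 0.75)
}

#' DIA-NN long-report dialect
#'
#' The column scheme written by [convert_diann_report()] (fragment
#' intensities unrolled into one row per fragment). The localization default
#' is 0.01 on the DIA-NN PTM site confidence scale.
#'
#' @param ... Named overrides for individual logical fields.
#' @return A `report_dialect`.
#' @export
dialect_diann <- function(...) {
  map <- c(run               = "Run",
           modified_sequence = "Modified.Sequence",
           protein_group     = "Protein.Group",
           precursor_id      = "Precursor.Id",
           fragment_id       = "Fragment.Id",
           intensity         = "Fragment.Intensity",
           q_value           = "Q.Value",
           localization      = "PTM.Site.Confidence")
  overrides <- c(...)
  if (length(overrides) > 0L) {
    unknown <- setdiff(names(overrides), names(map))
    if (length(unknown) > 0L)
      stop("unknown logical field(s): ", paste(unknown, collapse = ", "))
    map[names(overrides)] <- overrides
  }
  dialect("diann", map, "unimod", 0.01)
}

#' Resolve a dialect from a short tool tag
#'
#' @param tool `"sn"`/`"spectronaut"` or `"diann"`.
#' @return A `report_dialect`.
#' @export
resolve_dialect <- function(tool) {
  switch(tolower(tool),
         "sn" = ,
         "spectronaut" = dialect_spectronaut(),
         "diann" = dialect_diann(),
         stop("unknown tool '", tool, "' (expected 'sn' or 'diann')"))
}

#' @export
print.report_dialect <- function(x, ...) {
  cat("<report_dialect> ", x$name,
      " (grammar: ", x$mod_grammar,
      ", localization default: ", x$default_loc_threshold, ")\n", sep = "")
  for (f in names(x$column_map))
    cat(sprintf("  %-18s <- %s\n", f, x$column_map[[f]]))
  invisible(x)
}

# internal message helper; all pipeline logging funnels through here
pr_log <- function(...) {
  message("[phosphoreport] ", sprintf(...))
}
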