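# Long-format report input/output and DIA-NN main-report conversion.
#
# The in-memory long report is a data.table with one row per fragment (or
# precursor) observation per run, holding the logical fields of
# long_report_fields() plus the derived stripped_sequence and a `quantified`
# flag (FALSE for zero/absent intensity).

#' Read a long-format search report
#'
#' Reads a tab-separated long-format export (one row per fragment or
#' precursor observation per run) using a dialect's column map. Numeric
#' cells that are empty, `"NA"`, `"NaN"` or `"Filtered"` become missing;
#' row order is preserved.
#'
#' @param path Path to a TSV report.
#' @param dialect A `report_dialect` (see [dialect_spectronaut()],
#'   [dialect_diann()]).
#' @return data.table with columns `run_id`, `modified_sequence`,
#'   `stripped_sequence`, `protein_group` (";"-joined accessions),
#'   `precursor_id`, `fragment_id` (`NA` for MS1/precursor rows),
#'   `intensity`, `q_value`, `localization`, `quantified`.
#' @export
read_long_report <- function(path, dialect = dialect_spectronaut()) {
  stopifnot(inherits(dialect, "report_dialect"))
  if (!file.exists(path)) stop("report file not found: ", path)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           showProgress = FALSE)
  map <- dialect$column_map
  required <- setdiff(names(map), .optional_fields)
  absent <- map[required][!map[required] %in% names(raw)]
  if (length(absent) > 0L)
    stop("missing required column(s) for dialect '", dialect$name, "': ",
         paste(absent, collapse = ", "))
  get_col <- function(field) {
    src <- map[[field]]
    if (src %in% names(raw)) raw[[src]] else rep(NA_character_, nrow(raw))
  }
  num_col <- function(field) {
    x <- get_col(field)
    x[x %in% c("", "NA", "NaN", "Filtered")] <- NA_character_
    v <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & is.na(v))
    if (length(bad) > 0L)
      stop("non-numeric ", field, " value '", x[bad[1]], "' at row ", bad[1],
           " of ", path)
    v
  }
  modseq <- get_col("modified_sequence")
  rows <- data.table::data.table(
    run_id            = get_col("run"),
    modified_sequence = modseq,
    stripped_sequence = strip_modified_sequence(modseq, dialect$mod_grammar),
    protein_group     = get_col("protein_group"),
    precursor_id      = get_col("precursor_id"),
    fragment_id       = get_col("fragment_id"),
    intensity         = num_col("intensity"),
    q_value           = num_col("q_value"),
    localization      = num_col("localization")
  )
  rows[, "quantified" := is.finite(rows$intensity) & rows$intensity > 0]
  n_zero <- sum(!rows$quantified)
  pr_log("read %d rows from %s (%d zero/absent intensity)",
         nrow(rows), path, n_zero)
  rows[]
}

#' Write a long report in a dialect's column scheme
#'
#' Inverse of [read_long_report()]: logical fields are written under the
#' dialect's source column names, tab-separated, UTF-8, "." decimal point,
#' no quoting. Reading the file back reproduces all logical fields.
#'
#' @param rows Long-report data.table (see [read_long_report()]).
#' @param path Output path.
#' @param dialect A `report_dialect`.
#' @return `path`, invisibly.
#' @export
write_long_report <- function(rows, path, dialect = dialect_spectronaut()) {
  stopifnot(inherits(dialect, "report_dialect"))
  map <- dialect$column_map
  out <- data.table::data.table(
    a = rows$run_id, b = rows$modified_sequence, c = rows$protein_group,
    d = rows$precursor_id, e = rows$fragment_id,
    f = rows$intensity, g = rows$q_value, h = rows$localization)
  data.table::setnames(out, c(map[["run"]], map[["modified_sequence"]],
                              map[["protein_group"]], map[["precursor_id"]],
                              map[["fragment_id"]], map[["intensity"]],
                              map[["q_value"]], map[["localization"]]))
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "",
                     eol = "\n", scipen = 50L)
  invisible(path)
}

#' Default column map of the DIA-NN main report
#'
#' Source columns consumed by [convert_diann_report()], following the
#' DIA-NN 1.8 main-report convention. Override entries for other versions,
#' e.g. `fragment_quant = "Fragment.Quant.Corrected"`.
#'
#' @return Named character vector with entries `run`, `protein_ids`,
#'   `modified_sequence`, `precursor_id`, `q_value`, `localization`,
#'   `fragment_quant`.
#' @export
diann_main_columns <- function() {
  c(run               = "Run",
    protein_ids       = "Protein.Ids",
    modified_sequence = "Modified.Sequence",
    precursor_id      = "Precursor.Id",
    q_value           = "Q.Value",
    localization      = "PTM.Site.Confidence",
    fragment_quant    = "Fragment.Quant.Raw")
}

#' Convert a DIA-NN main report to the long fragment format
#'
#' Each precursor row of the DIA-NN main report packs per-fragment
#' intensities into a single semicolon-separated field. The converter
#' unrolls them into one row per fragment with positive intensity
#' (`fragment_id = "<precursor>#<slot>"` where slot is the ordinal in the
#' packed field; zero entries encode "not quantified" and are dropped), and
#' recomputes the protein group by locating the stripped sequence in the
#' supplied proteome (all matching accessions, sorted lexicographically) so
#' that isoform membership is explicit. Peptides absent from every proteome
#' entry are dropped and counted.
#'
#' @param diann_path Path to the DIA-NN main-report TSV.
#' @param prot The [proteome()] used for the search or library construction.
#' @param columns Source column map, see [diann_main_columns()].
#' @return Long-report data.table as from
#'   `read_long_report(..., dialect_diann())`, with attributes
#'   `n_unmapped_peptides` and `n_zero_fragments`.
#' @export
convert_diann_report <- function(diann_path, prot,
                                 columns = diann_main_columns()) {
  if (!inherits(prot, "proteome") || length(prot$entries) == 0L)
    stop("empty or invalid proteome")
  if (!file.exists(diann_path)) stop("report file not found: ", diann_path)
  raw <- data.table::fread(diann_path, sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           showProgress = FALSE)
  required <- c("run", "modified_sequence", "precursor_id", "q_value",
                "fragment_quant")
  absent <- columns[required][!columns[required] %in% names(raw)]
  if (length(absent) > 0L)
    stop("missing required DIA-NN column(s): ", paste(absent, collapse = ", "))
  num <- function(field) {
    if (!columns[[field]] %in% names(raw)) return(rep(NA_real_, nrow(raw)))
    x <- raw[[columns[[field]]]]
    x[x %in% c("", "NA", "NaN")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  modseq <- raw[[columns[["modified_sequence"]]]]
  stripped <- strip_modified_sequence(modseq, "unimod")
  qv <- num("q_value")
  loc <- num("localization")

  # protein group per unique stripped sequence, from the proteome
  uniq <- unique(stripped)
  groups <- vapply(uniq, function(s) {
    hits <- locate_peptide(s, prot)
    paste(sort(unique(hits$accession), method = "radix"), collapse = ";")
  }, character(1))
  group_of <- groups[stripped]
  unmapped <- !nzchar(group_of)
  n_unmapped <- length(unique(stripped[unmapped]))
  if (n_unmapped > 0L)
    pr_log("dropped %d peptide(s) (%d rows) not found in the proteome",
           n_unmapped, sum(unmapped))

  out_list <- vector("list", nrow(raw))
  n_zero <- 0L
  packed_all <- raw[[columns[["fragment_quant"]]]]
  prec_all <- raw[[columns[["precursor_id"]]]]
  run_all <- raw[[columns[["run"]]]]
  for (i in seq_len(nrow(raw))) {
    if (unmapped[i]) next
    entries <- strsplit(packed_all[i], ";", fixed = TRUE)[[1]]
    entries <- entries[nzchar(trimws(entries))]
    vals <- suppressWarnings(as.numeric(entries))
    if (anyNA(vals))
      stop("unparsable packed fragment field '", packed_all[i],
           "' at row ", i, " of ", diann_path)
    keep <- which(vals > 0)
    n_zero <- n_zero + sum(vals == 0)
    if (length(keep) == 0L) next
    out_list[[i]] <- data.table::data.table(
      run_id            = run_all[i],
      modified_sequence = modseq[i],
      stripped_sequence = stripped[i],
      protein_group     = group_of[i],
      precursor_id      = prec_all[i],
      fragment_id       = paste0(prec_all[i], "#", keep),
      intensity         = vals[keep],
      q_value           = qv[i],
      localization      = loc[i])
  }
  rows <- data.table::rbindlist(out_list)
  if (nrow(rows) == 0L)
    rows <- data.table::data.table(
      run_id = character(0), modified_sequence = character(0),
      stripped_sequence = character(0), protein_group = character(0),
      precursor_id = character(0), fragment_id = character(0),
      intensity = numeric(0), q_value = numeric(0), localization = numeric(0))
  rows[, "quantified" := is.finite(rows$intensity) & rows$intensity > 0]
  pr_log("converted %d precursor rows to %d fragment rows (%d zero entries dropped)",
         nrow(raw), nrow(rows), n_zero)
  data.table::setattr(rows, "n_unmapped_peptides", n_unmapped)
  data.table::setattr(rows, "n_zero_fragments", n_zero)
  rows[]
}

# render a numeric matrix cell for the wide report; "" encodes missing
.render_value <- function(x) {
  ifelse(is.na(x), "", sprintf("%.10g", x))
}

#' Write a wide-format quantification report
#'
#' One row per site/peptide key: the rendered key, its descriptive parts,
#' then one column per sample holding log2 abundance (empty cell =
#' missing). The quantification method is recorded on a `#` header line so
#' that [read_wide_report()] round-trips it.
#'
#' @param result A `quant_result` (see [quantify_keys()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wide_report <- function(result, path) {
  stopifnot(inherits(result, "quant_result"))
  if (length(result$keys) < 1L || length(result$sample_ids) < 1L)
    stop("result must have at least one key and one sample")
  tab <- data.table::as.data.table(list(key = result$keys))
  info <- result$key_info
  if (!is.null(info)) {
    for (cn in setdiff(names(info), "key")) tab[, (cn) := info[[cn]]]
  }
  tab[, "n_ions" := result$n_ions]
  mat <- result$log2_abundance
  for (s in result$sample_ids) tab[, (s) := .render_value(mat[, s])]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0("# method=", result$method), con, sep = "\n")
  writeLines(paste(names(tab), collapse = "\t"), con, sep = "\n")
  body <- do.call(paste, c(lapply(tab, function(col) {
    col <- as.character(col); col[is.na(col)] <- ""; col
  }), sep = "\t"))
  if (length(body) > 0L) writeLines(body, con, sep = "\n")
  invisible(path)
}

#' Read back a wide-format quantification report
#'
#' @param path Path written by [write_wide_report()].
#' @return List with `method`, `table` (character data.table exactly as
#'   rendered) and `log2_abundance` (numeric matrix keys x samples).
#' @export
read_wide_report <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L || !startsWith(lines[1], "# method="))
    stop("not a wide report: ", path)
  method <- sub("^# method=", "", lines[1])
  tab <- data.table::fread(text = lines[-1], sep = "\t", header = TRUE,
                           colClasses = "character", na.strings = NULL)
  meta_cols <- intersect(names(tab),
                         c("key", "protein_group", "positions", "multiplicity",
                           "sequence", "modifications", "n_ions"))
  sample_cols <- setdiff(names(tab), meta_cols)
  mat <- sapply(sample_cols, function(s) {
    v <- tab[[s]]
    v[v == ""] <- NA_character_
    as.numeric(v)
  })
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = nrow(tab),
                                       dimnames = list(NULL, sample_cols))
  rownames(mat) <- tab$key
  list(method = method, table = tab, log2_abundance = mat)
}
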