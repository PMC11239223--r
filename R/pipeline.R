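# End-to-end pipeline: normalize -> filter -> keys -> quantify.

#' Run the site- or peptide-level reporting pipeline
#'
#' The four processing steps in order: optional median normalization
#' ([normalize_median()]), class I confidence filtering
#' ([filter_confident()]; localization is enforced in site mode only),
#' identifier construction ([build_site_keys()] /
#' [build_peptide_key()]), and per-key quantification
#' ([quantify_keys()]).
#'
#' @param rows Long-report data.table from [read_long_report()] or
#'   [convert_diann_report()], or a path to a long-format TSV.
#' @param dialect A `report_dialect`; drives parsing grammar and the
#'   localization default.
#' @param mode `"site"` or `"peptide"`.
#' @param prot A [proteome()]; required in site mode for peptide-to-protein
#'   mapping.
#' @param method Quantification method: `"maxlfq"` (default), `"sum"`,
#'   `"max"`.
#' @param normalize Run median normalization first? Default `TRUE`.
#' @param q_max Peptide q-value cutoff (strictly below). Default 0.01.
#' @param loc_min Localization cutoff (at or above); default is the
#'   dialect's conventional threshold.
#' @param quant_level `"ms2"`, `"ms1"` or `"both"` (default).
#' @param tracked_mods In peptide mode, modifications to count; default all.
#' @param min_shared_ions Minimum shared ions per sample pair for MaxLFQ.
#' @return A `quant_result` (see [quantify_keys()]).
#' @examples
#' \dontrun{
#' prot <- read_fasta("proteome.fasta")
#' rows <- read_long_report("report.tsv", dialect_spectronaut())
#' sites <- phospho_report(rows, dialect_spectronaut(), "site", prot)
#' write_wide_report(sites, "report-sites.tsv")
#' }
#' @export
phospho_report <- function(rows, dialect = dialect_spectronaut(),
                           mode = c("site", "peptide"), prot = NULL,
                           method = c("maxlfq", "sum", "max"),
                           normalize = TRUE, q_max = 0.01, loc_min = NULL,
                           quant_level = c("both", "ms2", "ms1"),
                           tracked_mods = NULL, min_shared_ions = 1L) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  quant_level <- match.arg(quant_level)
  if (is.character(rows) && length(rows) == 1L)
    rows <- read_long_report(rows, dialect)
  if (mode == "site" && is.null(prot))
    stop("site-level reporting requires a proteome (FASTA)")
  if (normalize) rows <- normalize_median(rows)
  rows <- filter_confident(rows, q_max = q_max, loc_min = loc_min,
                           require_loc = (mode == "site"), dialect = dialect)
  if (nrow(rows) == 0L) stop("no rows left after confidence filtering")
  keymap <- build_keymap(rows, mode = mode, prot = prot, dialect = dialect,
                         tracked = tracked_mods)
  if (nrow(keymap) == 0L) stop("no ", mode, " keys could be constructed")
  mats <- collate_ions(rows, keymap, quant_level = quant_level)
  info <- key_info_table(rows, keymap, mode, prot = prot, dialect = dialect,
                         tracked = tracked_mods)
  res <- quantify_keys(mats, method = method, key_info = info,
                       min_shared_ions = min_shared_ions)
  pr_log("%s-level report: %d keys x %d samples (%s)",
         mode, length(res$keys), length(res$sample_ids), method)
  res
}
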