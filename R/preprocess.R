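# Median normalization and class I confidence filtering.

#' Median-normalize intensities across runs
#'
#' Brings the per-run median intensity to a common level: each run's
#' intensities are multiplied by `f_r = exp(m - m_r)` where `m_r` is the
#' median natural-log intensity of the run's positive-intensity rows and
#' `m` the mean of the `m_r` (i.e. the common target is the geometric mean
#' of the run medians, which leaves the overall scale unchanged). Relative
#' intensities within a run are untouched; zero/absent intensities are left
#' as they are. Typically used to adjust for differing input amounts.
#'
#' @param rows Long-report data.table (see [read_long_report()]).
#' @return A new data.table with scaled intensities; the per-run factors
#'   are attached as attribute `"norm_factors"`.
#' @export
normalize_median <- function(rows) {
  rows <- data.table::copy(rows)
  pos <- rows$quantified
  runs <- unique(rows$run_id)
  dead <- setdiff(runs, unique(rows$run_id[pos]))
  if (length(dead) > 0L)
    stop("run(s) with no positive intensities: ", paste(dead, collapse = ", "))
  med <- vapply(runs, function(r)
    stats::median(log(rows$intensity[pos & rows$run_id == r])), numeric(1))
  f <- exp(mean(med) - med)
  names(f) <- runs
  rows[, "intensity" := rows$intensity * f[rows$run_id]]
  data.table::setattr(rows, "norm_factors", f)
  pr_log("median normalization: factors in [%.4g, %.4g] across %d runs",
         min(f), max(f), length(f))
  rows[]
}

#' Filter to confidently identified, well-localized observations
#'
#' Class I filtering: keeps rows with `q_value < q_max` and, when
#' `require_loc` is `TRUE` (site-level reporting), localization confidence
#' `>= loc_min`; rows with no localization score fail the localization
#' criterion. For peptide-level reporting `require_loc` is `FALSE` and the
#' localization score is ignored.
#'
#' The comparison directions are deliberate: strictly below the q-value
#' cutoff, at or above the localization cutoff.
#'
#' @param rows Long-report data.table.
#' @param q_max Maximum peptide q-value (exclusive). Default 0.01.
#' @param loc_min Minimum localization confidence (inclusive). Defaults to
#'   the dialect's conventional threshold (0.75 Spectronaut, 0.01 DIA-NN).
#' @param require_loc Enforce the localization criterion?
#' @param dialect Used only for the `loc_min` default.
#' @return Filtered data.table with attributes `"n_removed_q"` and
#'   `"n_removed_loc"`.
#' @export
filter_confident <- function(rows, q_max = 0.01, loc_min = NULL,
                             require_loc = TRUE,
                             dialect = dialect_spectronaut()) {
  if (is.null(loc_min)) loc_min <- dialect$default_loc_threshold
  stopifnot(q_max >= 0, q_max <= 1, loc_min >= 0, loc_min <= 1)
  pass_q <- !is.na(rows$q_value) & rows$q_value < q_max
  pass_loc <- if (require_loc) {
    !is.na(rows$localization) & rows$localization >= loc_min
  } else rep(TRUE, nrow(rows))
  keep <- pass_q & pass_loc
  n_q <- sum(!pass_q)
  n_loc <- sum(pass_q & !pass_loc)
  out <- rows[keep]
  data.table::setattr(out, "n_removed_q", n_q)
  data.table::setattr(out, "n_removed_loc", n_loc)
  pr_log("confidence filter: kept %d/%d rows (%d failed q-value, %d failed localization)",
         nrow(out), nrow(rows), n_q, n_loc)
  out[]
}
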