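# Per-key ion x sample matrices and the three quantification methods.
#
# MaxLFQ estimates per-sample log2 abundances from median pairwise
# log-ratios over shared ions, solved as a least-squares problem on the
# sample graph; it is robust to ions differing in ionization/fragmentation
# efficiency and to missing values, unlike plain summing.

#' Collate per-key ion intensity matrices
#'
#' Splits the (filtered, normalized) long report into one ions x samples
#' matrix per key. A row contributing to k keys (e.g. a doubly
#' phosphorylated peptide) appears in all k matrices. Duplicate
#' (ion, sample) observations are reduced by taking the maximum intensity.
#' Zero/absent intensities become explicit missing values. All matrices
#' share the same sample order.
#'
#' @param rows Long-report data.table.
#' @param keymap data.table `(modified_sequence, protein_group, key)` as
#'   built internally from [build_site_keys()] / [build_peptide_key()].
#' @param quant_level Ion evidence to use: `"ms2"` (fragment rows),
#'   `"ms1"` (precursor rows, i.e. rows with no fragment id), or `"both"`.
#' @param sample_ids Sample order; defaults to first appearance in `rows`.
#' @return Named list of `ion_matrix` objects (list with `key`, `ion_ids`,
#'   `sample_ids`, `values`), one per distinct key; attribute
#'   `"n_duplicates"` counts reduced duplicate observations.
#' @export
collate_ions <- function(rows, keymap, quant_level = c("both", "ms2", "ms1"),
                         sample_ids = NULL) {
  quant_level <- match.arg(quant_level)
  if (is.null(sample_ids)) sample_ids <- unique(rows$run_id)
  is_ms2 <- !is.na(rows$fragment_id) & nzchar(rows$fragment_id)
  use <- switch(quant_level, ms2 = is_ms2, ms1 = !is_ms2,
                both = rep(TRUE, nrow(rows)))
  use <- use & rows$quantified
  d <- rows[use, c("run_id", "modified_sequence", "protein_group",
                   "precursor_id", "fragment_id", "intensity")]
  d[, "ion_id" := ifelse(is.na(d$fragment_id) | !nzchar(d$fragment_id),
                         paste0(d$precursor_id, ":MS1"), d$fragment_id)]
  d <- merge(d, keymap, by = c("modified_sequence", "protein_group"),
             allow.cartesian = TRUE)
  n_before <- nrow(d)
  red <- d[, list(intensity = max(intensity)),
           by = c("key", "ion_id", "run_id")]
  n_dup <- n_before - nrow(red)
  if (n_dup > 0L)
    pr_log("reduced %d duplicate (ion, sample) observation(s) by max", n_dup)
  split_list <- split(red, by = "key", keep.by = TRUE)
  out <- lapply(split_list, function(g) {
    ions <- sort(unique(g$ion_id), method = "radix")
    m <- matrix(NA_real_, nrow = length(ions), ncol = length(sample_ids),
                dimnames = list(ions, sample_ids))
    m[cbind(match(g$ion_id, ions), match(g$run_id, sample_ids))] <- g$intensity
    structure(list(key = g$key[1], ion_ids = ions, sample_ids = sample_ids,
                   values = m),
              class = "ion_matrix")
  })
  attr(out, "n_duplicates") <- n_dup
  out
}

.check_ion_matrix <- function(m) {
  stopifnot(inherits(m, "ion_matrix"))
  if (nrow(m$values) == 0L) stop("empty ion matrix")
  invisible(m)
}

#' Quantify a key by summed intensity
#'
#' Per sample, log2 of the sum of observed ion intensities; missing where
#' no ion was observed.
#'
#' @param m An `ion_matrix`.
#' @return Named numeric vector of per-sample log2 abundance.
#' @export
quantify_sum <- function(m) {
  .check_ion_matrix(m)
  v <- m$values
  s <- colSums(v, na.rm = TRUE)
  s[colSums(!is.na(v)) == 0L] <- NA_real_
  log2(s)
}

#' Quantify a key by maximal intensity
#'
#' Per sample, log2 of the maximum observed ion intensity; missing where
#' no ion was observed.
#'
#' @param m An `ion_matrix`.
#' @return Named numeric vector of per-sample log2 abundance.
#' @export
quantify_max <- function(m) {
  .check_ion_matrix(m)
  v <- m$values
  s <- apply(v, 2L, function(col)
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE))
  log2(s)
}

#' Quantify a key by MaxLFQ
#'
#' Let `X` be the log2 intensity matrix (ions x samples, missing allowed).
#' For every sample pair (i, j) sharing at least `min_shared_ions` ions,
#' the pairwise log-ratio `r_ij` is the median over shared ions of
#' `X[, j] - X[, i]`. Samples connected by such pairs form components; in
#' each component the abundance vector `w` minimizes
#' `sum over pairs (w_j - w_i - r_ij)^2`, with the free additive constant
#' fixed by anchoring `sum(w)` to the sum of per-sample means of observed
#' log2 intensities (so the overall intensity scale is preserved). A
#' single-sample component gets the mean of its observed log2 intensities;
#' samples with no observations are missing.
#'
#' @param m An `ion_matrix`.
#' @param min_shared_ions Minimum shared ions for a pair to contribute a
#'   ratio. Default 1: phosphosites are often covered by few ions.
#' @return Named numeric vector of per-sample log2 abundance.
#' @export
quantify_maxlfq <- function(m, min_shared_ions = 1L) {
  .check_ion_matrix(m)
  X <- log2(m$values)
  maxlfq_solve(X, min_shared_ions = min_shared_ions)
}

# Core MaxLFQ solver on a log2 matrix. Split out so the synthetic-data and
# test code can call it on raw matrices.
#' @rdname quantify_maxlfq
#' @param X Log2 intensity matrix (ions x samples) with NA for missing.
#' @export
maxlfq_solve <- function(X, min_shared_ions = 1L) {
  S <- ncol(X)
  samples <- colnames(X)
  w <- stats::setNames(rep(NA_real_, S), samples)
  obs_mask <- !is.na(X)
  observed <- which(colSums(obs_mask) > 0L)
  if (length(observed) == 0L) return(w)
  if (length(observed) == 1L) {
    w[observed] <- mean(X[, observed], na.rm = TRUE)
    return(w)
  }
  k <- length(observed)
  Xo <- X[, observed, drop = FALSE]
  Mo <- obs_mask[, observed, drop = FALSE]
  # pairwise median log-ratios among observed samples
  R <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1L)) {
    sh_i <- Mo[, i]
    for (j in seq(i + 1L, k)) {
      sh <- sh_i & Mo[, j]
      if (sum(sh) >= min_shared_ions)
        R[i, j] <- stats::median(Xo[sh, j] - Xo[sh, i])
    }
  }
  adj <- !is.na(R) | !is.na(t(R))
  comp <- .components(adj)
  col_means <- colMeans(Xo, na.rm = TRUE)
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1L) {
      w[observed[idx]] <- col_means[idx]
      next
    }
    n <- length(idx)
    L <- matrix(0, n, n)
    b <- numeric(n)
    for (a in seq_len(n - 1L)) {
      for (bb in seq(a + 1L, n)) {
        r <- R[idx[a], idx[bb]]
        if (is.na(r)) next
        L[a, a] <- L[a, a] + 1
        L[bb, bb] <- L[bb, bb] + 1
        L[a, bb] <- L[a, bb] - 1
        L[bb, a] <- L[bb, a] - 1
        b[a] <- b[a] - r
        b[bb] <- b[bb] + r
      }
    }
    anchor <- sum(col_means[idx])
    A <- rbind(cbind(L, 1), c(rep(1, n), 0))
    sol <- solve(A, c(b, anchor))
    w[observed[idx]] <- sol[seq_len(n)]
  }
  w
}

# connected components of a logical adjacency matrix (tiny n; BFS)
.components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[1L]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Quantify all keys of a collated report
#'
#' @param matrices List of `ion_matrix` from [collate_ions()].
#' @param method `"maxlfq"` (default), `"sum"` or `"max"`.
#' @param key_info Optional data.table of descriptive key parts (merged by
#'   `key`) carried into the wide report.
#' @param min_shared_ions Passed to [quantify_maxlfq()].
#' @return Object of class `quant_result`: list with `keys`, `sample_ids`,
#'   `log2_abundance` (keys x samples matrix), `method`, `n_ions`,
#'   `key_info`.
#' @export
quantify_keys <- function(matrices, method = c("maxlfq", "sum", "max"),
                          key_info = NULL, min_shared_ions = 1L) {
  method <- match.arg(method)
  if (length(matrices) == 0L) stop("no keys to quantify")
  keys <- unname(vapply(matrices, function(m) m$key, character(1)))
  o <- order(keys, method = "radix")
  matrices <- matrices[o]
  keys <- keys[o]
  sample_ids <- matrices[[1]]$sample_ids
  fun <- switch(method,
                maxlfq = function(m) quantify_maxlfq(m, min_shared_ions),
                sum = quantify_sum,
                max = quantify_max)
  mat <- t(vapply(matrices, fun, numeric(length(sample_ids))))
  dimnames(mat) <- list(keys, sample_ids)
  info <- NULL
  if (!is.null(key_info)) {
    info <- key_info[match(keys, key_info$key)]
  }
  structure(
    list(keys = keys, sample_ids = sample_ids, log2_abundance = mat,
         method = method,
         n_ions = unname(vapply(matrices, function(m) nrow(m$values),
                                integer(1))),
         key_info = info),
    class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result> ", length(x$keys), " keys x ", length(x$sample_ids),
      " samples, method: ", x$method, "\n", sep = "")
  miss <- mean(is.na(x$log2_abundance))
  cat(sprintf("  %.1f%% missing cells\n", 100 * miss))
  invisible(x)
}
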