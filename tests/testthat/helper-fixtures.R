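# Shared fixtures and independent oracles for the test suite.

# --- independent MaxLFQ oracle ----------------------------------------------
# Solves the same pairwise-median least-squares problem by explicit
# pseudoinverse of the edge incidence matrix (MASS::ginv), with components
# found by iterated label closure. Written independently of maxlfq_solve().
maxlfq_oracle <- function(X, min_shared = 1L) {
  S <- ncol(X)
  w <- stats::setNames(rep(NA_real_, S), colnames(X))
  obs <- which(colSums(!is.na(X)) > 0L)
  if (length(obs) == 0L) return(w)
  Xo <- X[, obs, drop = FALSE]
  k <- length(obs)
  pairs <- list()
  rs <- numeric(0)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      sh <- !is.na(Xo[, i]) & !is.na(Xo[, j])
      if (sum(sh) >= min_shared) {
        pairs[[length(pairs) + 1L]] <- c(i, j)
        rs <- c(rs, stats::median(Xo[sh, j] - Xo[sh, i]))
      }
    }
  }
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (p in pairs) {
      m <- min(comp[p])
      if (any(comp[p] != m)) {
        comp[comp %in% comp[p]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) == 1L) {
      w[obs[idx]] <- mean(Xo[, idx], na.rm = TRUE)
      next
    }
    sel <- which(vapply(pairs, function(p) all(p %in% idx), logical(1)))
    A <- matrix(0, length(sel), length(idx))
    for (q in seq_along(sel)) {
      p <- pairs[[sel[q]]]
      A[q, match(p[1], idx)] <- -1
      A[q, match(p[2], idx)] <- 1
    }
    w0 <- as.vector(MASS::ginv(A) %*% rs[sel])
    anchor <- sum(colMeans(Xo[, idx, drop = FALSE], na.rm = TRUE))
    w[obs[idx]] <- w0 + (anchor - sum(w0)) / length(idx)
  }
  w
}

# random log2 ion matrix with controlled missingness; guarantees >=1 value
random_log2_matrix <- function(n_ions, n_samples, missing_rate) {
  X <- matrix(rnorm(n_ions * n_samples, mean = 20, sd = 2),
              n_ions, n_samples,
              dimnames = list(paste0("ion", seq_len(n_ions)),
                              paste0("s", seq_len(n_samples))))
  X[runif(length(X)) < missing_rate] <- NA_real_
  if (all(is.na(X))) X[1, 1] <- 20
  X
}

as_ion_matrix <- function(X_log2, key = "k") {
  structure(list(key = key,
                 ion_ids = rownames(X_log2),
                 sample_ids = colnames(X_log2),
                 values = 2^X_log2),
            class = "ion_matrix")
}

# --- toy proteome exercising all five site-key scenarios --------------------
# A:      "SAAASK" occurs once                      -> scenario i
# B:      "AASTYK" occurs at 1 and 9                -> scenario ii (repeat)
# C1/C2:  "VVSEK" occurs in both isoforms           -> scenario v
# D:      "ASTK", doubly phosphorylated             -> scenario iii
# E:      "SSTYK", triply phosphorylated            -> scenario iv
scenario_proteome <- function() {
  proteome(c(
    A  = "MKSAAASKR",               # SAAASK at 3: S3, S7
    B  = "AASTYKXXAASTYK",          # AASTYK at 1 and 9: S3/S11
    C1 = "MKVVSEKAAA",              # VVSEK at 3: S5
    C2 = "AAAAAAVVSEKR",            # VVSEK at 7: S9
    D  = "MKASTKR",                 # ASTK at 3: S4, T5
    E  = "MKSSTYKR"                 # SSTYK at 3: S3, S4, Y6
  ))
}

# the five scenario peptides as (modified sequence, protein group) pairs,
# bracket grammar, and their hand-enumerated site keys
scenario_cases <- function() {
  ph <- "[Phospho (STY)]"
  list(
    list(modseq = paste0("_S", ph, "AAASK_"), group = "A",
         keys = "A_S3_M1"),
    list(modseq = paste0("_AAS", ph, "TYK_"), group = "B",
         keys = "B_S3|S11_M1"),
    list(modseq = paste0("_AS", ph, "T", ph, "K_"), group = "D",
         keys = c("D_S4_M2", "D_T5_M2")),
    list(modseq = paste0("_S", ph, "S", ph, "TY", ph, "K_"), group = "E",
         keys = c("E_S3_M3", "E_S4_M3", "E_Y6_M3")),
    list(modseq = paste0("_VVS", ph, "EK_"), group = "C1;C2",
         keys = "C1;C2_S5;S9_M1")
  )
}

# build an in-memory long report from (modseq, group) cases: one fragment
# per peptide in each of `runs`, confident scores, unit intensities
scenario_report <- function(runs = c("r1", "r2")) {
  cases <- scenario_cases()
  rows <- data.table::rbindlist(lapply(cases, function(cs)
    data.table::CJ(run_id = runs, modified_sequence = cs$modseq)[,
      `:=`(protein_group = cs$group)]))
  rows[, `:=`(
    stripped_sequence = strip_modified_sequence(modified_sequence, "bracket"),
    precursor_id = paste0(modified_sequence, ".2"),
    fragment_id = paste0(modified_sequence, "#1"),
    intensity = 1000,
    q_value = 0.001,
    localization = 0.95,
    quantified = TRUE)]
  rows[]
}

# small synthetic experiment shared by several test files
small_synth <- function(seed = 42L, ...) {
  cfg <- synth_config(n_proteins = c(spike = 6L, background = 20L),
                      replicates = 3L, seed = seed, ...)
  suppressMessages(generate_experiment(cfg, tempfile("synth")))
}

quiet <- function(expr) suppressMessages(expr)
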