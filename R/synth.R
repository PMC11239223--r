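# Synthetic spike-in experiments with known ground truth.
#
# Emulates a mixed-species benchmark: phosphopeptides of a "spike" species
# change across conditions by known multipliers while a constant
# "background" species dominates the sample, as in yeast-in-human spike-in
# designs. Fragment intensities follow a multiplicative ion x sample model
# on the log2 scale:
#   log2 I(f, s) = base_p + a_f + b_s + log2(multiplier[condition(s)]) + noise
# (the condition term applies to spike-species peptides only), with
# missing-completely-at-random dropout and threshold-violating decoy rows
# for exercising the confidence filter.

#' Configuration of a synthetic spike-in experiment
#'
#' Defaults mirror a two-proteome spike-in benchmark with five conditions
#' at spike-species multipliers 0.25, 0.5, 1 (reference), 1.5 and 2, six
#' replicates each. The background species contributes the large majority
#' of peptides (as a small spike into a full-proteome background does), so
#' that median normalization is driven by the constant background.
#'
#' @param n_proteins Named integer vector `c(spike = , background = )`.
#' @param seq_length Length-2 integer range of protein lengths.
#' @param phospho_site_rate Per-S/T/Y probability of phosphorylation.
#' @param conditions Named numeric vector: condition name -> spike-species
#'   abundance multiplier.
#' @param reference Name of the reference condition (multiplier 1).
#' @param replicates Replicates per condition.
#' @param base_log2_mean,base_log2_sd Peptide baseline abundance (log2).
#' @param ion_effect_sd SD of per-ion (ionization/fragmentation) effects,
#'   log2 scale.
#' @param sample_effect_sd SD of per-run loading effects, log2 scale
#'   (removed by median normalization).
#' @param noise_sd SD of per-observation measurement noise, log2 scale.
#' @param missing_rate Probability that an observation is absent (MCAR).
#' @param decoy_fraction Fraction of phosphopeptides whose rows violate a
#'   confidence filter (half fail the q-value, half the localization).
#' @param oxidation_rate Per-M probability of Oxidation (M).
#' @param nterm_acetyl_rate Probability of protein-N-terminal acetylation
#'   for protein-initial peptides.
#' @param n_fragments Length-2 integer range of fragment ions per peptide.
#' @param dialect_name `"spectronaut"` or `"diann"`: output dialect of the
#'   report.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_proteins = c(spike = 50L, background = 2000L),
                         seq_length = c(250L, 450L),
                         phospho_site_rate = 0.25,
                         conditions = c(spike25 = 0.25, spike50 = 0.5,
                                        spike100 = 1, spike150 = 1.5,
                                        spike200 = 2),
                         reference = "spike100",
                         replicates = 6L,
                         base_log2_mean = 20, base_log2_sd = 2,
                         ion_effect_sd = 1,
                         sample_effect_sd = 0.25,
                         noise_sd = 0.3,
                         missing_rate = 0.2,
                         decoy_fraction = 0.1,
                         oxidation_rate = 0.1,
                         nterm_acetyl_rate = 0.3,
                         n_fragments = c(3L, 6L),
                         dialect_name = c("spectronaut", "diann"),
                         seed = 1L) {
  dialect_name <- match.arg(dialect_name)
  stopifnot(all(c("spike", "background") %in% names(n_proteins)),
            length(seq_length) == 2L, seq_length[1] >= 30L,
            phospho_site_rate >= 0, phospho_site_rate <= 1,
            missing_rate >= 0, missing_rate <= 1,
            decoy_fraction >= 0, decoy_fraction < 1,
            replicates >= 1L,
            reference %in% names(conditions),
            conditions[[reference]] == 1)
  structure(as.list(environment()), class = "synth_config")
}

.render_modseq <- function(stripped, mod_pos, mod_name, grammar) {
  # mod_pos: integer positions (0 = protein N-term), sorted ascending
  token <- function(name) {
    if (grammar == "bracket") paste0("[", name, "]")
    else {
      id <- names(.unimod_map)[match(name, .unimod_map)]
      if (is.na(id)) paste0("(", name, ")") else paste0("(UniMod:", id, ")")
    }
  }
  chars <- strsplit(stripped, "")[[1]]
  pieces <- character(length(chars) + 1L)
  for (k in seq_along(mod_pos))
    pieces[mod_pos[k] + 1L] <- paste0(pieces[mod_pos[k] + 1L],
                                      token(mod_name[k]))
  body <- paste0(pieces[1L],
                 paste0(chars, pieces[-1L], collapse = ""))
  if (grammar == "bracket") paste0("_", body, "_") else body
}

# tryptic digestion: cleave after K/R except before P; returns start + peptide
.digest <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[cut_after + 1L] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  data.table::data.table(start = starts,
                         peptide = substring(seq, starts, ends))
}

#' Generate a synthetic spike-in experiment
#'
#' Generates a random proteome, digests it in silico (cleavage after K/R
#' except before P, peptide length 7-25), phosphorylates S/T/Y residues at
#' the configured rate, and writes a FASTA proteome plus a long-format
#' fragment report in the configured dialect together with ground-truth
#' tables. Peptides whose sequence occurs more than once in the whole
#' proteome are excluded so that each ground-truth site key is
#' unambiguous.
#'
#' @param cfg A [synth_config()].
#' @param dir Output directory (created if needed).
#' @return List with `fasta_path`, `report_path`, `proteome`, `rows` (the
#'   report as a long-report data.table), `truth_sites` (key, species,
#'   accession, position, multiplicity, is_decoy, ...), `truth_abundance`
#'   (key, run_id, true_log2), `design` (condition, multiplier,
#'   ratio_vs_reference), `dialect`, `config`.
#' @export
generate_experiment <- function(cfg, dir = tempfile("synthexp")) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dia <- if (cfg$dialect_name == "spectronaut") dialect_spectronaut()
         else dialect_diann()
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

  # --- proteome ------------------------------------------------------------
  species <- rep(c("spike", "background"),
                 times = c(cfg$n_proteins[["spike"]],
                           cfg$n_proteins[["background"]]))
  n_prot <- length(species)
  acc <- ifelse(species == "spike",
                sprintf("SPK%04d", cumsum(species == "spike")),
                sprintf("BGD%04d", cumsum(species == "background")))
  lens <- sample(seq(cfg$seq_length[1], cfg$seq_length[2]), n_prot,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- acc
  prot <- proteome(seqs, stats::setNames(
    paste0("synthetic ", species, " protein"), acc))
  fasta_path <- file.path(dir, "proteome.fasta")
  write_fasta(prot, fasta_path)

  # --- digestion and phospho-form assignment -------------------------------
  peps <- data.table::rbindlist(lapply(seq_len(n_prot), function(i) {
    d <- .digest(seqs[i])
    d[, `:=`(accession = acc[i], species = species[i])]
    d
  }))
  peps <- peps[nchar(peps$peptide) >= 7L & nchar(peps$peptide) <= 25L]
  if (nrow(peps) == 0L)
    stop("configuration yields no peptides; increase sequence length")

  # keep only peptides occurring exactly once in the whole proteome
  big <- paste(seqs, collapse = "!")
  occ <- vapply(peps$peptide, function(p) {
    m <- gregexpr(p, big, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
  peps <- peps[occ == 1L]

  # phosphorylation and auxiliary modifications
  forms <- vector("list", nrow(peps))
  for (i in seq_len(nrow(peps))) {
    p <- peps$peptide[i]
    chars <- strsplit(p, "")[[1]]
    sty <- which(chars %in% c("S", "T", "Y"))
    ph <- sty[stats::runif(length(sty)) < cfg$phospho_site_rate]
    if (length(ph) == 0L) next
    pos <- ph
    nm <- rep("Phospho (STY)", length(ph))
    mm <- which(chars == "M")
    ox <- mm[stats::runif(length(mm)) < cfg$oxidation_rate]
    if (length(ox) > 0L) { pos <- c(pos, ox); nm <- c(nm, rep("Oxidation (M)", length(ox))) }
    cc <- which(chars == "C")
    if (length(cc) > 0L) { pos <- c(pos, cc); nm <- c(nm, rep("Carbamidomethyl (C)", length(cc))) }
    if (peps$start[i] == 1L && stats::runif(1) < cfg$nterm_acetyl_rate) {
      pos <- c(pos, 0L); nm <- c(nm, "Acetyl (Protein N-term)")
    }
    o <- order(pos)
    forms[[i]] <- list(phospho = ph, mod_pos = pos[o], mod_name = nm[o])
  }
  has_form <- !vapply(forms, is.null, logical(1))
  peps <- peps[has_form]
  forms <- forms[has_form]
  if (nrow(peps) == 0L)
    stop("configuration yields no phosphopeptides; increase phospho_site_rate or sequence length")

  peps[, `:=`(
    pep_id = seq_len(nrow(peps)),
    modseq = vapply(seq_along(forms), function(i)
      .render_modseq(peps$peptide[i], forms[[i]]$mod_pos,
                     forms[[i]]$mod_name, dia$mod_grammar), character(1)),
    n_phospho = vapply(forms, function(f) length(f$phospho), integer(1)),
    base_log2 = stats::rnorm(nrow(peps), cfg$base_log2_mean, cfg$base_log2_sd),
    n_frag = sample(seq(cfg$n_fragments[1], cfg$n_fragments[2]),
                    nrow(peps), replace = TRUE)
  )]
  peps[, "precursor_id" := paste0(peps$modseq, ".2")]

  # decoys: a fraction of phosphopeptides violate one filter in all rows
  n_decoy <- floor(cfg$decoy_fraction * nrow(peps))
  decoy_ids <- if (n_decoy > 0L) sample(peps$pep_id, n_decoy) else integer(0)
  peps[, "is_decoy" := peps$pep_id %in% decoy_ids]
  decoy_kind <- stats::setNames(rep(c("q", "loc"), length.out = n_decoy),
                                decoy_ids)

  # --- samples -------------------------------------------------------------
  runs <- data.table::data.table(
    condition = rep(names(cfg$conditions), each = cfg$replicates),
    replicate = rep(seq_len(cfg$replicates), length(cfg$conditions)))
  runs[, `:=`(run_id = sprintf("%s_r%02d", runs$condition, runs$replicate),
              multiplier = cfg$conditions[runs$condition],
              b_s = stats::rnorm(nrow(runs), 0, cfg$sample_effect_sd))]

  # --- fragment-level intensities ------------------------------------------
  frags <- peps[, list(frag_ord = seq_len(n_frag)), by = "pep_id"]
  frags[, `:=`(a_f = stats::rnorm(nrow(frags), 0, cfg$ion_effect_sd),
               fragment_id = paste0(frags$pep_id, "y", frags$frag_ord))]

  grid <- data.table::CJ(pep_id = peps$pep_id, run_idx = seq_len(nrow(runs)))
  grid <- merge(grid, peps[, c("pep_id", "species", "base_log2", "modseq",
                               "peptide", "precursor_id", "accession",
                               "is_decoy")],
                by = "pep_id")
  grid[, `:=`(run_id = runs$run_id[grid$run_idx],
              b_s = runs$b_s[grid$run_idx],
              multiplier = runs$multiplier[grid$run_idx])]
  grid[, "cond_log2" := ifelse(grid$species == "spike",
                               log2(grid$multiplier), 0)]
  # per (peptide, run) confidence scores
  thr <- dia$default_loc_threshold
  loc_true <- c(min(thr + 0.01, 0.99), 1)
  loc_decoy <- c(0, max(thr * 0.5, thr - 0.1))
  npr <- nrow(grid)
  grid[, `:=`(q_value = stats::runif(npr, 0, 0.009),
              localization = stats::runif(npr, loc_true[1], loc_true[2]))]
  if (n_decoy > 0L) {
    kind <- decoy_kind[as.character(grid$pep_id)]
    bad_q <- !is.na(kind) & kind == "q"
    bad_l <- !is.na(kind) & kind == "loc"
    grid[bad_q, "q_value" := stats::runif(sum(bad_q), 0.02, 0.5)]
    grid[bad_l, "localization" := stats::runif(sum(bad_l), loc_decoy[1],
                                               loc_decoy[2])]
  }

  rows <- merge(frags, grid, by = "pep_id", allow.cartesian = TRUE)
  rows[, "log2_int" := rows$base_log2 + rows$a_f + rows$b_s + rows$cond_log2 +
         stats::rnorm(nrow(rows), 0, cfg$noise_sd)]
  if (cfg$missing_rate > 0)
    rows <- rows[stats::runif(nrow(rows)) >= cfg$missing_rate]
  if (nrow(rows) == 0L) stop("all observations dropped; lower missing_rate")

  long <- data.table::data.table(
    run_id            = rows$run_id,
    modified_sequence = rows$modseq,
    stripped_sequence = rows$peptide,
    protein_group     = rows$accession,
    precursor_id      = rows$precursor_id,
    fragment_id       = rows$fragment_id,
    intensity         = 2^rows$log2_int,
    q_value           = rows$q_value,
    localization      = rows$localization)
  data.table::setorder(long, run_id, modified_sequence, fragment_id)
  long[, "quantified" := is.finite(long$intensity) & long$intensity > 0]
  report_path <- file.path(dir, "report.tsv")
  write_long_report(long, report_path, dia)

  # --- ground truth --------------------------------------------------------
  truth_sites <- peps[, {
    ph <- forms[[match(pep_id, peps$pep_id)]]$phospho
    mult <- min(length(ph), 3L)
    prot_pos <- start + ph - 1L
    residue <- substring(peptide, ph, ph)
    list(key = paste0(accession, "_", residue, prot_pos, "_M", mult),
         accession = accession, position = prot_pos, residue = residue,
         multiplicity = mult, species = species, is_decoy = is_decoy,
         stripped = peptide, modified_sequence = modseq)
  }, by = "pep_id"]

  truth_abundance <- grid[, list(
    pep_id = grid$pep_id, run_id = grid$run_id,
    true_log2 = grid$base_log2 + grid$b_s + grid$cond_log2)]
  truth_abundance <- merge(truth_abundance,
                           truth_sites[, c("pep_id", "key")],
                           by = "pep_id", allow.cartesian = TRUE)
  truth_abundance <- truth_abundance[, c("key", "run_id", "true_log2")]

  design <- data.table::data.table(
    condition = names(cfg$conditions),
    multiplier = unname(cfg$conditions),
    ratio_vs_reference = unname(cfg$conditions) / cfg$conditions[[cfg$reference]])

  data.table::fwrite(truth_sites, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(truth_abundance, file.path(dir, "truth_abundance.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE)

  pr_log("synthetic experiment: %d proteins, %d phosphopeptides (%d decoy), %d report rows",
         n_prot, nrow(peps), n_decoy, nrow(long))
  list(fasta_path = fasta_path, report_path = report_path,
       proteome = prot, rows = long, truth_sites = truth_sites,
       truth_abundance = truth_abundance, design = design,
       dialect = dia, config = cfg)
}
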