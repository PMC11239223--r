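# Phosphosite and phosphopeptide identifier construction.
#
# A site key names a protein group, the phosphorylated residue position(s)
# in each protein, and the phosphorylation multiplicity of the evidencing
# peptide. Five situations are resolved:
#   (i)   singly phosphorylated peptide, one protein, one occurrence;
#   (ii)  the peptide occurs at several positions of one protein -- one key
#         per site listing every alternative position, flagged ambiguous;
#   (iii) doubly phosphorylated peptide -- one key per site, multiplicity 2;
#   (iv)  three or more phospho groups -- one key per site, multiplicity 3;
#   (v)   the peptide maps to several isoforms of the group -- a single key
#         listing all isoforms with their per-isoform positions.
# These compose (a doubly phosphorylated multi-isoform peptide yields two
# multi-accession keys with multiplicity 2), and the quantitative evidence
# of one peptide attaches to every key it generates.

#' Phosphorylation multiplicity class
#'
#' MaxQuant-style multiplicity: 1 for singly, 2 for doubly, 3 for three or
#' more phospho groups on the evidencing peptide.
#'
#' @param n_phospho Number of phospho groups (>= 1).
#' @return Integer in `{1, 2, 3}`.
#' @export
multiplicity <- function(n_phospho) {
  stopifnot(length(n_phospho) == 1L)
  if (is.na(n_phospho) || n_phospho < 1L)
    stop("no site key for an unphosphorylated peptide (n_phospho = ",
         n_phospho, ")")
  as.integer(min(n_phospho, 3L))
}

# Rendering: accessions joined by ";", then "_", then per-accession
# "<residue><position>" lists (alternatives within one accession joined by
# "|") joined by ";", then "_M<multiplicity>". Example: "P1;P2_S12;S45_M1".
.render_site_key <- function(accessions, site_strings, mult) {
  paste0(paste(accessions, collapse = ";"), "_",
         paste(site_strings, collapse = ";"), "_M", mult)
}

#' Build phosphosite keys for one modified peptide
#'
#' Maps each phospho position of `pep` to protein coordinates through every
#' occurrence of the stripped sequence in the accessions of `group`, and
#' emits one key per phospho group. Accessions in `group` that are missing
#' from the proteome are skipped with a log message; a peptide matching no
#' accession yields zero keys.
#'
#' @param pep A `modified_peptide` with at least one phospho group.
#' @param group Character vector of accessions (the protein group), or a
#'   single ";"-joined string. Isoform order in the key follows this order.
#' @param prot A [proteome()].
#' @return data.table with one row per key: `key` (rendered string),
#'   `protein_group`, `positions`, `multiplicity`, `ambiguous`.
#' @export
build_site_keys <- function(pep, group, prot) {
  stopifnot(inherits(pep, "modified_peptide"))
  pp <- pep$phospho_positions
  if (length(pp) == 0L)
    stop("no site key for an unphosphorylated peptide")
  mult <- multiplicity(length(pp))
  if (length(group) == 1L && grepl(";", group, fixed = TRUE))
    group <- strsplit(group, ";", fixed = TRUE)[[1]]
  group <- group[nzchar(group)]
  if (length(group) == 0L) stop("empty protein group")

  entries <- prot$entries
  known <- group %in% names(entries)
  if (any(!known))
    pr_log("accession(s) not in proteome, skipped: %s",
           paste(group[!known], collapse = ", "))
  group <- group[known]

  plen <- nchar(pep$stripped)
  starts_by_acc <- list()
  for (acc in group) {
    m <- gregexpr(paste0("(?=", pep$stripped, ")"), entries[[acc]],
                  perl = TRUE)[[1]]
    if (m[1] != -1L) starts_by_acc[[acc]] <- as.integer(m)
  }
  accs <- group[group %in% names(starts_by_acc)]  # keep group order
  if (length(accs) == 0L) {
    pr_log("peptide %s not found in any accession of its group", pep$stripped)
    return(data.table::as.data.table(list(
      key = character(0), protein_group = character(0),
      positions = character(0), multiplicity = integer(0),
      ambiguous = logical(0))))
  }
  ambiguous <- any(vapply(starts_by_acc[accs], length, integer(1)) > 1L)

  out <- vector("list", length(pp))
  for (k in seq_along(pp)) {
    p <- pp[k]
    site_strings <- vapply(accs, function(acc) {
      pos <- sort(unique(map_site_to_protein(starts_by_acc[[acc]], p)))
      if (any(pos + 0L > nchar(entries[[acc]])) || any(pos < 1L))
        stop("site position outside protein bounds for ", acc)
      letters_ <- substring(entries[[acc]], pos, pos)
      pep_letter <- substring(pep$stripped, p, p)
      if (any(letters_ != pep_letter))
        stop("residue mismatch at mapped site in ", acc,
             " (expected ", pep_letter, ")")
      paste0(letters_, pos, collapse = "|")
    }, character(1))
    out[[k]] <- data.table::as.data.table(list(
      key = .render_site_key(accs, site_strings, mult),
      protein_group = paste(accs, collapse = ";"),
      positions = paste(site_strings, collapse = ";"),
      multiplicity = mult,
      ambiguous = ambiguous))
  }
  data.table::rbindlist(out)
}

#' Build the modification-count peptide key
#'
#' Peptide-level identifier: the stripped sequence with the count of each
#' modification appended (`"<seq>_<name>x<count>"`), tracked modifications
#' first in the canonical order of [canonical_modifications()], any other
#' labels after in lexicographic order; zero counts are omitted. Positions
#' are discarded, so positional phospho-isomers with the same composition
#' share one peptide key.
#'
#' @param pep A `modified_peptide`.
#' @param tracked Modifications to count; others are counted too unless
#'   excluded here. Default: all observed.
#' @return List of class `peptide_key` with `stripped`, `mod_counts`
#'   (named integer vector) and `key` (rendered string).
#' @export
build_peptide_key <- function(pep, tracked = NULL) {
  stopifnot(inherits(pep, "modified_peptide"))
  nm <- pep$mods$name
  if (!is.null(tracked)) nm <- nm[nm %in% tracked]
  counts <- if (length(nm) > 0L) table(nm) else NULL
  canon <- canonical_modifications()
  order_of <- function(n) {
    i <- match(n, canon)
    ifelse(is.na(i), length(canon) + 1L, i)
  }
  if (!is.null(counts)) {
    labs <- names(counts)
    labs <- labs[order(order_of(labs), labs, method = "radix")]
    counts <- stats::setNames(as.integer(counts[labs]), labs)
    key <- paste0(pep$stripped,
                  paste0("_", labs, "x", counts, collapse = ""))
  } else {
    counts <- integer(0)
    key <- pep$stripped
  }
  structure(list(stripped = pep$stripped, mod_counts = counts, key = key),
            class = "peptide_key")
}

# Vectorized key construction over the unique peptides of a report.
# Returns a keymap: one row per (modified_sequence, protein_group, key).
build_keymap <- function(rows, mode = c("site", "peptide"), prot = NULL,
                         dialect = dialect_spectronaut(), tracked = NULL) {
  mode <- match.arg(mode)
  uniq <- unique(rows[, c("modified_sequence", "protein_group")])
  if (mode == "site" && is.null(prot))
    stop("site-level reporting requires a proteome (FASTA)")
  maps <- vector("list", nrow(uniq))
  n_keyless <- 0L
  for (i in seq_len(nrow(uniq))) {
    pep <- parse_modified_sequence(uniq$modified_sequence[i], dialect)
    if (mode == "site") {
      if (length(pep$phospho_positions) == 0L) { n_keyless <- n_keyless + 1L; next }
      keys <- build_site_keys(pep, uniq$protein_group[i], prot)
      if (nrow(keys) == 0L) { n_keyless <- n_keyless + 1L; next }
      maps[[i]] <- data.table::as.data.table(list(
        modified_sequence = rep(uniq$modified_sequence[i], nrow(keys)),
        protein_group = rep(uniq$protein_group[i], nrow(keys)),
        key = keys$key))
    } else {
      pk <- build_peptide_key(pep, tracked)
      maps[[i]] <- data.table::as.data.table(list(
        modified_sequence = uniq$modified_sequence[i],
        protein_group = uniq$protein_group[i],
        key = pk$key))
    }
  }
  if (n_keyless > 0L)
    pr_log("%d peptide(s) generated no %s key", n_keyless, mode)
  keymap <- data.table::rbindlist(maps)
  if (nrow(keymap) == 0L)
    keymap <- data.table::as.data.table(list(
      modified_sequence = character(0), protein_group = character(0),
      key = character(0)))
  keymap
}

# descriptive parts per distinct key, for the wide report
key_info_table <- function(rows, keymap, mode, prot = NULL,
                           dialect = dialect_spectronaut(), tracked = NULL) {
  if (mode == "site") {
    uniq <- unique(keymap[, c("modified_sequence", "protein_group")])
    parts <- vector("list", nrow(uniq))
    for (i in seq_len(nrow(uniq))) {
      pep <- parse_modified_sequence(uniq$modified_sequence[i], dialect)
      parts[[i]] <- build_site_keys(pep, uniq$protein_group[i], prot)
    }
    info <- unique(data.table::rbindlist(parts),  by = "key")
    info[, c("key", "protein_group", "positions", "multiplicity")]
  } else {
    uniq <- unique(keymap$modified_sequence)
    parts <- lapply(uniq, function(ms) {
      pk <- build_peptide_key(parse_modified_sequence(ms, dialect), tracked)
      mods <- if (length(pk$mod_counts) > 0L)
        paste0(names(pk$mod_counts), "x", pk$mod_counts, collapse = ";") else ""
      data.table::as.data.table(list(key = pk$key, sequence = pk$stripped,
                                     modifications = mods))
    })
    unique(data.table::rbindlist(parts), by = "key")
  }
}
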