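# Modified-sequence parsing and peptide/site coordinate mapping.
#
# Two grammars are supported:
#   bracket: "_AAS[Phospho (STY)]K_"  -- token in [] follows the modified
#            residue; leading/trailing underscores are padding; a token
#            before any residue must be protein-N-terminal.
#   unimod:  "AAS(UniMod:21)K"        -- "(UniMod:N)" after the residue.

.phospho_label <- "Phospho (STY)"

#' Canonical modification labels
#'
#' The four modifications tracked by default in phosphoproteomics searches,
#' in the fixed order used when rendering peptide keys. Other labels are
#' preserved verbatim and sorted after these.
#'
#' @return Character vector of canonical labels.
#' @export
canonical_modifications <- function() {
  c("Phospho (STY)", "Acetyl (Protein N-term)",
    "Carbamidomethyl (C)", "Oxidation (M)")
}

.unimod_map <- c("21" = "Phospho (STY)",
                 "35" = "Oxidation (M)",
                 "4"  = "Carbamidomethyl (C)",
                 "1"  = "Acetyl (Protein N-term)")

#' Strip modification tokens from modified sequences (vectorised)
#'
#' @param modseq Character vector of modified sequences.
#' @param grammar `"bracket"` or `"unimod"` (or a `report_dialect`).
#' @return Character vector of plain amino-acid sequences.
#' @export
strip_modified_sequence <- function(modseq, grammar = "bracket") {
  if (inherits(grammar, "report_dialect")) grammar <- grammar$mod_grammar
  out <- switch(grammar,
    bracket = gsub("_", "", gsub("\\[[^][]*\\]", "", modseq), fixed = TRUE),
    unimod  = gsub("\\(UniMod:[0-9]+\\)", "", modseq),
    stop("unknown grammar: ", grammar))
  out
}

#' Parse one modified sequence
#'
#' Produces the stripped sequence plus positioned modifications. Positions
#' are 1-based indices into the stripped sequence; protein-N-terminal
#' modifications carry position 0. In the unimod grammar the UniMod ids
#' 21, 35, 4 and 1 are canonicalised to the labels of
#' [canonical_modifications()]; unknown ids are preserved as `"UniMod:N"`.
#'
#' @param modseq A single modified-sequence string.
#' @param dialect A `report_dialect`, or a grammar name.
#' @return An object of class `modified_peptide`: list with `stripped`,
#'   `mods` (data.table with columns `position`, `name`, sorted by
#'   position) and `phospho_positions` (integer vector).
#' @export
parse_modified_sequence <- function(modseq, dialect = dialect_spectronaut()) {
  grammar <- if (inherits(dialect, "report_dialect")) dialect$mod_grammar else dialect
  stopifnot(length(modseq) == 1L, is.character(modseq))
  if (grammar == "bracket") {
    res <- .parse_tokens(modseq, open = "[", close = "]", trim_underscore = TRUE,
                         canon = identity)
  } else if (grammar == "unimod") {
    canon <- function(name) {
      id <- sub("^UniMod:", "", name)
      if (id %in% names(.unimod_map)) .unimod_map[[id]] else name
    }
    res <- .parse_tokens(modseq, open = "(", close = ")", trim_underscore = FALSE,
                         canon = canon)
  } else stop("unknown grammar: ", grammar)
  mods <- data.table::data.table(position = res$positions, name = res$names)
  data.table::setorder(mods, position)
  structure(
    list(stripped = res$stripped,
         mods = mods,
         phospho_positions = mods$position[mods$name == .phospho_label]),
    class = "modified_peptide"
  )
}

# shared token scanner for both grammars
.parse_tokens <- function(modseq, open, close, trim_underscore, canon) {
  s <- modseq
  if (trim_underscore) s <- gsub("^_+|_+$", "", s)
  chars <- strsplit(s, "")[[1]]
  stripped <- character(0)
  positions <- integer(0)
  names_ <- character(0)
  i <- 1L
  n <- length(chars)
  pos <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == open) {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == open) depth <- depth + 1L
        if (chars[j] == close) depth <- depth - 1L
        if (depth == 0L) break
        j <- j + 1L
      }
      if (j > n || depth > 0L)
        stop("unbalanced '", open, "' at offset ", i, " in: ", modseq)
      name <- canon(paste(chars[seq(i + 1L, j - 1L)], collapse = ""))
      if (pos == 0L && !grepl("N-term", name, fixed = TRUE))
        stop("modification token '", name, "' at sequence start (offset ", i,
             ") has no preceding residue and is not N-terminal: ", modseq)
      positions <- c(positions, pos)
      names_ <- c(names_, name)
      i <- j + 1L
    } else if (ch == close) {
      stop("unbalanced '", close, "' at offset ", i, " in: ", modseq)
    } else {
      pos <- pos + 1L
      stripped <- c(stripped, ch)
      i <- i + 1L
    }
  }
  list(stripped = paste(stripped, collapse = ""),
       positions = positions, names = names_)
}

#' @export
print.modified_peptide <- function(x, ...) {
  cat("<modified_peptide> ", x$stripped, "\n", sep = "")
  if (nrow(x$mods) > 0L) {
    for (k in seq_len(nrow(x$mods)))
      cat("  ", x$mods$name[k], " @ ", x$mods$position[k], "\n", sep = "")
  } else cat("  (unmodified)\n")
  invisible(x)
}

#' Locate a peptide in a proteome
#'
#' All exact substring occurrences, including overlapping matches and
#' repeats within one accession, ordered by accession (lexicographic,
#' C locale) then start position. Leu and Ile are distinct letters.
#'
#' @param stripped Plain amino-acid sequence (non-empty).
#' @param prot A [proteome()], or a named character vector of sequences.
#' @return data.table with columns `accession`, `start` (1-based); zero
#'   rows when the peptide is absent.
#' @export
locate_peptide <- function(stripped, prot) {
  stopifnot(is.character(stripped), length(stripped) == 1L, nzchar(stripped))
  entries <- if (inherits(prot, "proteome")) prot$entries else prot
  accs <- sort(names(entries), method = "radix")
  out_acc <- character(0)
  out_start <- integer(0)
  pat <- paste0("(?=", stripped, ")")  # lookahead: overlapping matches
  for (acc in accs) {
    m <- gregexpr(pat, entries[[acc]], perl = TRUE)[[1]]
    if (m[1] != -1L) {
      out_acc <- c(out_acc, rep(acc, length(m)))
      out_start <- c(out_start, as.integer(m))
    }
  }
  data.table::data.table(accession = out_acc, start = out_start)
}

#' Map a peptide-local site position to protein coordinates
#'
#' @param start 1-based start of the peptide in the protein.
#' @param site_pos 1-based position of the site within the peptide.
#' @return 1-based position of the site in the protein:
#'   `start + site_pos - 1`.
#' @export
map_site_to_protein <- function(start, site_pos) {
  stopifnot(all(start >= 1L), all(site_pos >= 1L))
  start + site_pos - 1L
}
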