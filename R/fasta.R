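# Proteome container and FASTA input. Peptide-to-protein mapping works on
# exact amino-acid strings, so sequences are stored uppercased, one entry
# per accession.

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U")

#' Construct a proteome
#'
#' @param sequences Named character vector, accession -> amino-acid sequence.
#' @param descriptions Optional named character vector of free-text
#'   descriptions (same names as `sequences`).
#' @return An object of class `proteome`: a list with elements `entries`
#'   (named uppercase sequences) and `descriptions`.
#' @export
proteome <- function(sequences, descriptions = NULL) {
  if (length(sequences) == 0L) stop("empty proteome")
  acc <- names(sequences)
  if (is.null(acc) || any(!nzchar(acc)))
    stop("all sequences must be named by accession")
  dup <- acc[duplicated(acc)]
  if (length(dup) > 0L)
    stop("duplicate accession: ", paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences))) stop("empty sequence for accession: ",
                                    paste(acc[!nzchar(sequences)], collapse = ", "))
  bad <- vapply(strsplit(sequences, ""), function(ch)
    any(!ch %in% .aa_alphabet), logical(1))
  if (any(bad))
    stop("non-amino-acid characters in sequence of: ",
         paste(acc[bad], collapse = ", "))
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(acc)), acc)
  structure(list(entries = sequences, descriptions = descriptions[acc]),
            class = "proteome")
}

#' Read a FASTA proteome
#'
#' Accessions are taken from the second pipe-delimited field of
#' UniProt-style headers (`>sp|P12345|NAME ...`), otherwise from the whole
#' first whitespace-delimited token. Wrapped sequence lines are
#' concatenated and uppercased.
#'
#' @param path Path to a FASTA file.
#' @return A [proteome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header_idx <- grep("^>", lines)
  if (length(header_idx) == 0L) stop("empty proteome")
  ends <- c(header_idx[-1L] - 1L, length(lines))
  acc <- character(length(header_idx))
  desc <- character(length(header_idx))
  seqs <- character(length(header_idx))
  for (k in seq_along(header_idx)) {
    header <- sub("^>", "", lines[header_idx[k]])
    token <- strsplit(header, "[ \t]")[[1]][1]
    parts <- strsplit(token, "|", fixed = TRUE)[[1]]
    acc[k] <- if (length(parts) >= 2L) parts[2L] else token
    desc[k] <- trimws(sub("^\\S*", "", header))
    body <- lines[seq(header_idx[k] + 1L, ends[k])]
    body <- body[!grepl("^>", body)]
    seqs[k] <- toupper(gsub("[ \t]", "", paste(body, collapse = "")))
  }
  if (all(!nzchar(seqs))) stop("empty proteome")
  names(seqs) <- acc
  names(desc) <- acc
  proteome(seqs, desc)
}

#' Write a proteome to FASTA
#'
#' @param prot A [proteome()].
#' @param path Output path.
#' @param width Sequence line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(prot, path, width = 60L) {
  stopifnot(inherits(prot, "proteome"))
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  for (acc in names(prot$entries)) {
    desc <- prot$descriptions[[acc]]
    header <- if (nzchar(desc)) paste0(">", acc, " ", desc) else paste0(">", acc)
    s <- prot$entries[[acc]]
    starts <- seq(1L, nchar(s), by = width)
    body <- substring(s, starts, pmin(starts + width - 1L, nchar(s)))
    writeLines(c(header, body), con, sep = "\n")
  }
  invisible(path)
}

#' @export
print.proteome <- function(x, ...) {
  n <- length(x$entries)
  cat("<proteome> ", n, " entr", if (n == 1L) "y" else "ies",
      ", total ", sum(nchar(x$entries)), " residues\n", sep = "")
  show <- utils::head(names(x$entries), 5L)
  for (acc in show)
    cat("  ", acc, " (", nchar(x$entries[[acc]]), " aa)\n", sep = "")
  if (n > 5L) cat("  ...\n")
  invisible(x)
}

#' @export
length.proteome <- function(x) length(x$entries)
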