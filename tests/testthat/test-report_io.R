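test_that("read_fasta parses UniProt and bare headers, wraps lines", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|X some description", "MKSAAASKR",
               ">P2", "MK", "SA"), tf)
  p <- read_fasta(tf)
  expect_identical(unname(p$entries["P1"]), "MKSAAASKR")
  expect_identical(unname(p$entries["P2"]), "MKSA")
  expect_identical(unname(p$descriptions["P1"]), "some description")
})

test_that("read_fasta rejects empty files and duplicate accessions", {
  tf <- tempfile(fileext = ".fasta")
  writeLines(character(0), tf)
  expect_error(read_fasta(tf), "empty proteome")
  writeLines(c(">sp|P1|A", "MKSA", ">sp|P1|A", "MKSA"), tf)
  expect_error(read_fasta(tf), "P1")
})

test_that("long report read populates logical fields from dialect columns", {
  exp <- small_synth()
  rows <- quiet(read_long_report(exp$report_path, exp$dialect))
  expect_gt(nrow(rows), 0L)
  expect_identical(rows$stripped_sequence,
                   strip_modified_sequence(rows$modified_sequence, "bracket"))
  expect_true(all(rows$q_value >= 0 & rows$q_value <= 1))
  expect_true(all(rows$intensity > 0))
  # row order and fields survive a write/read cycle (identity invariant)
  tf <- tempfile(fileext = ".tsv")
  write_long_report(rows, tf, exp$dialect)
  back <- quiet(read_long_report(tf, exp$dialect))
  for (f in c("run_id", "modified_sequence", "protein_group", "precursor_id",
              "fragment_id")) {
    expect_identical(back[[f]], rows[[f]])
  }
  expect_equal(back$intensity, rows$intensity, tolerance = 1e-12)
  expect_equal(back$q_value, rows$q_value, tolerance = 1e-12)
  expect_equal(back$localization, rows$localization, tolerance = 1e-12)
})

test_that("header-only report yields an empty row set without error", {
  tf <- tempfile(fileext = ".tsv")
  dia <- dialect_spectronaut()
  writeLines(paste(dia$column_map, collapse = "\t"), tf)
  rows <- quiet(read_long_report(tf, dia))
  expect_identical(nrow(rows), 0L)
})

test_that("missing protein-group column is reported by its dialect name", {
  tf <- tempfile(fileext = ".tsv")
  dia <- dialect_spectronaut()
  keep <- setdiff(unname(dia$column_map), "PG.ProteinGroups")
  writeLines(c(paste(keep, collapse = "\t"),
               paste(rep("x", length(keep)), collapse = "\t")), tf)
  expect_error(quiet(read_long_report(tf, dia)), "PG.ProteinGroups",
               fixed = TRUE)
})

test_that("non-numeric intensity cells are rejected with a row number", {
  exp <- small_synth()
  raw <- data.table::fread(exp$report_path, colClasses = "character")
  raw[["F.PeakArea"]][3] <- "oops"
  tf <- tempfile(fileext = ".tsv")
  data.table::fwrite(raw, tf, sep = "\t", quote = FALSE)
  expect_error(quiet(read_long_report(tf, dialect_spectronaut())), "row 3")
})

# --- DIA-NN conversion -------------------------------------------------------

diann_fixture <- function(rows) {
  tf <- tempfile(fileext = ".tsv")
  header <- c("Run", "Protein.Ids", "Modified.Sequence", "Precursor.Id",
              "Q.Value", "PTM.Site.Confidence", "Fragment.Quant.Raw")
  writeLines(c(paste(header, collapse = "\t"),
               vapply(rows, paste, character(1), collapse = "\t")), tf)
  tf
}

test_that("conversion unrolls packed fragments, dropping zero entries", {
  prot <- proteome(c(P1 = "MKSAAASKR"))
  tf <- diann_fixture(list(
    c("runA", "P1", "SAAAS(UniMod:21)K", "SAAASK2", "0.001", "0.9",
      "100;200;0")))
  rows <- quiet(convert_diann_report(tf, prot))
  expect_identical(nrow(rows), 2L)
  expect_equal(rows$intensity, c(100, 200))
  expect_identical(rows$fragment_id, c("SAAASK2#1", "SAAASK2#2"))
  expect_identical(attr(rows, "n_zero_fragments"), 1L)
})

test_that("conversion conserves summed intensity per precursor", {
  prot <- proteome(c(P1 = "MKSAAASKR", P2 = "AAAAVVSEKR"))
  packed <- c("12.5;0;88;19", "5;5;0;0;7")
  tf <- diann_fixture(list(
    c("runA", "P1", "SAAAS(UniMod:21)K", "p1", "0.001", "0.9", packed[1]),
    c("runB", "P2", "VVS(UniMod:21)EK", "p2", "0.002", "0.8", packed[2])))
  rows <- quiet(convert_diann_report(tf, prot))
  for (i in 1:2) {
    vals <- as.numeric(strsplit(packed[i], ";")[[1]])
    expect_equal(sum(rows$intensity[rows$precursor_id == paste0("p", i)]),
                 sum(vals[vals > 0]))
  }
  expect_true(all(rows$intensity > 0))
})

test_that("conversion recomputes isoform membership from the proteome", {
  prot <- proteome(c(P2 = "AAAAVVSEKR", P1 = "MKVVSEKAAA"))
  tf <- diann_fixture(list(
    c("runA", "P1", "VVS(UniMod:21)EK", "p1", "0.001", "0.9", "10;20"),
    c("runA", "P9", "WWWWWWW", "p9", "0.001", "0.9", "10")))
  rows <- quiet(convert_diann_report(tf, prot))
  expect_identical(unique(rows$protein_group), "P1;P2")  # lexicographic
  expect_identical(attr(rows, "n_unmapped_peptides"), 1L)
  expect_false("p9" %in% rows$precursor_id)
})

test_that("conversion rejects empty proteomes and unparsable packed fields", {
  prot <- proteome(c(P1 = "MKSAAASKR"))
  tf <- diann_fixture(list(
    c("runA", "P1", "SAAAS(UniMod:21)K", "p1", "0.001", "0.9", "100;x;2")))
  expect_error(quiet(convert_diann_report(tf, prot)), "row 1")
  expect_error(convert_diann_report(tf, list()), "proteome")
})

test_that("converted output satisfies the long-report invariants", {
  prot <- proteome(c(P1 = "MKSAAASKR"))
  tf <- diann_fixture(list(
    c("runA", "P1", "SAAAS(UniMod:21)K", "p1", "0.001", "0.9", "100;200;0"),
    c("runB", "P1", "SAAAS(UniMod:21)K", "p1", "0.002", "0.8", "50")))
  rows <- quiet(convert_diann_report(tf, prot))
  expect_identical(rows$stripped_sequence,
                   strip_modified_sequence(rows$modified_sequence, "unimod"))
  expect_true(all(nzchar(rows$protein_group)))
  expect_true(all(is.finite(rows$intensity) & rows$intensity > 0))
  expect_true(all(rows$quantified))
})

# --- wide report -------------------------------------------------------------

test_that("wide report renders keys x samples with empty cells for missing", {
  X <- matrix(c(1.5, NA, 2.25, NA, NA, NA), nrow = 2, byrow = TRUE,
              dimnames = list(c("k1", "k2"), c("s1", "s2", "s3")))
  res <- structure(list(keys = rownames(X), sample_ids = colnames(X),
                        log2_abundance = X, method = "sum",
                        n_ions = c(2L, 1L), key_info = NULL),
                   class = "quant_result")
  tf <- tempfile(fileext = ".tsv")
  write_wide_report(res, tf)
  back <- read_wide_report(tf)
  expect_identical(back$method, "sum")
  expect_identical(nrow(back$table), 2L)        # all-missing row retained
  expect_identical(back$table$s2, c("", ""))
  expect_equal(back$log2_abundance, X)
  # round-trip: re-rendering equals the file's rendered values
  rendered <- ifelse(is.na(X), "", sprintf("%.10g", X))
  got <- as.matrix(back$table[, c("s1", "s2", "s3")])
  dimnames(rendered) <- dimnames(got)
  expect_identical(got, rendered)
})
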