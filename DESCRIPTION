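Package: phosphoreport
Title: Site-Level and Peptide-Level Reporting for DIA-MS Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts long-format DIA-MS search reports (Spectronaut-style
    exports, or DIA-NN main reports via a built-in converter) into
    confidence-filtered, normalized phosphosite-level and phosphopeptide-level
    quantitative tables. Phosphosite identifiers combine the protein group,
    protein site positions and phosphorylation multiplicity, resolving
    repeated peptide occurrences and protein isoforms; phosphopeptide
    identifiers append per-modification counts to the stripped sequence.
    Per-identifier ion-by-sample intensity matrices are summarized by MaxLFQ,
    intensity summing, or maximum intensity. A synthetic-data module generates
    self-contained two-species spike-in experiments with known ground truth
    for validating the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
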