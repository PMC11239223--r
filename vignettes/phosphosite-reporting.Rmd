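---
title: "Phosphosite reporting and MaxLFQ quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phosphosite reporting and MaxLFQ quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosphoreport)
```

This vignette documents the models, conventions and numerical choices
behind phosphoreport, in the spirit of a methods section: what each step
assumes, which knobs matter, and what the synthetic benchmark does and
does not demonstrate.

## Pipeline overview

Site-level reporting proceeds in four steps, each a plain function:

1. **Median normalization** (`normalize_median()`, optional, default on) —
   corrects for differing amounts of input material per run.
2. **Class I confidence filtering** (`filter_confident()`) — keeps
   observations with peptide q-value strictly below 0.01 and, for site
   reporting, localization confidence at or above the tool's threshold.
3. **Site-key construction** (`build_site_keys()`) — maps peptide-local
   phospho positions to protein coordinates and renders the identifier.
4. **Quantification** (`quantify_keys()`) — MaxLFQ (default), summed, or
   maximal intensity per key and sample.

Peptide-level reporting replaces step 3 with modification-count keys
(`build_peptide_key()`) and drops the localization requirement in step 2,
since a composition count needs no positional confidence.

## Input model and dialects

The unit of input is one fragment-ion (or precursor) observation in one
run, with a modified-sequence string, a protein group, a q-value, a
localization score and an intensity. A `report_dialect` object carries the
column map, the modified-sequence grammar (`S[Phospho (STY)]` bracket
style vs `S(UniMod:21)` style) and the localization-threshold convention:
0.75 for Spectronaut-style assay probabilities, 0.01 for DIA-NN-style site
confidence, two operating points reported in the literature as roughly
equivalent. Every column is user-overridable because export schemes drift
across tool versions; the DIA-NN converter's map (`diann_main_columns()`)
is likewise a documented default (DIA-NN 1.8 main-report names), not a
fixed contract.

DIA-NN main reports pack per-fragment intensities into a
semicolon-separated field. The converter unrolls them into one row per
fragment with positive intensity. Zero packed entries encode "not
quantified" and are dropped rather than stored as zeros, so missingness
stays explicit for MaxLFQ. The protein group is recomputed by exact
substring search of the stripped peptide against the search proteome (all
matching accessions, sorted lexicographically for deterministic keys),
because isoform membership in the upstream report is not guaranteed to
cover every isoform of the supplied FASTA. Leu/Ile are kept distinct: the
mapping is against the stated database, not against mass-equivalence
classes.

## Normalization

Run `r`'s intensities are scaled by `f_r = exp(m − m_r)`, where `m_r` is
the median natural-log intensity of the run's positive-intensity rows and
`m` is the mean of the `m_r`. All runs end up with a common median (the
geometric mean of the original medians, so the overall scale is
preserved); within-run ratios are untouched, and the operation is
idempotent to floating-point precision. Normalization runs before
filtering. The factors are computed from fragment-level rows (the
quantified unit); MS1 rows, when present, are scaled by the same per-run
factor.

The method assumes most analytes are constant across runs. In a spike-in
design this holds only because the changing species is a small fraction of
the signal; the median then shifts by roughly (spike share) × (log2
multiplier), a bias the synthetic benchmark makes visible (see below). For
experiments where a large fraction of sites move, normalization should be
disabled (`normalize = FALSE`, `--no-normalize`).

## Filtering conventions

The q-value comparison is strict (`q < q_max`), the localization
comparison inclusive (`loc ≥ loc_min`), read literally from the usual
statement of the class I criterion ("below 1% FDR, localization at least
0.75"). Rows with no localization score fail the site-mode filter — an
unlocalized observation cannot support a positional claim — but pass in
peptide mode. Filtering is a pure row subset: idempotent, order-preserving,
with removal counts logged per criterion.

## Site keys: the five cases and their composition

One key is emitted per phospho group of the evidencing peptide, with
multiplicity `min(number of phospho groups, 3)`. The renderer is
`accessions ; -joined _ per-accession position lists _ M<multiplicity>`,
with `|` separating alternative positions within one accession. Rendering
is injective over valid keys, which is the binding requirement; the
separators themselves are package conventions.

Two cases deserve comment:

* **Repeated peptide within one protein.** The peptide is one piece of
  evidence; emitting one key per alternative position would multiply-count
  it. phosphoreport emits a single key enumerating the alternatives
  (`B_S3|S11_M1`) and flags it ambiguous. These sites are exactly the ones
  a naive exact-position join silently drops.
* **Isoform-shared peptides.** All matching isoforms of the group are
  listed in one key with their per-isoform positions, in the group's
  order. No re-grouping is attempted: the group is taken as given
  (Spectronaut) or as recomputed from the FASTA (DIA-NN conversion).

Protein-N-terminal acetylation is carried at peptide position 0; it never
generates site keys but is counted in peptide keys. Positional
phospho-isomers with equal composition share one peptide key but distinct
site keys — the two report levels answer different questions.

## MaxLFQ: estimator and numerical choices

For a site's log2 ion-by-sample matrix `X`, pairwise ratios
`r_ij = median_f(X[f,j] − X[f,i])` are computed over every sample pair
sharing at least `min_shared_ions` ions (default 1 — phosphosites are
often covered by a single precursor's few fragments, and requiring 2+
shared ions would silently drop many sites). Samples joined by such pairs
form connected components; within a component the abundance vector
minimizes `Σ (w_j − w_i − r_ij)²`. The least-squares problem fixes only
differences, so one gauge constraint is needed per component: the sum of
`w` is anchored to the sum of per-sample means of observed log2
intensities. This preserves the overall intensity scale, reduces to the
ion's own values for a single-ion site, and makes the estimator exactly
shift-equivariant: scaling one sample's raw intensities by `c` moves only
that sample's value, by `log2(c)`.

The bordered normal-equation system (Laplacian plus the constraint row) is
solved directly; it is nonsingular for every connected component, so no
tolerance parameter exists. Single-sample components fall back to the mean
of observed values; samples with no observations are missing. Duplicate
(ion, sample) observations — e.g. re-integrated features — are reduced to
their maximum before quantification, a deterministic rule logged with a
count. The test suite pins the whole estimator against an independent
solver that builds the edge incidence matrix explicitly and applies a
Moore–Penrose pseudoinverse; agreement is required to 1e-8 over hundreds
of random missingness patterns.

Sum and max quantification ignore missing cells and return log2 of the
column reduction; all three methods coincide on single-ion matrices. The
default ion set is fragments plus any MS1 precursor trace (`quant_level =
"both"`); restrict to `"ms2"` or `"ms1"` to benchmark evidence levels.

## The synthetic benchmark

`generate_experiment()` builds a self-contained experiment: random protein
sequences over the 20-letter alphabet, tryptic digestion (cleave after K/R
except before P, peptides of length 7–25), per-S/T/Y phosphorylation at a
configurable rate, 3–6 fragment ions per peptide, and intensities from the
multiplicative model

```
log2 I(f, s) = base_p + a_f + b_s + log2(multiplier[condition(s)]) + ε
```

with per-ion effects `a_f ~ N(0, 1)`, per-run loading effects
`b_s ~ N(0, 0.25)`, measurement noise `ε ~ N(0, 0.3)` and 20%
missing-completely-at-random dropout. The condition term applies only to
the spike species. Defaults emulate a two-species spike-in benchmark: five
conditions at multipliers 0.25/0.5/1/1.5/2 (reference 1), six replicates,
and a spike species held at roughly 2–3% of report rows (50 spike vs 2000
background proteins). That share is deliberate: the median-normalization
bias on background ratios is approximately the spike row share times the
log2 multiplier, so a small spike keeps the constant background in control
of the normalization — which is also what makes real spike-in designs
(a small spike into a full-proteome background) workable. True rows draw
q-values in [0, 0.009] and localization above the dialect threshold; a
configurable fraction of decoy peptides violates exactly one criterion, so
the filter's removals can be counted exactly. Peptides whose sequence
occurs more than once in the synthetic proteome are dropped, making every
ground-truth key unambiguous; the repeated-peptide and isoform scenarios
are instead exercised by a hand-built toy proteome whose key set is
enumerated by hand in the tests.

What the generator does **not** emulate: correlated (intensity-dependent)
missingness, chimeric/interference noise, retention-time drift, charge
states and missed cleavages, realistic FDR behaviour beyond
threshold-violating decoys, or shared peptides between the two species.
Passing the benchmark therefore shows that the pipeline's bookkeeping and
estimator are correct under its stated model, not that any search engine's
error control is valid.

Problem sizes: module tests run on experiments of ~26 proteins
(seconds); the quantitative benchmark uses the full default proteome
(~2050 proteins, ≈ 300–400 spike sites, ≈ 650 000 report rows, five
conditions × three replicates), which completes in about 90 seconds. At
that scale MaxLFQ recovers the design ratios to within a few percent
(median spike-site ratios ≈ 0.256/0.505/1.49/1.97 against 0.25/0.5/1.5/2)
and background medians within ~1% of 1.0; the residual deviation is
dominated by the normalization composition bias discussed above, not by
the estimator.

## Known limitations

* Site keys are only as good as the proteome: a peptide absent from the
  FASTA yields no key (logged), and sequence databases with redundant
  entries inflate multi-accession keys.
* Ambiguous (repeated-peptide) keys enumerate alternatives but do not
  split evidence probabilistically; localization-weighted splitting is out
  of scope.
* MaxLFQ's large-ratio stabilization variants and missing-value imputation
  are intentionally not implemented; absent means absent.
* The CLI's flag surface uses GNU-style long options; tool tags are
  `--tool sn` and `--tool diann`.
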