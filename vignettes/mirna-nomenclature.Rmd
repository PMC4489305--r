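---
title: "Sequence-keyed harmonization of miRNA nomenclature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-keyed harmonization of miRNA nomenclature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirharmony)
library(dplyr)
```

## The problem

Mature microRNAs (miRNAs) are short (19–25 nt) regulatory RNAs catalogued in
a versioned reference repository, miRBase. Between releases, entries are
renamed (most visibly when `-5p`/`-3p` arm suffixes were introduced),
retired ("dead" entries), added, and occasionally even re-sequenced.
Commercial profiling platforms (microarrays, RT-qPCR panels) design their
probes against whichever release was current at design time, and their
annotation files are updated loosely, when at all; some carry outright
design errors in which a probe's reported name and its target sequence
disagree. A published miRNA list therefore means different things depending
on which release or platform annotation produced it, and name-based
comparison of data sets across studies silently drops or mislabels entries.

The way out is to stop trusting names. The mature sequence is what a probe
physically hybridizes to and what a sequencing read is, so two entries are
*the same miRNA* exactly when their mature sequences are identical. This
package makes that principle operational: every mapping operation keys on
the normalized full-length mature sequence, and names are treated as
version-scoped labels attached to sequences.

## The model

A **namespace** is any source of (name, mature sequence) pairs: a
species-scoped release snapshot or a platform probe set. Within a namespace,
name → sequence must be single-valued (a violation is a data defect, flagged
and excluded, never silently resolved); sequence → names may be multi-valued,
because paralogous precursors can yield identical matures — these surface
downstream as status `multiple`.

Translation of a name list from namespace *S* to namespace *D* is the
composition

    name --S--> sequence --D--> {names}

and each input row receives one of six statuses forming a partition:
`stable` (the single destination name equals the input), `renamed` (single,
different), `multiple` (two or more destination names), `dead` (sequence
absent from *D* and the source accession is in *D*'s dead registry),
`missing` (absent with no evidence of retirement), `unrecognized` (the input
name is not in *S* at all — typical of control probes and other non-miRNA
annotations). The same machinery underlies the four list/matrix operations
(`translate_names()`, `overlap_namespaces()`, `update_matrix()`,
`intersect_matrices()`); matrix operations carry the expression values over
bit-identically and never drop an input row — untranslatable rows keep their
diagnostic status, optionally sorted to the bottom.

Name history (`build_history()`, `time_warp_query()`) is the one place
identity is keyed on the MIMAT accession instead of the sequence: sequences
themselves can change between releases, while the accession is the
repository's stable handle. Events (`introduced`, `renamed`, `deleted`,
`sequence_changed`) are reconstructed purely from consecutive-release
comparison, plus dead-registry membership.

## Parameters that matter

* **Identity key** — the normalized full-length mature sequence (uppercase,
  RNA alphabet, whitespace stripped), compared by *exact equality within one
  species*. Substring/overhang probe matching is deliberately rejected:
  vendor probes longer than the mature sequence must be pre-trimmed in the
  annotation file. Exact match is the only reading of sequence-keyed
  commonality that is reproducible across tools; containment would make
  "same miRNA" depend on trimming heuristics. This is an interpretation — an
  annotation pipeline could instead trim or anchor — and it is the package's
  contract.
* **Arm** (5p/3p, reported as "strand" in some result tables) is derived from
  the name suffix and never stored independently, because pre-arm-suffix
  names simply lack it; such entries get `unspecified`.
* **Dead inference** — dead registries are carried per release. When a series
  is loaded without dead lists, `infer_dead()` marks an accession dead from
  the first release where it disappears. Without accession evidence a
  sequence absent from the destination is reported `missing`, never `dead`:
  the package does not over-claim retirement.
* **Case rescue** (`case_rescue = TRUE`) — names are matched case-sensitively
  after whitespace trimming; a case-insensitive fallback is attempted and,
  only when it rescues a name *uniquely*, used and annotated in `note`.
  Vendor files differ in capitalization (`hsa-miR` vs `hsa-mir`), but silent
  case-folding would mask genuine mature-vs-precursor name distinctions.
  Note that a rescued row reports status `renamed` (the emitted name differs
  from the typed one), which keeps the status partition exact.
* **Version order** (`mir_config()`) — version labels are opaque strings
  ordered by an explicit list (default the classic "10.0" … "21" ladder);
  they are never parsed numerically, since "10.1" and "21" do not order
  numerically.
* **Multi-name output** — one row with a `;`-joined name list by default;
  `explode_translation()` yields the long format.
* **Default species** — `hsa` in the CLI configuration, matching the most
  common use; library functions take the species explicitly.

## The synthetic-data generator

Everything is testable offline because `generate_series()` fabricates a
miniature release series together with the exact scripted event log that
produced it. The generator emulates the *structure* of release evolution —
renames (letter bumps, e.g. `syn-miR-2-3p → syn-miR-2b-3p`, mirroring how
the original member of a family implicitly becomes the "a" form), deletions
with cumulative dead registries, additions, sequence revisions, and scripted
sequence collisions (pairs like `syn-miR-5a`/`syn-miR-5b` sharing one
sequence) — under the synthetic species code `syn`, which guarantees no
fixture can be mistaken for real annotation. Sequences are uniform random
over {A,C,G,U}, 19–25 nt; collisions are always constructed by copying,
never left to chance, because accidental identical 19–25-mers are
vanishingly rare and tests need scripted ones.

Scripted-count mode selects event targets by a deterministic
tail-of-accession rule, so a given spec always renames and deletes the same
entries; rate mode draws targets under the seed. The canonical two-release
toy (`fixture_toy3()`) exercises one of everything and anchors the unit
tests.

What the generator does **not** emulate: realistic expression biology
(matrix values are log-normal noise with known provenance, nothing more),
vendor-specific file quirks beyond the defined platform CSV schema,
cross-species paralogy, or the historical quirks of real releases
(reinstatements, alias lists). Passing tests therefore demonstrate that the
*mapping logic* is exact on structurally faithful inputs; they do not
certify any particular real release file, whose ingestion path
(`read_mature_fasta()`, `read_release_tsv()`) is exercised by round-trip
tests instead. As a real-data illustration that must come from user-supplied
release files: hsa-miR-453 is a known rename casualty around release 15 —
the package reports whatever the loaded snapshots say and hard-codes no such
case.

## Numerical and edge-case choices

* Output determinism: multi-name sets, overlap rows and platform lists are
  sorted lexicographically; result files contain no timestamps.
* `update_matrix()` keeps input row order by default; `failures_last = TRUE`
  moves rows with no destination name to the bottom with a stable sort. Both
  orderings are supported because result tables are commonly eyeballed
  top-to-bottom and scripted left-joined, and the two uses prefer different
  layouts.
* `intersect_matrices()`: when two rows of one matrix resolve to the same
  sequence, the first is kept and later ones go to the side report with an
  explanatory note. Shared sequences absent from the destination namespace
  stay in the result with empty destination names — the intersection is
  sequence-keyed; the destination annotation only decorates it.
* Degenerate inputs: empty name lists, header-only matrices, empty
  namespaces and single-release series all pass through with empty (not
  error) results; malformed files (missing columns, ragged rows, duplicate
  probe ids, non-nucleotide characters) raise classed errors naming the
  offender.
* Generators restore the caller's RNG state (`withr::with_seed`), so
  fixtures cannot perturb user analyses.

## Problem sizes used in the checks

The test-suite and acceptance-script fixtures use series of 2–5 releases
with 15–250 initial records, 1,000-query oracle comparisons per seed over 5
seeds for the translation/lookup equivalence checks, 20 seeded series for
event-recovery, and 10 seeds each for conservation, round-trip and curation
checks — small enough to run in seconds, large enough that every status and
event kind occurs many times per run.

## Known limitations

Precursor (hairpin) records, genomic coordinates, families/clusters and
target prediction are out of scope, as are fuzzy or edit-distance sequence
matching and cross-species pooling of identical sequences. Alias-list
ingestion is not a history source — history is reconstructed only from the
loaded snapshots, so a series with gaps will report
deleted-then-reinstated where a continuous record might exist in the
unloaded releases. Merging more than two matrices is done by composing
pairwise intersections.
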