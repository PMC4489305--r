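# mirharmony

Sequence-keyed harmonization of miRNA nomenclature across miRBase release
versions and profiling-platform annotations.

## Why

Mature miRNA names are unstable: between miRBase releases entries are
renamed (`miR-21` → `miR-21-5p`), retired, added or re-sequenced, and
commercial profiling platforms (microarray and RT-qPCR panels) ship
annotations frozen at whatever release they were designed against —
sometimes with outright design errors where a probe's reported name and its
target sequence disagree. Comparing miRNA lists or expression data sets by
name alone therefore silently drops or mislabels entries.

`mirharmony` keys identity on the **normalized full-length mature
sequence** instead. Any source of (name, sequence) pairs — a species-scoped
miRBase release or a platform probe set — becomes a *namespace*, and
translation from namespace *S* to namespace *D* is the composition

```
name --S--> mature sequence --D--> {names}
```

Each translated name receives one of six statuses that partition all
outcomes: `stable`, `renamed`, `multiple` (one sequence, several
destination names), `dead` (retired accession), `missing`, `unrecognized`.

## What it does

* `translate_names()` / `overlap_namespaces()` — name-list translation
  between any two namespaces; sequence-keyed overlap of two namespaces.
* `update_matrix()` / `intersect_matrices()` — re-annotate an expression
  matrix (miRNA rows × sample columns) to another namespace, or join two
  matrices on shared sequences, carrying the values over bit-identically
  and never dropping a row.
* `build_history()` / `time_warp_query()` / `detecting_platforms()` —
  per-accession name history across an ordered release series
  (introductions, renames, deletions, sequence changes), with stringent
  (exact) or relaxed (substring) queries and platform detectability.
* `curate_platform()` — audit a platform annotation against its
  design-version release for name↔sequence consistency.
* `generate_series()` / `derive_platform()` / `generate_matrix()` — a
  deterministic synthetic fixture generator with a scripted ground-truth
  event log, so the whole pipeline is testable offline.
* Readers/writers for a canonical release TSV, the mature FASTA dialect,
  platform CSV and matrix CSV/TSV, plus a CLI (`inst/cli/mirharmony`) with
  subcommands `translate`, `overlap`, `update`, `intersect`, `timewarp`,
  `curate`, `fixtures`.

All user-facing functions take data frames / tibbles and return tibbles;
fitted-style results have `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

The canonical toy fixture has two releases: `v2` renames `syn-miR-2-3p` to
`syn-miR-2b-3p`, retires `syn-miR-3`, and adds the collision pair
`syn-miR-5a`/`syn-miR-5b` (one sequence, two names).

```r
library(mirharmony)

fx    <- fixture_toy3()
ns_v1 <- build_namespace(fx$index$releases[["v1"]], "syn")
ns_v2 <- build_namespace(fx$index$releases[["v2"]], "syn")

translate_names(c("syn-miR-1-5p", "syn-miR-2-3p", "syn-miR-3",
                  "spike-in-ctrl-1"), ns_v1, ns_v2) |>
  dplyr::select(input_name, status, output_names, output_accessions)
#> # A tibble: 4 × 4
#>   input_name      status       output_names    output_accessions
#>   <chr>           <chr>        <chr>           <chr>
#> 1 syn-miR-1-5p    stable       "syn-miR-1-5p"  "MIMAT0000001"
#> 2 syn-miR-2-3p    renamed      "syn-miR-2b-3p" "MIMAT0000002"
#> 3 syn-miR-3       dead         ""              ""
#> 4 spike-in-ctrl-1 unrecognized ""              ""
```

`syn-miR-1-5p` survives unchanged; `syn-miR-2-3p` is bridged to its new
name through its sequence; `syn-miR-3`'s accession sits in v2's dead
registry; the spike-in control was never a miRNA name and is flagged, not
guessed at. Name history confirms the rename and shows the entry is alive:

```r
hist <- build_history(fx$index, species = "syn")
time_warp_query(hist, "syn-miR-2-3p", species = "syn")
#> # A tibble: 1 × 8
#>   mimat_id     mi_ids   species current_name  current_sequence  arm   length alive
#> 1 MIMAT0000002 MI00000… syn     syn-miR-2b-3p GAAGUAGAAUCUUGC…  3p        25 TRUE
```

The stringent query matched a *former* name and returned the entry's
current state — exactly the lookup that name-based comparison gets wrong.

## Scope

Mature-sequence records only: precursor hairpins, genomic coordinates,
families and target prediction are out of scope, as is fuzzy sequence
matching. Real release files are user-supplied and never downloaded by the
package. See `vignettes/mirna-nomenclature.Rmd` for the model, design
decisions and limitations.
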