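#' Normalize a mature miRNA sequence
#'
#' Mature miRNA sequences arrive in many dialects: vendor annotation files are
#' frequently in the DNA alphabet (T instead of U), mixed case, or wrapped
#' across lines. All sequence-keyed operations in this package compare
#' sequences only after normalization, so that "the same mature sequence"
#' is well defined across sources.
#'
#' Normalization removes all whitespace, uppercases, and replaces T with U.
#' The result contains only A, C, G, U. The function is idempotent.
#'
#' @param raw Character vector of raw sequences.
#' @return Character vector of normalized sequences, same length as `raw`.
#' @examples
#' normalize_sequence("ugagGUAG")   # "UGAGGUAG"
#' normalize_sequence("TGAGGTAG")   # "UGAGGUAG"
#' @export
normalize_sequence <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  out <- stringr::str_remove_all(raw, "\\s+")
  bad_empty <- !is.na(out) & out == ""
  if (any(bad_empty)) {
    rlang::abort("invalid sequence: empty after removing whitespace",
                 class = "mirharmony_invalid_sequence")
  }
  out <- chartr("acgut", "ACGUT", out)
  offending <- stringr::str_extract(out, "[^ACGUT]")
  if (any(!is.na(offending))) {
    ch <- offending[!is.na(offending)][1L]
    rlang::abort(
      paste0("invalid sequence: character '", ch, "' outside alphabet {A,C,G,U,T}"),
      class = "mirharmony_invalid_sequence"
    )
  }
  chartr("T", "U", out)
}

#' Derive the arm (5p/3p) from a miRNA name
#'
#' The arm records which side of the hairpin precursor the mature sequence
#' derives from. Result tables of some tools call this "strand". It is derived
#' from the name suffix and never stored independently, because names that
#' predate arm-suffixed nomenclature simply lack the information.
#'
#' @param name Character vector of miRNA names.
#' @return Character vector over `"5p"`, `"3p"`, `"unspecified"`.
#' @export
arm_from_name <- function(name) {
  dplyr::case_when(
    stringr::str_ends(name, stringr::fixed("-5p")) ~ "5p",
    stringr::str_ends(name, stringr::fixed("-3p")) ~ "3p",
    .default = "unspecified"
  )
}

#' Extract the species code prefix from a miRNA name
#'
#' @param name Character vector of miRNA names (e.g. `"hsa-miR-21-5p"`).
#' @return The three/four-letter code, or `NA` for unprefixed names.
#' @export
species_from_name <- function(name) {
  m <- stringr::str_match(name, "^([a-z]{3,4})-")[, 2]
  m
}

#' Construct a miRBase release snapshot
#'
#' A release is one versioned snapshot of the mature-miRNA catalogue: a table
#' of mature records plus the set of accessions retired ("dead") at or before
#' this release. Records are identified by their MIMAT accession; names may
#' change between releases but accessions are the stable handle.
#'
#' @param records Data frame with at least `mimat_id`, `name`, `sequence`.
#'   Optional columns: `species` (derived from the name prefix when absent),
#'   `mi_ids` (comma-joined string or list column of precursor accessions),
#'   `arm`, `length` (both derived when absent).
#' @param version_label Version label string, e.g. `"21"` or `"v1"`.
#' @param dead_ids Character vector of retired MIMAT accessions.
#' @return A `mir_release` object: list with `version_label`, `records`
#'   (tibble), `dead_ids`, `species_set`.
#' @export
mir_release <- function(records, version_label, dead_ids = character()) {
  records <- tibble::as_tibble(records)
  required <- c("mimat_id", "name", "sequence")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("release records lack column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mirharmony_format_error")
  }
  records$sequence <- if (nrow(records)) normalize_sequence(records$sequence) else character()
  if (!"species" %in% names(records)) {
    records$species <- species_from_name(records$name)
  }
  if (!"mi_ids" %in% names(records)) {
    records$mi_ids <- vector("list", nrow(records))
    records$mi_ids <- purrr::map(records$mi_ids, ~ character())
  } else if (is.character(records$mi_ids)) {
    records$mi_ids <- stringr::str_split(records$mi_ids, stringr::fixed(","))
    records$mi_ids <- purrr::map(records$mi_ids, ~ .x[.x != ""])
  }
  if (!"arm" %in% names(records)) records$arm <- arm_from_name(records$name)
  if (!"length" %in% names(records)) records$length <- nchar(records$sequence)
  records$length <- as.integer(records$length)
  records <- dplyr::select(records, "mimat_id", "name", "sequence", "species",
                           "mi_ids", "arm", "length")
  structure(
    list(
      version_label = as.character(version_label),
      records = records,
      dead_ids = unique(as.character(dead_ids)),
      species_set = sort(unique(records$species[!is.na(records$species)]))
    ),
    class = "mir_release"
  )
}

#' @export
print.mir_release <- function(x, ...) {
  cat("<mir_release> version ", x$version_label, ": ",
      nrow(x$records), " mature records, ",
      length(x$dead_ids), " dead accessions, species {",
      paste(x$species_set, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Validate a release against its structural invariants
#'
#' Violations are data, not exceptions: the return value is a tibble with one
#' row per violation, empty when the release is valid. Checked rules:
#' accession uniqueness, no accession both alive and dead, (species, name)
#' uniqueness, declared length equal to sequence length, sequence alphabet,
#' species prefix consistency, and arm/suffix consistency.
#'
#' @param release A `mir_release`.
#' @return Tibble with columns `mimat_id`, `rule`, `detail`.
#' @export
validate_release <- function(release) {
  stopifnot(inherits(release, "mir_release"))
  rec <- release$records
  v <- list()
  viol <- function(id, rule, detail) tibble::tibble(mimat_id = id, rule = rule, detail = detail)

  dup <- rec$mimat_id[duplicated(rec$mimat_id)]
  if (length(dup)) {
    v[[length(v) + 1L]] <- viol(unique(dup), "mimat_unique",
                                "accession appears more than once")
  }
  both <- intersect(rec$mimat_id, release$dead_ids)
  if (length(both)) {
    v[[length(v) + 1L]] <- viol(both, "alive_xor_dead",
                                "accession is both a live record and listed dead")
  }
  key <- paste(rec$species, rec$name, sep = "\r")
  dupname <- rec$mimat_id[duplicated(key) | duplicated(key, fromLast = TRUE)]
  dupname <- setdiff(dupname, dup)
  if (length(key[duplicated(key)])) {
    v[[length(v) + 1L]] <- viol(unique(dupname), "species_name_unique",
                                "duplicated (species, name) pair")
  }
  badlen <- rec$mimat_id[rec$length != nchar(rec$sequence)]
  if (length(badlen)) {
    v[[length(v) + 1L]] <- viol(badlen, "length_matches_sequence",
                                "length field differs from sequence length")
  }
  badalpha <- rec$mimat_id[stringr::str_detect(rec$sequence, "[^ACGU]")]
  if (length(badalpha)) {
    v[[length(v) + 1L]] <- viol(badalpha, "sequence_alphabet",
                                "sequence has characters outside {A,C,G,U}")
  }
  pre <- species_from_name(rec$name)
  badsp <- rec$mimat_id[!is.na(pre) & pre != rec$species]
  if (length(badsp)) {
    v[[length(v) + 1L]] <- viol(badsp, "species_prefix",
                                "species differs from the name prefix")
  }
  badarm <- rec$mimat_id[rec$arm != arm_from_name(rec$name)]
  if (length(badarm)) {
    v[[length(v) + 1L]] <- viol(badarm, "arm_from_suffix",
                                "arm inconsistent with the -5p/-3p name suffix")
  }
  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(mimat_id = character(), rule = character(), detail = character())
}

#' Construct an ordered series of releases
#'
#' Version labels are opaque strings: "10.1" and "21" do not order numerically,
#' so the caller's order (oldest to newest) is authoritative.
#'
#' @param releases List of `mir_release`, oldest first.
#' @return A `mir_version_index`: list with `releases` (named by label) and
#'   `order` (character vector of labels, oldest first).
#' @export
mir_version_index <- function(releases) {
  stopifnot(length(releases) >= 1L,
            all(purrr::map_lgl(releases, inherits, "mir_release")))
  labels <- purrr::map_chr(releases, "version_label")
  if (anyDuplicated(labels)) {
    rlang::abort("version labels must be unique within an index",
                 class = "mirharmony_format_error")
  }
  names(releases) <- labels
  structure(list(releases = releases, order = labels),
            class = "mir_version_index")
}

#' @export
print.mir_version_index <- function(x, ...) {
  cat("<mir_version_index> ", length(x$order), " releases: ",
      paste(x$order, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Infer dead accessions from presence/absence across a release series
#'
#' Real dead-entry lists are not always distributed per snapshot. When a
#' release carries no dead list, an accession present in an earlier release of
#' the series and absent later is inferred dead from the first absent release
#' onward. Releases that already carry dead lists are left untouched.
#'
#' @param index A `mir_version_index`.
#' @return A new `mir_version_index` with augmented `dead_ids`.
#' @export
infer_dead <- function(index) {
  stopifnot(inherits(index, "mir_version_index"))
  seen <- character()
  releases <- index$releases
  for (lab in index$order) {
    rel <- releases[[lab]]
    if (length(rel$dead_ids) == 0L) {
      gone <- setdiff(seen, rel$records$mimat_id)
      if (length(gone)) {
        releases[[lab]] <- mir_release(rel$records, rel$version_label, gone)
      }
    }
    seen <- union(seen, rel$records$mimat_id)
  }
  mir_version_index(unname(releases))
}

#' Construct a profiling platform
#'
#' A platform is a commercial miRNA detection probe set (microarray or
#' RT-qPCR): probes carry a vendor-reported miRNA name and the mature target
#' sequence the probe was designed against, referencing some miRBase version.
#' Control/housekeeping probes are flagged and excluded from all
#' sequence-keyed mapping.
#'
#' @param probes Data frame with columns `probe_id`, `reported_name`,
#'   `target_sequence`, and optionally `is_control` (default `FALSE`).
#' @param platform_id Platform identifier string.
#' @param vendor Vendor name.
#' @param design_version miRBase version label the vendor annotation
#'   referenced, or `NA` when unknown.
#' @param species_scope Character vector of species codes the platform
#'   covers; empty means unrestricted.
#' @return A `mir_platform` object.
#' @export
mir_platform <- function(probes, platform_id, vendor = "synthetic",
                         design_version = NA_character_,
                         species_scope = character()) {
  probes <- tibble::as_tibble(probes)
  required <- c("probe_id", "reported_name", "target_sequence")
  missing_cols <- setdiff(required, names(probes))
  if (length(missing_cols) > 0L) {
    rlang::abort(paste0("platform probes lack column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mirharmony_format_error")
  }
  if (!"is_control" %in% names(probes)) probes$is_control <- FALSE
  probes$is_control <- as.logical(probes$is_control)
  if (anyDuplicated(probes$probe_id)) {
    rlang::abort(paste0("duplicate probe_id within platform: ",
                        probes$probe_id[duplicated(probes$probe_id)][1L]),
                 class = "mirharmony_format_error")
  }
  probes$target_sequence <- if (nrow(probes))
    normalize_sequence(probes$target_sequence) else character()
  probes <- dplyr::select(probes, "probe_id", "reported_name",
                          "target_sequence", "is_control")
  structure(
    list(platform_id = as.character(platform_id),
         vendor = as.character(vendor),
         design_version = as.character(design_version),
         species_scope = as.character(species_scope),
         probes = probes),
    class = "mir_platform"
  )
}

#' @export
print.mir_platform <- function(x, ...) {
  cat("<mir_platform> ", x$platform_id, " (", x$vendor, "), design version ",
      x$design_version, ": ", nrow(x$probes), " probes (",
      sum(x$probes$is_control), " controls)\n", sep = "")
  invisible(x)
}
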