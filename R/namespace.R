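#' Build a namespace from a release or a platform
#'
#' A namespace is the unifying abstraction over any source of
#' (name, mature sequence) pairs: a species-scoped miRBase release or a
#' profiling platform. It supports bidirectional lookup — name to sequence and
#' sequence to names — and is the object all translation, overlap, update and
#' intersection functions operate on. Within one namespace a name maps to at
#' most one sequence; one sequence may legitimately carry several names
#' (identical matures from paralogous precursors).
#'
#' For a release, the namespace holds exactly the records of the requested
#' species, with MIMAT accessions attached to each sequence and the release's
#' dead-accession registry carried along. For a platform, one entry per
#' non-control probe; duplicate (name, sequence) probes collapse to a single
#' entry; a name reported with two different target sequences is a data
#' defect — such probes contribute nothing here and surface through
#' [curate_platform()] instead.
#'
#' @param x A `mir_release` or `mir_platform`.
#' @param species For releases: species code to scope to. A species absent
#'   from the release yields an empty namespace with a warning.
#' @param ... Passed to methods.
#' @return A `mir_namespace`: list with `label`, `kind` (`"release"` or
#'   `"platform"`), `species`, `source_version`, `table` (tibble of `name`,
#'   `sequence`, `accessions` list column), `dead_accessions`.
#' @export
build_namespace <- function(x, ...) UseMethod("build_namespace")

new_namespace <- function(label, kind, species, source_version, table,
                          dead_accessions = character()) {
  table <- dplyr::arrange(table, .data$name)
  structure(
    list(label = label, kind = kind, species = species,
         source_version = source_version, table = table,
         dead_accessions = dead_accessions),
    class = "mir_namespace"
  )
}

#' @rdname build_namespace
#' @export
build_namespace.mir_release <- function(x, species, ...) {
  stopifnot(is.character(species), length(species) == 1L)
  rec <- dplyr::filter(x$records, .data$species == !!species)
  if (nrow(rec) == 0L && !(species %in% x$species_set)) {
    rlang::warn(paste0("species '", species, "' not present in release ",
                       x$version_label, "; namespace is empty"))
  }
  tab <- tibble::tibble(
    name = rec$name,
    sequence = rec$sequence,
    accessions = purrr::map(rec$mimat_id, ~ .x)
  )
  new_namespace(
    label = paste0("mirbase:", x$version_label, ":", species),
    kind = "release", species = species, source_version = x$version_label,
    table = tab, dead_accessions = x$dead_ids
  )
}

#' @rdname build_namespace
#' @export
build_namespace.mir_platform <- function(x, ...) {
  pr <- dplyr::filter(x$probes, !.data$is_control)
  pr <- dplyr::distinct(pr, .data$reported_name, .data$target_sequence)
  # a name reported with >1 distinct sequences is a vendor defect: drop all
  conflicted <- pr |>
    dplyr::count(.data$reported_name) |>
    dplyr::filter(.data$n > 1L) |>
    dplyr::pull("reported_name")
  if (length(conflicted)) {
    rlang::warn(paste0("platform ", x$platform_id, ": ", length(conflicted),
                       " name(s) map to multiple sequences; excluded from the ",
                       "namespace (see curate_platform)"))
    pr <- dplyr::filter(pr, !.data$reported_name %in% conflicted)
  }
  tab <- tibble::tibble(
    name = pr$reported_name,
    sequence = pr$target_sequence,
    accessions = purrr::map(seq_len(nrow(pr)), ~ character())
  )
  sp <- if (length(x$species_scope) == 1L) x$species_scope else NA_character_
  new_namespace(
    label = paste0("platform:", x$platform_id),
    kind = "platform", species = sp, source_version = x$design_version,
    table = tab
  )
}

#' @export
print.mir_namespace <- function(x, ...) {
  cat("<mir_namespace> ", x$label, ": ", nrow(x$table), " names, ",
      dplyr::n_distinct(x$table$sequence), " sequence keys\n", sep = "")
  invisible(x)
}

#' @method tidy mir_namespace
#' @export
tidy.mir_namespace <- function(x, ...) {
  dplyr::mutate(x$table,
                accessions = purrr::map_chr(.data$accessions, paste, collapse = ","))
}

#' @method glance mir_namespace
#' @export
glance.mir_namespace <- function(x, ...) {
  tibble::tibble(
    label = x$label,
    kind = x$kind,
    n_names = nrow(x$table),
    n_sequences = dplyr::n_distinct(x$table$sequence),
    n_multi_name_sequences = sum(table(x$table$sequence) >= 2L),
    n_dead_accessions = length(x$dead_accessions)
  )
}

#' Look up all names carried by a mature sequence
#'
#' The query is normalized first, so DNA-alphabet or mixed-case input finds
#' RNA-alphabet entries. The returned order is lexicographic for
#' reproducibility.
#'
#' @param ns A `mir_namespace`.
#' @param sequence A single sequence string.
#' @return Character vector of names, possibly empty.
#' @export
lookup_names <- function(ns, sequence) {
  stopifnot(inherits(ns, "mir_namespace"))
  key <- normalize_sequence(sequence)
  sort(ns$table$name[ns$table$sequence == key])
}

ns_seq_of_name <- function(ns, name) {
  hit <- ns$table$sequence[ns$table$name == name]
  if (length(hit)) hit[1L] else NA_character_
}

ns_accessions_of_seq <- function(ns, sequence) {
  sel <- ns$table$sequence == sequence
  sort(unique(unlist(ns$table$accessions[sel])))
}

#' Check a platform annotation for name/sequence consistency
#'
#' The premise of sequence-keyed harmonization is that each source's
#' name-to-sequence correspondence is single-valued and agrees with the
#' miRBase release the vendor designed against. This function audits a
#' platform against the namespace of its design-version release and reports
#' every deviation as a finding; nothing is repaired silently.
#'
#' Finding kinds: `name_sequence_mismatch` (the reported name exists in the
#' reference but the probe's target sequence differs — a design or annotation
#' error), `unknown_name` (the reported name is absent from the reference),
#' `duplicate_probe_name` (the same name is reported with different target
#' sequences within the platform), `control_excluded` (control probes, noted
#' and excluded from mapping).
#'
#' @param platform A `mir_platform`.
#' @param reference A `mir_namespace` built from the platform's design-version
#'   release (`kind == "release"`).
#' @return A tibble of findings with columns `probe_id`, `finding_kind`,
#'   `detail`, `expected_sequence`, `observed_sequence`; class
#'   `mir_curation`.
#' @export
curate_platform <- function(platform, reference) {
  stopifnot(inherits(platform, "mir_platform"),
            inherits(reference, "mir_namespace"))
  if (reference$kind != "release") {
    rlang::abort("curation reference must be a release namespace",
                 class = "mirharmony_config_error")
  }
  pr <- platform$probes
  findings <- list()
  add <- function(probe_id, kind, detail, expected = "", observed = "") {
    tibble::tibble(probe_id = probe_id, finding_kind = kind, detail = detail,
                   expected_sequence = expected, observed_sequence = observed)
  }

  ctrl <- pr[pr$is_control, ]
  if (nrow(ctrl)) {
    findings[[length(findings) + 1L]] <- add(
      ctrl$probe_id, "control_excluded",
      paste0("control probe '", ctrl$reported_name,
             "' excluded from sequence-keyed mapping"))
  }

  live <- pr[!pr$is_control, ]
  if (nrow(live)) {
    dup_names <- live |>
      dplyr::distinct(.data$reported_name, .data$target_sequence) |>
      dplyr::count(.data$reported_name) |>
      dplyr::filter(.data$n > 1L) |>
      dplyr::pull("reported_name")
    dup <- live[live$reported_name %in% dup_names, ]
    if (nrow(dup)) {
      findings[[length(findings) + 1L]] <- add(
        dup$probe_id, "duplicate_probe_name",
        paste0("name '", dup$reported_name,
               "' reported with multiple target sequences"),
        observed = dup$target_sequence)
    }
    for (i in seq_len(nrow(live))) {
      nm <- live$reported_name[i]
      expected <- ns_seq_of_name(reference, nm)
      if (is.na(expected)) {
        findings[[length(findings) + 1L]] <- add(
          live$probe_id[i], "unknown_name",
          paste0("name '", nm, "' not found in ", reference$label),
          observed = live$target_sequence[i])
      } else if (expected != live$target_sequence[i]) {
        findings[[length(findings) + 1L]] <- add(
          live$probe_id[i], "name_sequence_mismatch",
          paste0("probe sequence differs from ", reference$label,
                 " sequence for '", nm, "'"),
          expected = expected, observed = live$target_sequence[i])
      }
    }
  }
  out <- if (length(findings)) dplyr::bind_rows(findings) else
    tibble::tibble(probe_id = character(), finding_kind = character(),
                   detail = character(), expected_sequence = character(),
                   observed_sequence = character())
  out <- dplyr::arrange(out, .data$probe_id, .data$finding_kind)
  class(out) <- c("mir_curation", class(out))
  out
}

#' Plot curation findings by kind
#'
#' @param object A `mir_curation` tibble from [curate_platform()].
#' @param ... Unused.
#' @return A ggplot bar chart of finding counts.
#' @method autoplot mir_curation
#' @export
autoplot.mir_curation <- function(object, ...) {
  dat <- dplyr::count(tibble::as_tibble(object), .data$finding_kind)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$finding_kind, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "finding kind", y = "probes",
                  title = "Platform curation findings") +
    ggplot2::theme_minimal()
}
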