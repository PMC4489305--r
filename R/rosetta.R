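#' Translate a miRNA name list between two namespaces
#'
#' The core harmonization step: each input name is resolved to its mature
#' sequence in the source namespace, and that sequence is looked up in the
#' destination namespace. Names are never compared across namespaces — only
#' sequences are, so renames between miRBase versions or vendor-specific
#' spellings are bridged transparently.
#'
#' Each input name gets exactly one output row (duplicated inputs included),
#' in input order, with a status:
#' \describe{
#'   \item{stable}{one destination name, identical to the input}
#'   \item{renamed}{one destination name, different from the input}
#'   \item{multiple}{two or more destination names share the sequence}
#'   \item{dead}{sequence absent from the destination and its source
#'     accession is in the destination's dead registry}
#'   \item{missing}{sequence absent from the destination, no evidence of
#'     retirement}
#'   \item{unrecognized}{input name absent from the source namespace
#'     (typical for control probes and non-miRNA annotations)}
#' }
#'
#' Matching is case-sensitive after whitespace trimming. With
#' `case_rescue = TRUE` a case-insensitive fallback is tried; when it rescues
#' a name uniquely the row is used and annotated in `note` (vendor files
#' differ in capitalization, e.g. "hsa-miR" vs "hsa-mir", but silent
#' case-folding would mask genuine mature-vs-precursor distinctions).
#'
#' @param names Character vector of miRNA names, or a data frame whose first
#'   column holds them.
#' @param src Source `mir_namespace`.
#' @param dst Destination `mir_namespace`.
#' @param delimiter Separator used to join multiple output names/accessions.
#' @param case_rescue Attempt a unique case-insensitive match for names not
#'   found verbatim in the source.
#' @return A tibble (class `mir_translation`) with columns `input_name`,
#'   `matched_sequence`, `status`, `output_names`, `output_accessions`,
#'   `note`.
#' @export
translate_names <- function(names, src, dst, delimiter = ";",
                            case_rescue = TRUE) {
  stopifnot(inherits(src, "mir_namespace"), inherits(dst, "mir_namespace"))
  if (is.data.frame(names)) names <- names[[1L]]
  names <- as.character(names)
  rows <- purrr::map(names, function(raw) {
    nm <- stringr::str_trim(raw)
    note <- ""
    seq <- ns_seq_of_name(src, nm)
    if (is.na(seq) && case_rescue) {
      hits <- unique(src$table$name[tolower(src$table$name) == tolower(nm)])
      if (length(hits) == 1L) {
        seq <- ns_seq_of_name(src, hits)
        note <- paste0("case-insensitive match to source name '", hits, "'")
      }
    }
    if (is.na(seq)) {
      return(tibble::tibble(
        input_name = raw, matched_sequence = "", status = "unrecognized",
        output_names = "", output_accessions = "",
        note = "name not found in source namespace"))
    }
    outs <- lookup_names(dst, seq)
    accs <- ns_accessions_of_seq(dst, seq)
    if (length(outs) == 0L) {
      src_accs <- ns_accessions_of_seq(src, seq)
      status <- if (length(src_accs) && any(src_accs %in% dst$dead_accessions))
        "dead" else "missing"
      extra <- if (status == "dead")
        "accession retired in destination" else
        "sequence absent from destination"
      note <- if (nzchar(note)) paste(note, extra, sep = "; ") else extra
      return(tibble::tibble(
        input_name = raw, matched_sequence = seq, status = status,
        output_names = "", output_accessions = "", note = note))
    }
    status <- if (length(outs) >= 2L) "multiple"
      else if (outs == nm) "stable" else "renamed"
    tibble::tibble(
      input_name = raw, matched_sequence = seq, status = status,
      output_names = paste(outs, collapse = delimiter),
      output_accessions = paste(accs, collapse = delimiter),
      note = note)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(input_name = character(), matched_sequence = character(),
                   status = character(), output_names = character(),
                   output_accessions = character(), note = character())
  class(out) <- c("mir_translation", class(out))
  out
}

#' Expand multi-name translation rows to long format
#'
#' One row per (input name, output name) pair; rows without output names are
#' kept with an empty `output_name`.
#'
#' @param result A `mir_translation` tibble.
#' @param delimiter The delimiter used when the result was built.
#' @return A long-format tibble with column `output_name`.
#' @export
explode_translation <- function(result, delimiter = ";") {
  tibble::as_tibble(result) |>
    dplyr::mutate(output_name = stringr::str_split(.data$output_names,
                                                   stringr::fixed(delimiter))) |>
    tidyr::unnest_longer("output_name", keep_empty = TRUE) |>
    dplyr::mutate(output_name = dplyr::coalesce(.data$output_name, "")) |>
    dplyr::select(-"output_names")
}

#' @method glance mir_translation
#' @export
glance.mir_translation <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x),
    n_stable = sum(x$status == "stable"),
    n_renamed = sum(x$status == "renamed"),
    n_multiple = sum(x$status == "multiple"),
    n_dead = sum(x$status == "dead"),
    n_missing = sum(x$status == "missing"),
    n_unrecognized = sum(x$status == "unrecognized")
  )
}

#' Plot translation status composition
#'
#' @param object A `mir_translation` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of row counts per status.
#' @method autoplot mir_translation
#' @export
autoplot.mir_translation <- function(object, ...) {
  lv <- c("stable", "renamed", "multiple", "dead", "missing", "unrecognized")
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(status = factor(.data$status, levels = lv)) |>
    dplyr::count(.data$status, .drop = FALSE)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$status, y = .data$n,
                                    fill = .data$status)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "names",
                  title = "Translation outcome by status") +
    ggplot2::theme_minimal()
}

#' Sequence-keyed overlap of two namespaces
#'
#' Reports the mature sequences present in both namespaces regardless of name
#' variation, with the names each side uses for them. Useful to compare the
#' detection repertoire of two platforms, the miRBase coverage of a platform,
#' or sequence conservation between two miRBase versions.
#'
#' @param a,b `mir_namespace` objects.
#' @param delimiter Separator joining names on each side.
#' @return Tibble with columns `sequence`, `names_a`, `names_b`, sorted by
#'   sequence.
#' @export
overlap_namespaces <- function(a, b, delimiter = ";") {
  stopifnot(inherits(a, "mir_namespace"), inherits(b, "mir_namespace"))
  shared <- sort(intersect(unique(a$table$sequence), unique(b$table$sequence)))
  tibble::tibble(
    sequence = shared,
    names_a = purrr::map_chr(shared, ~ paste(lookup_names(a, .x), collapse = delimiter)),
    names_b = purrr::map_chr(shared, ~ paste(lookup_names(b, .x), collapse = delimiter))
  )
}

check_matrix <- function(m, arg = "matrix") {
  m <- tibble::as_tibble(m)
  if (ncol(m) < 1L) {
    rlang::abort(paste0(arg, " must have a miRNA name column"),
                 class = "mirharmony_format_error")
  }
  samples <- names(m)[-1L]
  if (anyDuplicated(samples)) {
    rlang::abort(paste0(arg, ": duplicate sample id '",
                        samples[duplicated(samples)][1L], "'"),
                 class = "mirharmony_format_error")
  }
  m
}

#' Update the annotation of an expression matrix
#'
#' Re-annotates the rows of an expression matrix (miRNA rows by sample
#' columns) from a source namespace to a destination namespace, carrying the
#' expression values over unchanged. Every input row yields exactly one
#' output record, in input order; rows that cannot be translated are retained
#' with their diagnostic status rather than dropped, optionally sorted to the
#' bottom.
#'
#' @param m Data frame: first column miRNA names, remaining columns samples.
#' @param src,dst Source and destination `mir_namespace`.
#' @param failures_last Sort rows with no destination name (dead, missing,
#'   unrecognized) to the bottom, preserving relative order otherwise.
#' @param delimiter,case_rescue Passed to [translate_names()].
#' @return Tibble (class `mir_translation`): translation columns followed by
#'   the carried sample columns.
#' @export
update_matrix <- function(m, src, dst, failures_last = FALSE, delimiter = ";",
                          case_rescue = TRUE) {
  m <- check_matrix(m, "expression matrix")
  tr <- translate_names(m[[1L]], src, dst, delimiter = delimiter,
                        case_rescue = case_rescue)
  out <- dplyr::bind_cols(tr, m[, -1L, drop = FALSE])
  if (failures_last) {
    out <- out[order(out$output_names == "", method = "radix"), , drop = FALSE]
  }
  class(out) <- c("mir_translation", setdiff(class(out), "mir_translation"))
  out
}

resolve_rows <- function(m, ns, case_rescue) {
  nm <- stringr::str_trim(as.character(m[[1L]]))
  purrr::map_chr(nm, function(x) {
    s <- ns_seq_of_name(ns, x)
    if (is.na(s) && case_rescue) {
      hits <- unique(ns$table$name[tolower(ns$table$name) == tolower(x)])
      if (length(hits) == 1L) s <- ns_seq_of_name(ns, hits)
    }
    if (is.na(s)) "" else s
  })
}

#' Sequence-keyed intersection of two expression matrices
#'
#' Builds a joined matrix over the mature sequences present in both data
#' sets, regardless of any name changes between their annotations, with the
#' expression values of both carried over unchanged (samples of A first, then
#' samples of B). Rows of either input that do not resolve to a sequence, or
#' whose sequence is not shared, are listed in a side report with
#' translation-style statuses.
#'
#' @param m_a,m_b Expression matrices (first column miRNA names).
#' @param ns_a,ns_b Namespaces annotating the rows of `m_a` / `m_b`.
#' @param dst Destination namespace used to annotate the joined rows.
#' @param prefix Optional length-2 character vector `c(a=, b=)` prepended to
#'   sample ids to disambiguate. A sample-id clash without prefixing is a
#'   configuration error.
#' @param delimiter,case_rescue As in [translate_names()].
#' @return A `mir_intersection`: list with `result` (tibble: `sequence`,
#'   `output_names`, `output_accessions`, sample columns) and `side_report`
#'   (tibble: `source`, `input_name`, `matched_sequence`, `status`, `note`).
#' @export
intersect_matrices <- function(m_a, ns_a, m_b, ns_b, dst, prefix = NULL,
                               delimiter = ";", case_rescue = TRUE) {
  stopifnot(inherits(ns_a, "mir_namespace"), inherits(ns_b, "mir_namespace"),
            inherits(dst, "mir_namespace"))
  m_a <- check_matrix(m_a, "matrix A")
  m_b <- check_matrix(m_b, "matrix B")
  if (!is.null(prefix)) {
    stopifnot(length(prefix) == 2L)
    names(m_a)[-1L] <- paste0(prefix[[1L]], names(m_a)[-1L])
    names(m_b)[-1L] <- paste0(prefix[[2L]], names(m_b)[-1L])
  }
  clash <- intersect(names(m_a)[-1L], names(m_b)[-1L])
  if (length(clash)) {
    rlang::abort(paste0("sample id '", clash[1L],
                        "' appears in both matrices; supply `prefix`"),
                 class = "mirharmony_config_error")
  }
  seq_a <- resolve_rows(m_a, ns_a, case_rescue)
  seq_b <- resolve_rows(m_b, ns_b, case_rescue)
  shared <- sort(intersect(setdiff(unique(seq_a), ""),
                           setdiff(unique(seq_b), "")))

  take_first <- function(seqs) match(shared, seqs)
  ia <- take_first(seq_a)
  ib <- take_first(seq_b)
  result <- tibble::tibble(
    sequence = shared,
    output_names = purrr::map_chr(shared, ~ paste(lookup_names(dst, .x),
                                                  collapse = delimiter)),
    output_accessions = purrr::map_chr(shared,
      ~ paste(ns_accessions_of_seq(dst, .x), collapse = delimiter))
  )
  result <- dplyr::bind_cols(result,
                             m_a[ia, -1L, drop = FALSE],
                             m_b[ib, -1L, drop = FALSE])

  side <- function(m, seqs, used_rows, src_ns, tag) {
    keep <- setdiff(seq_len(nrow(m)), used_rows[!is.na(used_rows)])
    purrr::map(keep, function(i) {
      s <- seqs[i]
      nm <- as.character(m[[1L]][i])
      if (s == "") {
        tibble::tibble(source = tag, input_name = nm, matched_sequence = "",
                       status = "unrecognized",
                       note = "name not found in its namespace")
      } else if (s %in% shared) {
        tr <- translate_names(nm, src_ns, dst, delimiter = delimiter,
                              case_rescue = case_rescue)
        tibble::tibble(source = tag, input_name = nm, matched_sequence = s,
                       status = tr$status[1L],
                       note = "duplicate sequence within this matrix; first occurrence kept")
      } else {
        tr <- translate_names(nm, src_ns, dst, delimiter = delimiter,
                              case_rescue = case_rescue)
        tibble::tibble(source = tag, input_name = nm, matched_sequence = s,
                       status = tr$status[1L],
                       note = "sequence not shared with the other matrix")
      }
    }) |> dplyr::bind_rows()
  }
  empty_side <- tibble::tibble(source = character(), input_name = character(),
                               matched_sequence = character(),
                               status = character(), note = character())
  side_report <- dplyr::bind_rows(
    empty_side,
    side(m_a, seq_a, ia, ns_a, "a"),
    side(m_b, seq_b, ib, ns_b, "b")
  )
  structure(list(result = result, side_report = side_report),
            class = "mir_intersection")
}

#' @export
print.mir_intersection <- function(x, ...) {
  cat("<mir_intersection> ", nrow(x$result), " shared sequences, ",
      nrow(x$side_report), " unmatched input rows\n", sep = "")
  invisible(x)
}

#' @method tidy mir_intersection
#' @export
tidy.mir_intersection <- function(x, ...) x$result

#' @method glance mir_intersection
#' @export
glance.mir_intersection <- function(x, ...) {
  tibble::tibble(
    n_shared = nrow(x$result),
    n_unmatched = nrow(x$side_report),
    n_samples = ncol(x$result) - 3L
  )
}

#' Plot the size of a matrix intersection
#'
#' @param object A `mir_intersection`.
#' @param ... Unused.
#' @return A ggplot bar chart: shared rows vs unmatched rows per source.
#' @method autoplot mir_intersection
#' @export
autoplot.mir_intersection <- function(object, ...) {
  dat <- dplyr::bind_rows(
    tibble::tibble(class = "shared", n = nrow(object$result)),
    dplyr::count(object$side_report, .data$source) |>
      dplyr::transmute(class = paste0("unmatched (", .data$source, ")"),
                       n = .data$n)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$class, y = .data$n)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "rows", title = "Intersection outcome") +
    ggplot2::theme_minimal()
}
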