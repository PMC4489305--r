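#' Package configuration defaults
#'
#' @param version_order Ordered version labels, oldest first. The default is
#'   the classic release ladder "10.0" through "21"; labels are opaque
#'   strings ordered by this list, never parsed numerically ("10.1" and "21"
#'   do not order numerically).
#' @param default_species Default species code (`"hsa"`, Homo sapiens).
#' @param multi_name_delimiter Separator for multi-name output fields.
#' @param failures_last Sort untranslatable matrix rows to the bottom.
#' @param case_rescue Enable the unique case-insensitive fallback match.
#' @return A `mir_config` list.
#' @export
mir_config <- function(version_order = c("10.0", "10.1", "11.0", "12.0",
                                         "13.0", "14.0", "15", "16", "17",
                                         "18", "19", "20", "21"),
                       default_species = "hsa",
                       multi_name_delimiter = ";",
                       failures_last = FALSE,
                       case_rescue = TRUE) {
  if (anyDuplicated(version_order)) {
    rlang::abort("version_order labels must be unique",
                 class = "mirharmony_config_error")
  }
  structure(list(version_order = version_order,
                 default_species = default_species,
                 multi_name_delimiter = multi_name_delimiter,
                 failures_last = failures_last,
                 case_rescue = case_rescue),
            class = "mir_config")
}

release_tsv_cols <- c("version", "species", "mi_ids", "mimat_id", "name",
                      "sequence", "dead")

#' Read / write a release in the canonical TSV interchange format
#'
#' Tab-separated with header; columns `version`, `species`, `mi_ids`
#' (comma-joined precursor accessions), `mimat_id`, `name`, `sequence`,
#' `dead` (0/1). Rows with `dead == 1` populate the release's dead-accession
#' registry instead of its live records. Round trips are lossless.
#'
#' @param path File path.
#' @return `read_release_tsv()`: a `mir_release`.
#' @export
read_release_tsv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path),
                 class = "mirharmony_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing_cols <- setdiff(release_tsv_cols, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("release TSV lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mirharmony_format_error")
  }
  dead <- df$mimat_id[df$dead == "1"]
  live <- df[df$dead != "1", , drop = FALSE]
  version <- if (nrow(df)) df$version[1L] else "unknown"
  rel <- mir_release(
    tibble::tibble(mimat_id = live$mimat_id, name = live$name,
                   sequence = live$sequence, species = live$species,
                   mi_ids = live$mi_ids),
    version_label = version, dead_ids = dead)
  bad <- validate_release(rel)
  if (nrow(bad)) {
    rlang::abort(paste0("release TSV fails validation: ",
                        bad$rule[1L], " (", bad$mimat_id[1L], ")"),
                 class = "mirharmony_format_error")
  }
  rel
}

#' @rdname read_release_tsv
#' @param release A `mir_release`.
#' @return `write_release_tsv()`: `path`, invisibly.
#' @export
write_release_tsv <- function(release, path) {
  stopifnot(inherits(release, "mir_release"))
  rec <- release$records
  live <- tibble::tibble(
    version = rep(release$version_label, nrow(rec)),
    species = rec$species,
    mi_ids = purrr::map_chr(rec$mi_ids, paste, collapse = ","),
    mimat_id = rec$mimat_id, name = rec$name, sequence = rec$sequence,
    dead = rep("0", nrow(rec)))
  deadrows <- tibble::tibble(
    version = rep(release$version_label, length(release$dead_ids)),
    species = "", mi_ids = "", mimat_id = release$dead_ids, name = "",
    sequence = "", dead = "1")
  readr::write_tsv(dplyr::bind_rows(live, deadrows), path, progress = FALSE)
  invisible(path)
}

#' Read / write the mature FASTA dialect
#'
#' Release mature-sequence files use headers of the form
#' `>hsa-miR-21-5p MIMAT0000076 Homo sapiens miR-21-5p`: name, MIMAT
#' accession, then free text. The species code is derived from the name
#' prefix. Sequences are normalized on read (releases ship the RNA
#' alphabet). Only records are recovered — the dead list travels separately,
#' so the result is a partial release.
#'
#' @param path File path.
#' @param version_label Version label to stamp on the resulting release.
#' @return `read_mature_fasta()`: a `mir_release` (records only, no dead
#'   list).
#' @export
read_mature_fasta <- function(path, version_label) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "mirharmony_io_error")
  }
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    return(mir_release(tibble::tibble(mimat_id = character(),
                                      name = character(),
                                      sequence = character()),
                       version_label))
  }
  headers <- names(seqs)
  toks <- stringr::str_split(headers, "\\s+")
  mimat <- purrr::map_chr(toks, function(tk) {
    hit <- tk[stringr::str_detect(tk, "^MIMAT\\d+$")]
    if (length(hit)) hit[1L] else NA_character_
  })
  if (anyNA(mimat)) {
    line <- which(is.na(mimat))[1L]
    rlang::abort(paste0("FASTA header ", line, " ('", headers[line],
                        "') lacks a MIMAT accession"),
                 class = "mirharmony_format_error")
  }
  nm <- purrr::map_chr(toks, 1L)
  mir_release(tibble::tibble(mimat_id = mimat, name = nm,
                             sequence = as.character(seqs)),
              version_label)
}

#' @rdname read_mature_fasta
#' @param release A `mir_release`.
#' @return `write_mature_fasta()`: `path`, invisibly.
#' @export
write_mature_fasta <- function(release, path) {
  stopifnot(inherits(release, "mir_release"))
  rec <- release$records
  seqs <- Biostrings::RNAStringSet(rec$sequence)
  names(seqs) <- paste(rec$name, rec$mimat_id)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

platform_csv_cols <- c("platform_id", "vendor", "design_version", "probe_id",
                       "reported_name", "target_sequence", "is_control")

#' Read / write a platform annotation CSV
#'
#' Columns: `platform_id`, `vendor`, `design_version`, `probe_id`,
#' `reported_name`, `target_sequence`, `is_control` (0/1). Vendor files may
#' carry the DNA alphabet; T is normalized to U on read. Duplicate probe ids
#' are a format error.
#'
#' @param path File path.
#' @return `read_platform_csv()`: a `mir_platform`.
#' @export
read_platform_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "mirharmony_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  missing_cols <- setdiff(platform_csv_cols, names(df))
  if (length(missing_cols)) {
    rlang::abort(paste0("platform CSV lacks column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "mirharmony_format_error")
  }
  if (nrow(df) == 0L) {
    rlang::abort("platform CSV has no probe rows",
                 class = "mirharmony_format_error")
  }
  species <- unique(species_from_name(df$reported_name[df$is_control == "0"]))
  species <- species[!is.na(species)]
  mir_platform(
    tibble::tibble(probe_id = df$probe_id, reported_name = df$reported_name,
                   target_sequence = df$target_sequence,
                   is_control = df$is_control == "1"),
    platform_id = df$platform_id[1L], vendor = df$vendor[1L],
    design_version = df$design_version[1L], species_scope = species)
}

#' @rdname read_platform_csv
#' @param platform A `mir_platform`.
#' @return `write_platform_csv()`: `path`, invisibly.
#' @export
write_platform_csv <- function(platform, path) {
  stopifnot(inherits(platform, "mir_platform"))
  pr <- platform$probes
  out <- tibble::tibble(
    platform_id = rep(platform$platform_id, nrow(pr)),
    vendor = rep(platform$vendor, nrow(pr)),
    design_version = rep(platform$design_version, nrow(pr)),
    probe_id = pr$probe_id, reported_name = pr$reported_name,
    target_sequence = pr$target_sequence,
    is_control = ifelse(pr$is_control, "1", "0"))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

matrix_delim <- function(path) {
  if (stringr::str_ends(tolower(path), stringr::fixed(".csv"))) "," else "\t"
}

#' Read / write an expression matrix
#'
#' First column miRNA names, header row sample ids. The delimiter is sniffed
#' from the extension: `.csv` comma, `.tsv`/`.txt` tab. Ragged rows are a
#' format error reporting the first bad line.
#'
#' @param path File path.
#' @return `read_matrix()`: tibble, first column `mirna`.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "mirharmony_io_error")
  }
  df <- suppressWarnings(
    readr::read_delim(path, delim = matrix_delim(path), progress = FALSE,
                      col_types = readr::cols(.default = "c"),
                      show_col_types = FALSE))
  pb <- readr::problems(df)
  if (nrow(pb)) {
    rlang::abort(paste0("malformed matrix at line ", pb$row[1L], ": ",
                        pb$expected[1L], " expected, ", pb$actual[1L], " found"),
                 class = "mirharmony_format_error")
  }
  names(df)[1L] <- "mirna"
  df[-1L] <- lapply(df[-1L], as.numeric)
  check_matrix(df, path)
}

#' @rdname read_matrix
#' @param m Matrix tibble (first column names, rest samples).
#' @return `write_matrix()`: `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  readr::write_delim(tibble::as_tibble(m), path, delim = matrix_delim(path),
                     progress = FALSE)
  invisible(path)
}

#' Read a plain miRNA name list
#'
#' Names separated by whitespace or newlines, one file, no header.
#'
#' @param path File path.
#' @return Character vector of names.
#' @export
read_name_list <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such file: ", path), class = "mirharmony_io_error")
  }
  scan(path, what = character(), quiet = TRUE)
}

#' Write a translation/update result table
#'
#' Frozen column order: `input_name`, `matched_sequence`, `status`,
#' `output_names`, `output_accessions`, `note`, then one column per carried
#' sample, as CSV. Downstream scripts can rely on this layout.
#'
#' @param result A `mir_translation` tibble.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path) {
  fixed <- c("input_name", "matched_sequence", "status", "output_names",
             "output_accessions", "note")
  stopifnot(all(fixed %in% names(result)))
  extra <- setdiff(names(result), fixed)
  readr::write_csv(tibble::as_tibble(result)[, c(fixed, extra)], path,
                   progress = FALSE)
  invisible(path)
}

#' Write a track table for a set of accessions
#'
#' Columns: `mimat_id`, `mi_ids`, `species`, `current_name`,
#' `current_sequence`, `arm`, `length`, then one column per release holding
#' the name at that release, `"-"` before introduction and `"DEAD"` after
#' deletion.
#'
#' @param history A `mir_history`.
#' @param path File path.
#' @param tracks Subset of `history$tracks` to write (default all).
#' @return `path`, invisibly.
#' @export
write_tracks <- function(history, path, tracks = NULL) {
  stopifnot(inherits(history, "mir_history"))
  if (is.null(tracks)) tracks <- history$tracks
  tracks <- tracks[, c("mimat_id", "mi_ids", "species", "current_name",
                       "current_sequence", "arm", "length"), drop = FALSE]
  labs <- history$order
  nbv <- history$names_by_version
  percol <- purrr::map(labs, function(lab) {
    m <- nbv[nbv$version_label == lab, , drop = FALSE]
    nm <- m$name[match(tracks$mimat_id, m$mimat_id)]
    # absent: before introduction "-", after last presence "DEAD"
    last_ord <- tapply(match(nbv$version_label, labs), nbv$mimat_id, max)
    first_ord <- tapply(match(nbv$version_label, labs), nbv$mimat_id, min)
    k <- match(lab, labs)
    fo <- first_ord[tracks$mimat_id]
    lo <- last_ord[tracks$mimat_id]
    ifelse(!is.na(nm), nm, ifelse(k < fo, "-", ifelse(k > lo, "DEAD", "-")))
  })
  names(percol) <- labs
  out <- dplyr::bind_cols(tracks, tibble::as_tibble(percol))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
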