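#' Reconstruct per-accession name histories across a release series
#'
#' Walks the ordered release series and, for every MIMAT accession ever
#' observed, builds a chronological track of events: `introduced` (first
#' appearance; entries already alive in the earliest loaded release are
#' flagged `pre_series`), `renamed` (same accession, different name in
#' consecutive loaded releases), `deleted` (presence followed by absence, or
#' membership in a release's dead registry), `sequence_changed` (same
#' accession, different mature sequence). An accession absent from an
#' intermediate release but present later is treated as deleted then
#' reinstated (a second `introduced` event), reflecting what the loaded
#' snapshots literally say.
#'
#' History is keyed on the accession, not the sequence: sequences themselves
#' can change between releases, while the accession is the repository's
#' stable handle.
#'
#' @param index A `mir_version_index`, oldest release first.
#' @param species Species code to restrict to, or `"all"`.
#' @return A `mir_history`: list with `order` (version labels), `events`
#'   (tibble: `mimat_id`, `version_label`, `kind`, `old_name`, `new_name`,
#'   `sequence_at_version`, `pre_series`), `tracks` (one row per accession:
#'   `mimat_id`, `mi_ids`, `species`, `current_name`, `current_sequence`,
#'   `arm`, `length`, `alive`), and `names_by_version` (tibble: `mimat_id`,
#'   `version_label`, `name`, `sequence`).
#' @export
build_history <- function(index, species = "all") {
  stopifnot(inherits(index, "mir_version_index"))
  labs <- index$order
  snap <- purrr::map(labs, function(lab) {
    rec <- index$releases[[lab]]$records
    if (species != "all") rec <- rec[rec$species %in% species, , drop = FALSE]
    rec
  })
  names(snap) <- labs
  dead_reg <- purrr::map(labs, ~ index$releases[[.x]]$dead_ids)
  names(dead_reg) <- labs

  events <- list()
  push <- function(mimat, lab, kind, old_name = "", new_name = "",
                   seq = "", pre = FALSE) {
    events[[length(events) + 1L]] <<- tibble::tibble(
      mimat_id = mimat, version_label = lab, kind = kind, old_name = old_name,
      new_name = new_name, sequence_at_version = seq, pre_series = pre)
  }

  alive <- list()   # mimat -> list(name, sequence)
  ever_seen <- character()
  first <- TRUE
  for (lab in labs) {
    rec <- snap[[lab]]
    here <- rlang::set_names(seq_len(nrow(rec)), rec$mimat_id)
    # deletions: previously alive, now absent or listed dead
    for (mimat in names(alive)) {
      gone <- !(mimat %in% names(here)) || mimat %in% dead_reg[[lab]]
      if (gone) {
        push(mimat, lab, "deleted", old_name = alive[[mimat]]$name)
        alive[[mimat]] <- NULL
      }
    }
    for (i in seq_len(nrow(rec))) {
      mimat <- rec$mimat_id[i]
      if (mimat %in% dead_reg[[lab]]) next
      if (!mimat %in% names(alive)) {
        push(mimat, lab, "introduced", new_name = rec$name[i],
             seq = rec$sequence[i], pre = first && !(mimat %in% ever_seen))
        alive[[mimat]] <- list(name = rec$name[i], sequence = rec$sequence[i])
      } else {
        prev <- alive[[mimat]]
        if (prev$name != rec$name[i]) {
          push(mimat, lab, "renamed", old_name = prev$name,
               new_name = rec$name[i], seq = rec$sequence[i])
        }
        if (prev$sequence != rec$sequence[i]) {
          push(mimat, lab, "sequence_changed", old_name = prev$name,
               new_name = rec$name[i], seq = rec$sequence[i])
        }
        alive[[mimat]] <- list(name = rec$name[i], sequence = rec$sequence[i])
      }
    }
    ever_seen <- union(ever_seen, rec$mimat_id)
    first <- FALSE
  }
  events <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(mimat_id = character(), version_label = character(),
                   kind = character(), old_name = character(),
                   new_name = character(), sequence_at_version = character(),
                   pre_series = logical())
  events <- events[order(match(events$version_label, labs),
                         events$mimat_id), , drop = FALSE]

  nbv <- purrr::imap(snap, function(rec, lab) {
    tibble::tibble(mimat_id = rec$mimat_id, version_label = lab,
                   name = rec$name, sequence = rec$sequence)
  }) |> dplyr::bind_rows()

  last_state <- nbv |>
    dplyr::mutate(ord = match(.data$version_label, labs)) |>
    dplyr::group_by(.data$mimat_id) |>
    dplyr::slice_max(.data$ord, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  all_rec <- dplyr::bind_rows(snap)
  meta <- all_rec |>
    dplyr::group_by(.data$mimat_id) |>
    dplyr::summarise(
      mi_ids = paste(sort(unique(unlist(.data$mi_ids))), collapse = ","),
      species = dplyr::last(.data$species),
      .groups = "drop")
  tracks <- last_state |>
    dplyr::left_join(meta, by = "mimat_id") |>
    dplyr::mutate(
      alive = purrr::map_lgl(.data$mimat_id, ~ .x %in% names(alive)),
      current_name = dplyr::if_else(.data$alive, .data$name, ""),
      current_sequence = .data$sequence,
      arm = arm_from_name(.data$name),
      length = nchar(.data$sequence)) |>
    dplyr::select("mimat_id", "mi_ids", "species", "current_name",
                  "current_sequence", "arm", "length", "alive") |>
    dplyr::arrange(.data$mimat_id)

  structure(list(order = labs, events = events, tracks = tracks,
                 names_by_version = nbv),
            class = "mir_history")
}

#' @export
print.mir_history <- function(x, ...) {
  cat("<mir_history> ", nrow(x$tracks), " accessions across ",
      length(x$order), " releases (", paste(range(x$order), collapse = " .. "),
      "); ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' @method tidy mir_history
#' @export
tidy.mir_history <- function(x, ...) x$events

#' @method glance mir_history
#' @export
glance.mir_history <- function(x, ...) {
  tibble::tibble(
    n_accessions = nrow(x$tracks),
    n_releases = length(x$order),
    n_introduced = sum(x$events$kind == "introduced"),
    n_renamed = sum(x$events$kind == "renamed"),
    n_deleted = sum(x$events$kind == "deleted"),
    n_sequence_changed = sum(x$events$kind == "sequence_changed"),
    n_alive = sum(x$tracks$alive)
  )
}

#' Plot a name-history timeline
#'
#' Tiles one row per accession, one column per release, coloured by the event
#' occurring there (or "carried" when the entry persists unchanged).
#'
#' @param object A `mir_history`.
#' @param ... Unused.
#' @return A ggplot tile chart.
#' @method autoplot mir_history
#' @export
autoplot.mir_history <- function(object, ...) {
  grid <- tidyr::expand_grid(mimat_id = object$tracks$mimat_id,
                             version_label = object$order)
  ev <- object$events |>
    dplyr::group_by(.data$mimat_id, .data$version_label) |>
    dplyr::summarise(kind = paste(sort(.data$kind), collapse = "+"),
                     .groups = "drop")
  present <- dplyr::select(object$names_by_version, "mimat_id", "version_label") |>
    dplyr::mutate(present = TRUE)
  dat <- grid |>
    dplyr::left_join(ev, by = c("mimat_id", "version_label")) |>
    dplyr::left_join(present, by = c("mimat_id", "version_label")) |>
    dplyr::mutate(
      state = dplyr::case_when(
        !is.na(.data$kind) ~ .data$kind,
        !is.na(.data$present) ~ "carried",
        .default = "absent"),
      version_label = factor(.data$version_label, levels = object$order))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$version_label, y = .data$mimat_id,
                                    fill = .data$state)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::labs(x = "release", y = NULL, fill = "event",
                  title = "miRNA name history across releases") +
    ggplot2::theme_minimal()
}

#' Query name histories by current or former name
#'
#' Stringent mode (the default) matches by exact whole-name equality against
#' any name the entry ever bore at or after `start_version`; relaxed mode
#' retrieves every entry whose any-version name contains the query string,
#' case-insensitively. Queries lacking a species prefix (e.g. `"miR-21"`)
#' match that name under any prefix when `species = "all"`, and under the
#' selected species prefix otherwise.
#'
#' @param history A `mir_history` from [build_history()].
#' @param query Search string.
#' @param stringent Exact whole-name match (`TRUE`) or case-insensitive
#'   substring containment (`FALSE`).
#' @param species Species code filter, or `"all"`.
#' @param start_version Only names borne at or after this release are
#'   matched; default the earliest loaded release. Unknown labels are an
#'   error.
#' @return The matching rows of `history$tracks` (tibble), sorted by
#'   accession.
#' @export
time_warp_query <- function(history, query, stringent = TRUE,
                            species = "all", start_version = NULL) {
  stopifnot(inherits(history, "mir_history"))
  labs <- history$order
  if (is.null(start_version)) start_version <- labs[1L]
  k <- match(start_version, labs)
  if (is.na(k)) {
    rlang::abort(paste0("unknown start version '", start_version, "'"),
                 class = "mirharmony_unknown_version")
  }
  nbv <- history$names_by_version
  nbv <- nbv[match(nbv$version_label, labs) >= k, , drop = FALSE]
  query <- stringr::str_trim(query)
  if (stringent) {
    unprefixed <- is.na(species_from_name(query))
    if (unprefixed) {
      if (species == "all") {
        hit <- stringr::str_remove(nbv$name, "^[a-z]{3,4}-") == query
      } else {
        hit <- nbv$name == paste0(species, "-", query)
      }
    } else {
      hit <- nbv$name == query
    }
  } else {
    hit <- stringr::str_detect(tolower(nbv$name), stringr::fixed(tolower(query)))
  }
  ids <- unique(nbv$mimat_id[hit])
  out <- history$tracks[history$tracks$mimat_id %in% ids, , drop = FALSE]
  if (species != "all") out <- out[out$species %in% species, , drop = FALSE]
  dplyr::arrange(out, .data$mimat_id)
}

#' Which platforms can detect a given miRNA
#'
#' A platform detects an entry when one of its non-control probes targets
#' exactly the entry's current mature sequence and the platform's species
#' scope (when declared) covers the entry's species.
#'
#' @param track One row of `history$tracks` (or a list with
#'   `current_sequence`, `species`, `alive`).
#' @param registry List of `mir_platform` objects.
#' @return Sorted character vector of platform ids; empty (with a message)
#'   for deleted entries.
#' @export
detecting_platforms <- function(track, registry) {
  if (is.data.frame(track)) {
    stopifnot(nrow(track) == 1L)
    track <- as.list(track)
  }
  if (!isTRUE(track$alive) || !nzchar(track$current_sequence %||% "")) {
    rlang::inform("entry is deleted or has no current sequence; no platform can detect it")
    return(character(0))
  }
  key <- normalize_sequence(track$current_sequence)
  hits <- purrr::keep(registry, function(p) {
    if (length(p$species_scope) && !is.na(track$species) &&
        !(track$species %in% p$species_scope)) return(FALSE)
    any(!p$probes$is_control & p$probes$target_sequence == key)
  })
  sort(purrr::map_chr(hits, "platform_id"))
}
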