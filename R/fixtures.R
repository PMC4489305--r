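#' Specify a synthetic release series
#'
#' The generator emulates the raw material of nomenclature harmonization: an
#' ordered series of release snapshots in which entries are added, renamed,
#' deleted, mutated, or collide on sequence, together with the exact scripted
#' event log that produced them. The log is the ground truth that history
#' reconstruction and translation are tested against.
#'
#' Two modes share one spec. With `counts` (scripted mode) the per-step event
#' counts are fixed and targets are chosen by a deterministic rule — alive
#' records sorted by accession, deletions taken from the tail, then renames,
#' then sequence changes — so a given spec always names the same entries.
#' With `*_rate` probabilities (stochastic mode) each alive record is
#' independently renamed/deleted/mutated per step and additions are
#' binomially drawn; target choice is seeded-random. Sequence collisions are
#' always constructed by copying (never left to chance: accidental identical
#' 19–25-mers are negligible, and tests need scripted ones) and are injected
#' at the final step as a pair of fresh entries sharing one number with `a`/
#' `b` letter suffixes.
#'
#' Synthetic sequences are uniform over {A,C,G,U} with lengths 19–25 nt, the
#' canonical mature-miRNA length range. The synthetic species code `"syn"`
#' guarantees fixtures can never be mistaken for real annotation.
#'
#' @param seed Integer seed; same seed, same output, byte for byte.
#' @param n_versions Number of releases in the series (>= 1).
#' @param n_initial_records Records in the first release.
#' @param rename_rate,delete_rate,seq_change_rate,add_rate Per-record
#'   per-step probabilities (stochastic mode; ignored when `counts` given).
#' @param counts Named integer vector `c(rename=, delete=, add=,
#'   sequence_change=)` applied at every step after the first (scripted
#'   mode).
#' @param n_collisions Number of collision pairs injected at the final step.
#' @param species Species code for all synthetic records.
#' @return A `mir_fixture_spec` list.
#' @export
mir_fixture_spec <- function(seed, n_versions = 2L, n_initial_records = 3L,
                             rename_rate = 0, delete_rate = 0,
                             seq_change_rate = 0, add_rate = 0,
                             counts = NULL, n_collisions = 0L,
                             species = "syn") {
  rates <- c(rename_rate, delete_rate, seq_change_rate, add_rate)
  stopifnot(n_versions >= 1L, n_initial_records >= 0L, n_collisions >= 0L,
            all(rates >= 0 & rates <= 1))
  if (!is.null(counts)) {
    counts <- counts[intersect(names(counts),
                               c("rename", "delete", "add", "sequence_change"))]
    stopifnot(all(counts >= 0))
  }
  structure(list(seed = as.integer(seed), n_versions = as.integer(n_versions),
                 n_initial_records = as.integer(n_initial_records),
                 rename_rate = rename_rate, delete_rate = delete_rate,
                 seq_change_rate = seq_change_rate, add_rate = add_rate,
                 counts = counts, n_collisions = as.integer(n_collisions),
                 species = species),
            class = "mir_fixture_spec")
}

random_sequence <- function(n = 1L) {
  purrr::map_chr(seq_len(n), function(i) {
    len <- sample(19:25, 1L)
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  })
}

fixture_name <- function(species, num, letter = "", arm_ix = NULL) {
  arm <- if (is.null(arm_ix)) "" else c("-5p", "-3p", "")[(arm_ix - 1L) %% 3L + 1L]
  paste0(species, "-miR-", num, letter, arm)
}

bump_letter <- function(name) {
  # "syn-miR-2-3p" -> "syn-miR-2b-3p"; "syn-miR-2b-3p" -> "syn-miR-2c-3p"
  m <- stringr::str_match(name, "^(.*miR-\\d+)([a-z]?)((-[35]p)?)$")
  if (is.na(m[1, 1])) return(paste0(name, "b"))
  letter <- m[1, 3]
  nxt <- if (letter == "") "b" else rawToChar(as.raw(utf8ToInt(letter) + 1L))
  paste0(m[1, 2], nxt, m[1, 4])
}

#' Generate a synthetic release series with its ground-truth event log
#'
#' See [mir_fixture_spec()] for the generative model. The returned event log
#' describes exactly the differences between consecutive releases; applying
#' it to release *k* reproduces release *k+1*.
#'
#' Event kinds in the log: `add` (new entry, including every initial record
#' at the first release), `rename`, `delete`, `sequence_change`, `collide`
#' (a new entry created with a copy of an existing entry's sequence; its
#' sibling is logged as `add`).
#'
#' @param spec A `mir_fixture_spec`.
#' @return List with `index` (a `mir_version_index`) and `events` (tibble:
#'   `version_label`, `kind`, `accession`, `old_name`, `new_name`,
#'   `sequence`).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "mir_fixture_spec"))
  withr::with_seed(spec$seed, generate_series_impl(spec))
}

generate_series_impl <- function(spec) {
  sp <- spec$species
  counter <- 0L
  new_accession <- function() sprintf("MIMAT%07d", counter)
  events <- list()
  log_ev <- function(version_label, kind, accession, old_name = "",
                     new_name = "", sequence = "") {
    events[[length(events) + 1L]] <<- tibble::tibble(
      version_label = version_label, kind = kind, accession = accession,
      old_name = old_name, new_name = new_name, sequence = sequence)
  }

  make_record <- function(num, name, sequence) {
    tibble::tibble(mimat_id = sprintf("MIMAT%07d", num),
                   name = name, sequence = sequence, species = sp,
                   mi_ids = list(sprintf("MI%07d", num)))
  }

  labs <- paste0("v", seq_len(spec$n_versions))
  # initial release
  recs <- purrr::map(seq_len(spec$n_initial_records), function(i) {
    counter <<- counter + 1L
    r <- make_record(counter, fixture_name(sp, counter, arm_ix = counter),
                     random_sequence())
    log_ev(labs[1L], "add", r$mimat_id, new_name = r$name, sequence = r$sequence)
    r
  })
  current <- dplyr::bind_rows(recs)
  releases <- list(mir_release(current, labs[1L]))
  dead_set <- character()

  n_steps <- spec$n_versions - 1L
  for (k in seq_len(n_steps)) {
    lab <- labs[k + 1L]
    alive <- dplyr::arrange(current, .data$mimat_id)
    n_alive <- nrow(alive)

    if (!is.null(spec$counts)) {
      cnt <- function(what) {
        if (what %in% names(spec$counts)) as.integer(spec$counts[[what]]) else 0L
      }
      n_del <- min(cnt("delete"), n_alive)
      del_ix <- if (n_del) seq(n_alive - n_del + 1L, n_alive) else integer()
      rest <- setdiff(seq_len(n_alive), del_ix)
      n_ren <- min(cnt("rename"), length(rest))
      ren_ix <- if (n_ren) rest[seq(length(rest) - n_ren + 1L, length(rest))] else integer()
      rest2 <- setdiff(rest, ren_ix)
      n_chg <- min(cnt("sequence_change"), length(rest2))
      chg_ix <- if (n_chg) rest2[seq(length(rest2) - n_chg + 1L, length(rest2))] else integer()
      n_add <- cnt("add")
    } else {
      u <- stats::runif(n_alive)
      roles <- character(n_alive)
      roles[u < spec$delete_rate] <- "delete"
      roles[u >= spec$delete_rate &
              u < spec$delete_rate + spec$rename_rate] <- "rename"
      roles[u >= spec$delete_rate + spec$rename_rate &
              u < spec$delete_rate + spec$rename_rate + spec$seq_change_rate] <-
        "sequence_change"
      del_ix <- which(roles == "delete")
      ren_ix <- which(roles == "rename")
      chg_ix <- which(roles == "sequence_change")
      n_add <- stats::rbinom(1L, max(n_alive, 1L), spec$add_rate)
    }
    if (nrow(alive) - length(del_ix) < 0L) {
      rlang::abort("fixture spec deletes more records than exist",
                   class = "mirharmony_spec_error")
    }

    for (i in del_ix) {
      log_ev(lab, "delete", alive$mimat_id[i], old_name = alive$name[i])
      dead_set <- c(dead_set, alive$mimat_id[i])
    }
    for (i in ren_ix) {
      nn <- bump_letter(alive$name[i])
      log_ev(lab, "rename", alive$mimat_id[i], old_name = alive$name[i],
             new_name = nn, sequence = alive$sequence[i])
      alive$name[i] <- nn
    }
    for (i in chg_ix) {
      ns <- random_sequence()
      log_ev(lab, "sequence_change", alive$mimat_id[i],
             old_name = alive$name[i], new_name = alive$name[i], sequence = ns)
      alive$sequence[i] <- ns
    }
    keep <- alive[setdiff(seq_len(n_alive), del_ix), , drop = FALSE]
    adds <- purrr::map(seq_len(n_add), function(j) {
      counter <<- counter + 1L
      r <- make_record(counter, fixture_name(sp, counter, arm_ix = counter),
                       random_sequence())
      log_ev(lab, "add", r$mimat_id, new_name = r$name, sequence = r$sequence)
      r
    })
    current <- dplyr::bind_rows(keep, adds)

    if (k == n_steps && spec$n_collisions > 0L) {
      if (nrow(current) == 0L) {
        rlang::abort("cannot inject collisions into an empty release",
                     class = "mirharmony_spec_error")
      }
      for (j in seq_len(spec$n_collisions)) {
        counter <- counter + 1L
        num <- counter
        seq0 <- random_sequence()
        counter <- counter + 1L
        pair <- dplyr::bind_rows(
          make_record(num, fixture_name(sp, num, "a"), seq0) |>
            dplyr::mutate(mimat_id = sprintf("MIMAT%07d", num)),
          make_record(counter, fixture_name(sp, num, "b"), seq0) |>
            dplyr::mutate(mimat_id = sprintf("MIMAT%07d", counter))
        )
        log_ev(lab, "add", pair$mimat_id[1L], new_name = pair$name[1L],
               sequence = seq0)
        log_ev(lab, "collide", pair$mimat_id[2L], new_name = pair$name[2L],
               sequence = seq0)
        current <- dplyr::bind_rows(current, pair)
      }
    }
    releases[[k + 1L]] <- mir_release(current, lab, dead_ids = dead_set)
  }

  ev <- if (length(events)) dplyr::bind_rows(events) else
    tibble::tibble(version_label = character(), kind = character(),
                   accession = character(), old_name = character(),
                   new_name = character(), sequence = character())
  list(index = mir_version_index(releases), events = ev)
}

#' The toy3 fixture: three records, one rename, one delete, one add, one
#' collision pair
#'
#' A two-release miniature exercising every mapping outcome: `syn-miR-1-5p`
#' is stable, `syn-miR-2-3p` is renamed to `syn-miR-2b-3p`, `syn-miR-3` is
#' deleted, `syn-miR-4-5p` is added, and the collision pair `syn-miR-5a` /
#' `syn-miR-5b` shares one sequence key in v2. Used throughout the unit
#' tests and examples.
#'
#' @param seed Seed (default 42, the canonical toy3).
#' @return As [generate_series()].
#' @export
fixture_toy3 <- function(seed = 42L) {
  generate_series(mir_fixture_spec(
    seed = seed, n_versions = 2L, n_initial_records = 3L,
    counts = c(rename = 1L, delete = 1L, add = 1L), n_collisions = 1L))
}

#' Derive a synthetic platform from a release
#'
#' Emulates a vendor probe annotation file designed against one release:
#' probes sample the release's (name, sequence) pairs; a chosen number of
#' probes get an injected wrong sequence (swapped from another sampled
#' record) emulating vendor design/annotation errors; control probes with
#' non-miRNA names are appended. The injection manifest (which probes were
#' corrupted, expected and observed sequence) is attached as the
#' `injection_manifest` element, serving as ground truth for curation tests.
#'
#' @param release A `mir_release`.
#' @param n_probes Number of miRNA probes (at most the records available).
#' @param n_injected_mismatches Probes given a wrong target sequence.
#' @param n_controls Control probes appended.
#' @param seed Integer seed.
#' @param platform_id Identifier for the platform.
#' @param species Species whose records are sampled.
#' @return A `mir_platform` with an extra `injection_manifest` tibble
#'   (`probe_id`, `reported_name`, `expected_sequence`, `observed_sequence`).
#' @export
derive_platform <- function(release, n_probes, n_injected_mismatches = 0L,
                            n_controls = 0L, seed = 1L, platform_id = "P1",
                            species = "syn") {
  stopifnot(inherits(release, "mir_release"))
  rec <- release$records[release$records$species == species, , drop = FALSE]
  if (n_probes > nrow(rec)) {
    rlang::abort("platform spec requests more probes than records available",
                 class = "mirharmony_spec_error")
  }
  if (n_injected_mismatches > n_probes) {
    rlang::abort("more injected mismatches than probes",
                 class = "mirharmony_spec_error")
  }
  withr::with_seed(seed, {
    pick <- sort(sample(seq_len(nrow(rec)), n_probes))
    probes <- tibble::tibble(
      probe_id = sprintf("%s_probe_%03d", platform_id, seq_len(n_probes)),
      reported_name = rec$name[pick],
      target_sequence = rec$sequence[pick],
      is_control = FALSE)
    manifest <- tibble::tibble(probe_id = character(),
                               reported_name = character(),
                               expected_sequence = character(),
                               observed_sequence = character())
    if (n_injected_mismatches > 0L) {
      bad <- sample(seq_len(n_probes), n_injected_mismatches)
      for (i in bad) {
        donors <- setdiff(unique(rec$sequence), probes$target_sequence[i])
        wrong <- sample(donors, 1L)
        manifest <- dplyr::bind_rows(manifest, tibble::tibble(
          probe_id = probes$probe_id[i],
          reported_name = probes$reported_name[i],
          expected_sequence = probes$target_sequence[i],
          observed_sequence = wrong))
        probes$target_sequence[i] <- wrong
      }
      manifest <- dplyr::arrange(manifest, .data$probe_id)
    }
    if (n_controls > 0L) {
      ctrl <- tibble::tibble(
        probe_id = sprintf("%s_ctrl_%03d", platform_id, seq_len(n_controls)),
        reported_name = sprintf("spike-in-ctrl-%d", seq_len(n_controls)),
        target_sequence = random_sequence(n_controls),
        is_control = TRUE)
      probes <- dplyr::bind_rows(probes, ctrl)
    }
    p <- mir_platform(probes, platform_id = platform_id, vendor = "synthetic",
                      design_version = release$version_label,
                      species_scope = species)
    p$injection_manifest <- manifest
    p
  })
}

#' Generate a reproducible synthetic expression matrix
#'
#' One row per namespace name (lexicographic order), values drawn from a
#' log-normal distribution — the conventional rough shape of expression
#' intensities; the values carry no biological meaning, only known
#' provenance for carryover tests.
#'
#' @param ns A non-empty `mir_namespace`.
#' @param n_samples Number of sample columns (0 allowed: names-only matrix).
#' @param seed Integer seed.
#' @param meanlog,sdlog Log-normal parameters.
#' @return Tibble: column `mirna`, then samples `S1`..`Sn`.
#' @export
generate_matrix <- function(ns, n_samples, seed = 1L, meanlog = 5, sdlog = 1) {
  stopifnot(inherits(ns, "mir_namespace"))
  if (nrow(ns$table) == 0L) {
    rlang::abort("cannot generate a matrix from an empty namespace",
                 class = "mirharmony_spec_error")
  }
  nm <- sort(ns$table$name)
  withr::with_seed(seed, {
    vals <- matrix(stats::rlnorm(length(nm) * n_samples, meanlog, sdlog),
                   nrow = length(nm), ncol = n_samples)
    out <- tibble::tibble(mirna = nm)
    if (n_samples > 0L) {
      vals <- round(vals, 3)
      colnames(vals) <- paste0("S", seq_len(n_samples))
      out <- dplyr::bind_cols(out, tibble::as_tibble(vals))
    }
    out
  })
}
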