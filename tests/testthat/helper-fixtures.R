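# Shared fixture builders and independent brute-force oracles.
# The oracles operate directly on raw record tables (quadratic scans/joins),
# never through the namespace machinery they are used to check.

toy3 <- fixture_toy3()
toy3_v1 <- toy3$index$releases[["v1"]]
toy3_v2 <- toy3$index$releases[["v2"]]
ns_v1 <- build_namespace(toy3_v1, "syn")
ns_v2 <- build_namespace(toy3_v2, "syn")

# quadratic join oracle for a single name translation
oracle_translate_one <- function(nm, src_rec, dst_rec, dst_dead) {
  hit <- src_rec[src_rec$name == nm, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(list(status = "unrecognized", outputs = character()))
  }
  s <- hit$sequence[1L]
  outs <- sort(dst_rec$name[dst_rec$sequence == s])
  if (length(outs) == 0L) {
    accs <- src_rec$mimat_id[src_rec$sequence == s]
    status <- if (any(accs %in% dst_dead)) "dead" else "missing"
    return(list(status = status, outputs = character()))
  }
  status <- if (length(outs) >= 2L) "multiple"
    else if (outs == nm) "stable" else "renamed"
  list(status = status, outputs = outs)
}

oracle_translate <- function(names, src_rel, dst_rel) {
  purrr::map(names, oracle_translate_one,
             src_rec = src_rel$records, dst_rec = dst_rel$records,
             dst_dead = dst_rel$dead_ids)
}

# exhaustive pairwise sequence comparison of two record tables
oracle_overlap_sequences <- function(rec_a, rec_b) {
  hits <- character()
  for (sa in rec_a$sequence) {
    for (sb in rec_b$sequence) {
      if (sa == sb) hits <- c(hits, sa)
    }
  }
  sort(unique(hits))
}

# linear scan lookup oracle
oracle_lookup <- function(rec, sequence) {
  sort(rec$name[rec$sequence == sequence])
}

# a richer stochastic series for property tests
make_series <- function(seed, n_versions = 5L, n_initial = 30L) {
  generate_series(mir_fixture_spec(
    seed = seed, n_versions = n_versions, n_initial_records = n_initial,
    rename_rate = 0.15, delete_rate = 0.08, seq_change_rate = 0.05,
    add_rate = 0.15, n_collisions = 2L))
}

# map generator event kinds onto history event kinds
event_kind_map <- c(add = "introduced", collide = "introduced",
                    rename = "renamed", delete = "deleted",
                    sequence_change = "sequence_changed")
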