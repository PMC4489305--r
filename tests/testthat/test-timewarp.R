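test_that("history reconstructs the scripted toy events", {
  hist <- build_history(toy3$index, species = "syn")
  ev2 <- hist$events[hist$events$mimat_id == "MIMAT0000002", ]
  expect_equal(ev2$kind, c("introduced", "renamed"))
  expect_equal(ev2$version_label, c("v1", "v2"))
  expect_equal(ev2$old_name[2L], "syn-miR-2-3p")
  expect_equal(ev2$new_name[2L], "syn-miR-2b-3p")

  ev3 <- hist$events[hist$events$mimat_id == "MIMAT0000003", ]
  expect_equal(ev3$kind, c("introduced", "deleted"))
  expect_equal(ev3$version_label, c("v1", "v2"))
  tr3 <- hist$tracks[hist$tracks$mimat_id == "MIMAT0000003", ]
  expect_false(tr3$alive)
  expect_equal(tr3$current_name, "")
  expect_equal(tr3$current_sequence,
               toy3_v1$records$sequence[toy3_v1$records$mimat_id == "MIMAT0000003"])
})

test_that("a single-release index yields only pre-series introductions", {
  idx <- mir_version_index(list(toy3_v1))
  hist <- build_history(idx)
  expect_true(all(hist$events$kind == "introduced"))
  expect_true(all(hist$events$pre_series))
  expect_equal(nrow(hist$tracks), 3L)
})

test_that("history recovers the scripted event multiset exactly, any seed", {
  for (seed in 1:5) {
    fx <- make_series(seed, n_versions = 5L, n_initial = 30L)
    hist <- build_history(fx$index, species = "syn")
    got <- paste(hist$events$mimat_id, hist$events$kind,
                 hist$events$version_label)
    want <- paste(fx$events$accession, event_kind_map[fx$events$kind],
                  fx$events$version_label)
    expect_identical(sort(got), sort(want))
  }
})

test_that("an accession absent in between is deleted then reinstated", {
  rec <- toy3_v1$records
  idx <- mir_version_index(list(
    mir_release(rec, "v1"),
    mir_release(rec[-2L, ], "v2"),
    mir_release(rec, "v3")))
  hist <- build_history(idx)
  ev <- hist$events[hist$events$mimat_id == rec$mimat_id[2L], ]
  expect_equal(ev$kind, c("introduced", "deleted", "introduced"))
  expect_false(ev$pre_series[3L])
})

test_that("sequence changes are tracked as their own events", {
  rec <- toy3_v1$records
  rec2 <- rec
  rec2$sequence[1L] <- strrep("AC", 11)
  rec2$length <- nchar(rec2$sequence)
  idx <- mir_version_index(list(mir_release(rec, "v1"), mir_release(rec2, "v2")))
  hist <- build_history(idx)
  chg <- hist$events[hist$events$kind == "sequence_changed", ]
  expect_equal(chg$mimat_id, rec$mimat_id[1L])
  expect_equal(chg$sequence_at_version, strrep("AC", 11))
})

test_that("stringent queries match any name ever borne; relaxed is a superset", {
  hist <- build_history(toy3$index, species = "syn")
  hit <- time_warp_query(hist, "syn-miR-2-3p", stringent = TRUE, species = "syn")
  expect_equal(hit$mimat_id, "MIMAT0000002")
  expect_equal(hit$current_name, "syn-miR-2b-3p")

  relaxed <- time_warp_query(hist, "miR-2", stringent = FALSE, species = "syn")
  expect_true("MIMAT0000002" %in% relaxed$mimat_id)
  # oracle: substring scan over the ground-truth name table
  expect_equal(nrow(relaxed), sum(vapply(
    split(hist$names_by_version$name, hist$names_by_version$mimat_id),
    function(nm) any(grepl("mir-2", tolower(nm), fixed = TRUE)), logical(1))))

  expect_equal(nrow(time_warp_query(hist, "no-such-mir")), 0L)
  expect_error(time_warp_query(hist, "syn-miR-1-5p", start_version = "v99"),
               class = "mirharmony_unknown_version")
})

test_that("every stringent hit is also a relaxed hit, across seeds and queries", {
  for (seed in 1:3) {
    fx <- make_series(seed)
    hist <- build_history(fx$index, species = "syn")
    queries <- head(unique(hist$names_by_version$name), 25L)
    for (q in queries) {
      s_ids <- time_warp_query(hist, q, stringent = TRUE, species = "syn")$mimat_id
      r_ids <- time_warp_query(hist, q, stringent = FALSE, species = "syn")$mimat_id
      expect_true(all(s_ids %in% r_ids))
    }
  }
})

test_that("unprefixed stringent queries inject the species prefix", {
  hist <- build_history(toy3$index, species = "syn")
  hit <- time_warp_query(hist, "miR-1-5p", stringent = TRUE, species = "syn")
  expect_equal(hit$mimat_id, "MIMAT0000001")
  hit_all <- time_warp_query(hist, "miR-1-5p", stringent = TRUE, species = "all")
  expect_equal(hit_all$mimat_id, "MIMAT0000001")
})

test_that("a start version restricts matching to names borne from there on", {
  hist <- build_history(toy3$index, species = "syn")
  # the pre-rename name was never borne at or after v2
  expect_equal(nrow(time_warp_query(hist, "syn-miR-2-3p", start_version = "v2")), 0L)
  expect_equal(nrow(time_warp_query(hist, "syn-miR-2b-3p", start_version = "v2")), 1L)
})

test_that("adding a later release never removes events from existing tracks", {
  fx <- make_series(11L, n_versions = 5L, n_initial = 20L)
  rels <- purrr::map(fx$index$order, ~ fx$index$releases[[.x]])
  prev <- build_history(mir_version_index(rels[1:4]), species = "syn")
  full <- build_history(mir_version_index(rels), species = "syn")
  key <- function(e) paste(e$mimat_id, e$kind, e$version_label)
  expect_true(all(key(prev$events) %in% key(full$events)))
})

test_that("detecting platforms respects sequence identity and liveness", {
  hist <- build_history(toy3$index, species = "syn")
  p1 <- derive_platform(toy3_v1, n_probes = 3L, seed = 1L, platform_id = "P1")
  # P2 targets only a foreign sequence
  p2 <- mir_platform(tibble::tibble(probe_id = "x",
                                    reported_name = "syn-miR-77",
                                    target_sequence = strrep("GU", 11)),
                     "P2", species_scope = "syn")
  tr1 <- hist$tracks[hist$tracks$mimat_id == "MIMAT0000001", ]
  expect_equal(detecting_platforms(tr1, list(p1, p2)), "P1")
  expect_equal(detecting_platforms(tr1, list()), character(0))
  dead <- hist$tracks[hist$tracks$mimat_id == "MIMAT0000003", ]
  expect_message(out <- detecting_platforms(dead, list(p1, p2)))
  expect_equal(out, character(0))
})

test_that("history tidy/glance/autoplot expose events and counts", {
  hist <- build_history(toy3$index, species = "syn")
  expect_equal(nrow(tidy(hist)), nrow(hist$events))
  g <- glance(hist)
  expect_equal(g$n_renamed, 1L)
  expect_equal(g$n_deleted, 1L)
  expect_s3_class(autoplot(hist), "ggplot")
})
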