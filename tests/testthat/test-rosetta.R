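test_that("translation across the toy series yields the scripted statuses", {
  tr <- translate_names(c("syn-miR-1-5p", "syn-miR-2-3p", "syn-miR-3",
                          "spike-in-ctrl-1"), ns_v1, ns_v2)
  expect_equal(tr$status,
               c("stable", "renamed", "dead", "unrecognized"))
  expect_equal(tr$output_names[2L], "syn-miR-2b-3p")
  expect_equal(tr$output_names[3L], "")
  expect_equal(tr$output_accessions[1L], "MIMAT0000001")
  # oracle: brute-force sequence join of the two fixture tables
  or <- oracle_translate(tr$input_name, toy3_v1, toy3_v2)
  expect_equal(tr$status, purrr::map_chr(or, "status"))
})

test_that("self-translation is the identity with status stable", {
  tr <- translate_names(toy3_v1$records$name, ns_v1, ns_v1)
  expect_true(all(tr$status == "stable"))
  expect_equal(tr$output_names, tr$input_name)
})

test_that("a destination collision is reported as one multi-name row", {
  # syn-miR-5a exists only in v2; translate v2 -> v2 resolves its collided key
  tr <- translate_names("syn-miR-5a", ns_v2, ns_v2)
  expect_equal(tr$status, "multiple")
  expect_equal(tr$output_names, "syn-miR-5a;syn-miR-5b")
  long <- explode_translation(tr)
  expect_equal(long$output_name, c("syn-miR-5a", "syn-miR-5b"))
})

test_that("duplicate and empty inputs are handled row-per-input", {
  tr <- translate_names(c("syn-miR-1-5p", "syn-miR-1-5p"), ns_v1, ns_v2)
  expect_equal(nrow(tr), 2L)
  expect_equal(tr$status, c("stable", "stable"))
  expect_equal(nrow(translate_names(character(), ns_v1, ns_v2)), 0L)
})

test_that("case-insensitive rescue is applied and annotated, never silent", {
  tr <- translate_names("SYN-MIR-1-5P", ns_v1, ns_v2)
  # output name differs from the typed form, so by the partition it is renamed
  expect_equal(tr$status, "renamed")
  expect_equal(tr$output_names, "syn-miR-1-5p")
  expect_match(tr$note, "case-insensitive")
  off <- translate_names("SYN-MIR-1-5P", ns_v1, ns_v2, case_rescue = FALSE)
  expect_equal(off$status, "unrecognized")
})

test_that("every translation row satisfies the status partition invariants", {
  for (seed in 1:5) {
    fx <- make_series(seed)
    first <- fx$index$releases[[fx$index$order[1L]]]
    last <- fx$index$releases[[fx$index$order[length(fx$index$order)]]]
    src <- build_namespace(first, "syn")
    dst <- build_namespace(last, "syn")
    tr <- translate_names(first$records$name, src, dst)
    outs <- strsplit(tr$output_names, ";", fixed = TRUE)
    n_out <- purrr::map_int(outs, ~ sum(nzchar(.x)))
    expect_true(all((tr$status == "stable") == (n_out == 1L & tr$output_names == tr$input_name)))
    expect_true(all((tr$status == "renamed") == (n_out == 1L & tr$output_names != tr$input_name)))
    expect_true(all((tr$status == "multiple") == (n_out >= 2L)))
    expect_true(all((tr$status %in% c("dead", "missing", "unrecognized")) == (n_out == 0L)))
  }
})

test_that("translation agrees with the quadratic brute-force join across seeds", {
  for (seed in 1:5) {
    fx <- make_series(seed, n_versions = 4L, n_initial = 40L)
    a <- fx$index$releases[[fx$index$order[1L]]]
    b <- fx$index$releases[[fx$index$order[4L]]]
    src <- build_namespace(a, "syn")
    dst <- build_namespace(b, "syn")
    queries <- c(a$records$name, "syn-miR-nonexistent", "spike-in-ctrl-1")
    tr <- translate_names(queries, src, dst)
    or <- oracle_translate(queries, a, b)
    expect_equal(tr$status, purrr::map_chr(or, "status"))
    expect_equal(tr$output_names,
                 purrr::map_chr(or, ~ paste(.x$outputs, collapse = ";")))
  }
})

test_that("stable and renamed rows round-trip back to their input name", {
  for (seed in 1:10) {
    fx <- make_series(seed, n_versions = 3L, n_initial = 20L)
    src <- build_namespace(fx$index$releases[[1L]], "syn")
    dst <- build_namespace(fx$index$releases[[3L]], "syn")
    tr <- translate_names(src$table$name, src, dst)
    ok <- tr$status %in% c("stable", "renamed")
    if (!any(ok)) next
    back <- translate_names(tr$output_names[ok], dst, src)
    expect_equal(back$output_names, tr$input_name[ok])
  }
})

test_that("overlap is sequence-symmetric and matches exhaustive comparison", {
  self <- overlap_namespaces(ns_v1, ns_v1)
  expect_equal(nrow(self), 3L)
  expect_equal(self$names_a, self$names_b)

  empty <- suppressWarnings(build_namespace(toy3_v1, "xyz"))
  expect_equal(nrow(overlap_namespaces(ns_v1, empty)), 0L)

  ov <- overlap_namespaces(ns_v1, ns_v2)
  expect_equal(ov$sequence, oracle_overlap_sequences(toy3_v1$records, toy3_v2$records))
  for (seed in 1:10) {
    fx <- make_series(seed, n_versions = 3L, n_initial = 15L)
    x <- build_namespace(fx$index$releases[[1L]], "syn")
    y <- build_namespace(fx$index$releases[[3L]], "syn")
    expect_equal(overlap_namespaces(x, y)$sequence,
                 overlap_namespaces(y, x)$sequence)
  }
})

test_that("two platforms sharing exactly one target sequence overlap in one entry", {
  rec <- toy3_v1$records
  pa <- mir_platform(tibble::tibble(probe_id = c("a1", "a2"),
                                    reported_name = rec$name[1:2],
                                    target_sequence = rec$sequence[1:2]), "PA")
  pb <- mir_platform(tibble::tibble(probe_id = c("b1", "b2"),
                                    reported_name = c(rec$name[2L], "syn-miR-99"),
                                    target_sequence = c(rec$sequence[2L],
                                                        strrep("ACGU", 5))), "PB")
  ov <- overlap_namespaces(build_namespace(pa), build_namespace(pb))
  expect_equal(nrow(ov), 1L)
  expect_equal(ov$sequence, rec$sequence[2L])
})

test_that("matrix update preserves rows and values bit-exactly and re-annotates", {
  m <- generate_matrix(ns_v1, n_samples = 2L, seed = 7L)
  up <- update_matrix(m, ns_v1, ns_v2)
  expect_equal(nrow(up), nrow(m))
  expect_identical(up$S1, m$S1)
  expect_identical(up$S2, m$S2)
  renamed <- up[up$input_name == "syn-miR-2-3p", ]
  expect_equal(renamed$status, "renamed")
  expect_equal(renamed$output_names, "syn-miR-2b-3p")
  # oracle: translate_names on the row names gives the same annotation block
  expect_equal(up$status, translate_names(m$mirna, ns_v1, ns_v2)$status)
})

test_that("identity update is all-stable; empty matrix passes through", {
  m <- generate_matrix(ns_v1, n_samples = 2L, seed = 1L)
  up <- update_matrix(m, ns_v1, ns_v1)
  expect_true(all(up$status == "stable"))
  expect_equal(up$output_names, m$mirna)

  header_only <- m[0L, ]
  up0 <- update_matrix(header_only, ns_v1, ns_v2)
  expect_equal(nrow(up0), 0L)
  expect_true(all(c("S1", "S2") %in% names(up0)))
})

test_that("failures-last ordering keeps untranslatable rows at the bottom, order stable", {
  m <- tibble::tibble(mirna = c("syn-miR-3", "syn-miR-1-5p", "nonsense",
                                "syn-miR-2-3p"),
                      S1 = 1:4)
  up <- update_matrix(m, ns_v1, ns_v2, failures_last = TRUE)
  expect_equal(up$input_name,
               c("syn-miR-1-5p", "syn-miR-2-3p", "syn-miR-3", "nonsense"))
  expect_equal(up$S1, c(2L, 4L, 1L, 3L))
})

test_that("update conserves the multiset of carried values at every seed", {
  for (seed in 1:10) {
    fx <- make_series(seed, n_versions = 3L, n_initial = 20L)
    src <- build_namespace(fx$index$releases[[1L]], "syn")
    dst <- build_namespace(fx$index$releases[[3L]], "syn")
    m <- generate_matrix(src, n_samples = 3L, seed = seed)
    up <- update_matrix(m, src, dst)
    expect_equal(nrow(up), nrow(m))
    expect_identical(sort(unlist(up[, c("S1", "S2", "S3")])),
                     sort(unlist(m[, c("S1", "S2", "S3")])))
  }
})

test_that("intersection joins on the sequence despite renamed row names", {
  m1 <- tibble::tibble(mirna = c("syn-miR-1-5p", "syn-miR-2-3p"), X1 = c(1, 2))
  m2 <- tibble::tibble(mirna = c("syn-miR-1-5p", "syn-miR-2b-3p"), Y1 = c(3, 4))
  res <- intersect_matrices(m1, ns_v1, m2, ns_v2, ns_v2)
  expect_equal(nrow(res$result), 2L)
  expect_equal(names(res$result),
               c("sequence", "output_names", "output_accessions", "X1", "Y1"))
  # hand oracle: both sequences are shared; values carried by position
  r2 <- res$result[res$result$output_names == "syn-miR-2b-3p", ]
  expect_equal(r2$X1, 2)
  expect_equal(r2$Y1, 4)
  expect_equal(nrow(res$side_report), 0L)
})

test_that("sequence-disjoint matrices intersect to nothing, all rows reported", {
  m1 <- tibble::tibble(mirna = "syn-miR-1-5p", X1 = 1)
  m2 <- tibble::tibble(mirna = "syn-miR-4-5p", Y1 = 2)
  res <- intersect_matrices(m1, ns_v1, m2, ns_v2, ns_v2)
  expect_equal(nrow(res$result), 0L)
  expect_equal(nrow(res$side_report), 2L)
  expect_setequal(res$side_report$source, c("a", "b"))
})

test_that("self-intersection with prefixing carries equal values on both sides", {
  m <- generate_matrix(ns_v1, n_samples = 2L, seed = 3L)
  res <- intersect_matrices(m, ns_v1, m, ns_v1, ns_v1, prefix = c("A_", "B_"))
  expect_equal(nrow(res$result), 3L)
  expect_identical(res$result$A_S1, res$result$B_S1)
  expect_identical(res$result$A_S2, res$result$B_S2)
  expect_error(intersect_matrices(m, ns_v1, m, ns_v1, ns_v1),
               class = "mirharmony_config_error")
})

test_that("glance and autoplot work on translation results", {
  tr <- translate_names(c("syn-miR-1-5p", "syn-miR-3"), ns_v1, ns_v2)
  g <- glance(tr)
  expect_equal(g$n_stable, 1L)
  expect_equal(g$n_dead, 1L)
  expect_s3_class(autoplot(tr), "ggplot")
})
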