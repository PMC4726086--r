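mk_hit <- function(query_id = "q1", subject_id = "s1",
                   subject_organism = "orgX", percent_identity = 45,
                   alignment_length = 160L, evalue = 1e-20,
                   bit_score = 200, query_length = 200L,
                   subject_length = 200L) {
  tibble::tibble(query_id, subject_id, subject_organism, percent_identity,
                 alignment_length, evalue, bit_score, query_length,
                 subject_length)
}

test_that("threshold filtering keeps exactly the passing hits", {
  hits <- dplyr::bind_rows(
    mk_hit(),                                   # passes everything
    mk_hit(subject_id = "s2", percent_identity = 25),
    mk_hit(subject_id = "s3", evalue = 1e-4),
    mk_hit(subject_id = "s4", alignment_length = 100L)  # 50% coverage
  )
  kept <- filter_homology_hits(hits)
  expect_equal(kept$subject_id, "s1")
  expect_equal(kept$query_coverage, 80)

  ## query-only coverage accepts a hit whose subject side is too long
  long_subject <- mk_hit(subject_id = "s5", subject_length = 400L)
  expect_equal(nrow(filter_homology_hits(long_subject)), 0)
  expect_equal(nrow(filter_homology_hits(long_subject,
                                         coverage_mode = "query")), 1)

  expect_error(
    filter_homology_hits(mk_hit(query_length = 0L)), "positive"
  )
})

test_that("best hit per organism follows score then E-value then id", {
  hits <- dplyr::bind_rows(
    mk_hit(subject_id = "s1", bit_score = 200),
    mk_hit(subject_id = "s2", bit_score = 150),
    mk_hit(subject_id = "s9", subject_organism = "orgY", bit_score = 90)
  )
  map <- best_hit_per_organism(hits)
  expect_equal(nrow(map), 2)
  expect_equal(map$subject_id[map$subject_organism == "orgX"], "s1")
  expect_equal(map$subject_id[map$subject_organism == "orgY"], "s9")

  tie <- dplyr::bind_rows(
    mk_hit(subject_id = "sA", bit_score = 100, evalue = 1e-10),
    mk_hit(subject_id = "sB", bit_score = 100, evalue = 1e-12)
  )
  expect_equal(best_hit_per_organism(tie)$subject_id, "sB")

  tie2 <- dplyr::bind_rows(
    mk_hit(subject_id = "sD", bit_score = 100, evalue = 1e-10),
    mk_hit(subject_id = "sC", bit_score = 100, evalue = 1e-10)
  )
  expect_equal(best_hit_per_organism(tie2)$subject_id, "sC")
})

test_that("transfer emits exactly the same-organism supported pairs", {
  map <- tibble::tibble(
    query_id = c("A", "B"), subject_organism = "orgX",
    subject_id = c("a", "b"), bit_score = c(100, 100)
  )
  ref <- tibble::tibble(protein_a = "a", protein_b = "b", organism = "orgX")
  out <- transfer_interactions(map, ref)
  expect_equal(out$protein_a, "A")
  expect_equal(out$protein_b, "B")
  expect_equal(out$evidence, "interolog")
  expect_equal(out$sources, "orgX")

  ## unmapped partner -> nothing
  expect_equal(nrow(transfer_interactions(map[1, ], ref)), 0)
  ## supporting edge in another organism -> nothing
  ref_y <- tibble::tibble(protein_a = "a", protein_b = "b",
                          organism = "orgY")
  expect_equal(nrow(transfer_interactions(map, ref_y)), 0)
  ## homomeric reference edge -> flagged self loop
  self <- transfer_interactions(
    map, tibble::tibble(protein_a = "a", protein_b = "a",
                        organism = "orgX"))
  expect_true(self$self_loop)
  expect_equal(self$protein_a, "A")
})

test_that("transfer is monotone and thresholds are nested", {
  w <- generate_world(3, small_world_config())
  base <- predict_interolog(w$homology_hits, w$reference_edges)
  more_ref <- dplyr::bind_rows(
    w$reference_edges,
    tibble::tibble(protein_a = "orgA_BL0001", protein_b = "orgA_BL0002",
                   organism = "orgA")
  )
  grown <- predict_interolog(w$homology_hits, more_ref)
  key <- function(e) paste(e$protein_a, e$protein_b)
  expect_true(all(key(base) %in% key(grown)))

  tight <- predict_interolog(w$homology_hits, w$reference_edges,
                             min_identity = 60, min_coverage = 80)
  expect_true(all(key(tight) %in% key(base)))
})

test_that("planted interologs are fully recovered and nothing extra appears", {
  for (s in c(5, 9)) {
    w <- generate_world(s, small_world_config())
    pred <- predict_interolog(w$homology_hits, w$reference_edges)
    oracle <- interolog_brute_oracle(w$planted_orthologs, w$reference_edges)
    expect_identical(
      pred[, c("protein_a", "protein_b")],
      oracle
    )
  }
})
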