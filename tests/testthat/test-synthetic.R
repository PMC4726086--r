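test_that("worlds are deterministic down to their fixture bytes", {
  w1 <- generate_world(11, small_world_config())
  w2 <- generate_world(11, small_world_config())
  expect_identical(w1$homology_hits, w2$homology_hits)
  expect_identical(w1$truth_network$edges, w2$truth_network$edges)

  d1 <- tempfile(); d2 <- tempfile()
  write_fixtures(w1, d1)
  write_fixtures(w2, d2)
  for (f in setdiff(list.files(d1), "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("fixture files round-trip to the in-memory tables", {
  w <- generate_world(12, small_world_config())
  d <- tempfile()
  manifest <- write_fixtures(w, d)
  expect_true(all(file.exists(file.path(d, manifest$file))))

  hits <- read_homology_table(file.path(d, "homology_hits.tsv"),
                              w$organism_map)
  expect_equal(as.data.frame(hits), as.data.frame(w$homology_hits))

  dom <- read_domain_table(file.path(d, "domain_hits.tsv"))
  expect_equal(as.data.frame(dom), as.data.frame(w$domain_hits))

  expect_equal(as.data.frame(read_reference_edges(
    file.path(d, "reference_edges.tsv"))),
    as.data.frame(w$reference_edges))
  expect_equal(as.data.frame(read_ddi_table(file.path(d, "ddi_pairs.tsv"))),
               as.data.frame(w$ddis))
  expect_equal(as.data.frame(read_cog_annotations(file.path(d, "cog.tsv"))),
               as.data.frame(w$cog))
  expect_equal(as.data.frame(read_go_annotations(file.path(d, "go.tsv"))),
               as.data.frame(w$go))
  expect_equal(as.data.frame(read_expression_matrix(
    file.path(d, "expression.tsv"))),
    as.data.frame(w$expression))

  dag <- read_obo_subset(file.path(d, "go.obo"))
  expect_setequal(dag$terms, w$go_dag$terms)
  expect_equal(dplyr::arrange(dag$parents, term, parent),
               dplyr::arrange(w$go_dag$parents, term, parent))

  expect_identical(read_edge_list(file.path(d, "truth_network.tsv")),
                   w$truth_network$edges)
})

test_that("decoy-only homology tables predict nothing", {
  cfg <- small_world_config(ortholog_rate = 0, n_complexes = 0,
                            n_background_pairs = 0)
  w <- generate_world(13, cfg)
  expect_equal(nrow(w$planted_orthologs), 0)
  expect_true(nrow(w$homology_hits) > 0)     # decoys are present
  pred <- predict_interolog(w$homology_hits, w$reference_edges)
  expect_equal(nrow(pred), 0)
})

test_that("decoys fail exactly one filter each", {
  w <- generate_world(14, small_world_config())
  decoys <- dplyr::filter(w$homology_hits,
                          grepl("_DEC", subject_id)) |>
    dplyr::mutate(
      fail_id = percent_identity < 30,
      fail_e = evalue > 1e-5,
      fail_cov = pmin(100 * alignment_length / query_length,
                      100 * alignment_length / subject_length)
                 < 60
    )
  expect_true(all(decoys$fail_id + decoys$fail_e + decoys$fail_cov == 1))
})

test_that("interacting pairs correlate more than random pairs", {
  w <- generate_world(15, small_world_config())
  net <- remove_self_loops(w$truth_network)
  profiles <- as.matrix(w$expression[, c("11h", "22h", "33h")])
  rownames(profiles) <- w$expression$protein_id

  pcc_of <- function(a, b) {
    vapply(seq_along(a), function(i) cor(profiles[a[i], ], profiles[b[i], ]),
           numeric(1))
  }
  e <- dplyr::filter(net$edges, !self_loop)
  ppi_pcc <- pcc_of(e$protein_a, e$protein_b)
  set.seed(1)
  ra <- sample(net$nodes, 500, replace = TRUE)
  rb <- sample(net$nodes, 500, replace = TRUE)
  keep <- ra != rb
  rand_pcc <- pcc_of(ra[keep], rb[keep])
  rep <- wilcoxon_rank_sum(ppi_pcc[!is.na(ppi_pcc)],
                           rand_pcc[!is.na(rand_pcc)],
                           alternative = "greater")
  expect_lt(rep$p_value, 0.01)
})

test_that("inconsistent configurations are rejected", {
  expect_error(world_config(n_proteins = 10, n_complexes = 4,
                            complex_size_range = c(5, 10)),
               "config error")
  expect_error(world_config(n_ref_organisms = 0), "config error")
})
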