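test_that("Wang term similarity matches hand-computed values", {
  dag <- read_obo_subset(sibling_obo())
  expect_equal(go_term_similarity("GO:0000011", "GO:0000011", dag), 1)
  ## two leaves one is_a hop below a shared root:
  ## S-values {self: 1, root: 0.8}; sim = (0.8 + 0.8) / (1.8 + 1.8)
  expect_equal(round(go_term_similarity("GO:0000011", "GO:0000012", dag), 4),
               0.4444)
  expect_equal(go_term_similarity("GO:0000011", "GO:0000012", dag),
               go_term_similarity("GO:0000012", "GO:0000011", dag))

  ## disjoint components of one namespace share nothing
  two_comp <- write_temp_obo(c(
    "[Term]", "id: GO:0000021", "namespace: biological_process", "",
    "[Term]", "id: GO:0000022", "namespace: biological_process",
    "is_a: GO:0000021", "",
    "[Term]", "id: GO:0000023", "namespace: biological_process", "",
    "[Term]", "id: GO:0000024", "namespace: biological_process",
    "is_a: GO:0000023"
  ))
  dag2 <- read_obo_subset(two_comp)
  expect_equal(go_term_similarity("GO:0000022", "GO:0000024", dag2), 0)

  cross <- write_temp_obo(c(
    "[Term]", "id: GO:0000031", "namespace: biological_process", "",
    "[Term]", "id: GO:0000032", "namespace: molecular_function"
  ))
  dag3 <- read_obo_subset(cross)
  expect_error(go_term_similarity("GO:0000031", "GO:0000032", dag3),
               "namespaces")

  ## part_of carries weight 0.6
  po <- write_temp_obo(c(
    "[Term]", "id: GO:0000041", "namespace: biological_process", "",
    "[Term]", "id: GO:0000042", "namespace: biological_process",
    "relationship: part_of GO:0000041", "",
    "[Term]", "id: GO:0000043", "namespace: biological_process",
    "is_a: GO:0000041"
  ))
  dag4 <- read_obo_subset(po)
  expect_equal(go_term_similarity("GO:0000042", "GO:0000043", dag4),
               (0.6 + 0.8) / (1.6 + 1.8))
})

test_that("similarity decays along is_a chains", {
  dag <- read_obo_subset(chain_obo())  # GO:3 is_a GO:2 is_a GO:1
  s_near <- go_term_similarity("GO:0000003", "GO:0000002", dag)
  s_far <- go_term_similarity("GO:0000003", "GO:0000001", dag)
  expect_gt(s_near, s_far)
  expect_gt(s_far, 0)
})

test_that("protein similarity uses best-match averaging over namespaces", {
  dag <- read_obo_subset(sibling_obo())
  ann <- tibble::tibble(
    protein_id = c("A", "B", "B"),
    term = c("GO:0000011", "GO:0000011", "GO:0000012")
  )
  ## row max for A = 1; column maxima for B = (1, 0.4444);
  ## BMA = (1 + (1 + 0.4444)/2) / 2
  expect_equal(
    round(protein_functional_similarity("A", "B", ann, dag), 4),
    round((1 + (1 + (0.8 + 0.8) / 3.6) / 2) / 2, 4)
  )
  same <- tibble::tibble(protein_id = c("A", "B"), term = "GO:0000011")
  expect_equal(protein_functional_similarity("A", "B", same, dag), 1)

  ## proteins annotated only in different namespaces are undefined
  mixed_obo <- write_temp_obo(c(
    "[Term]", "id: GO:0000051", "namespace: biological_process", "",
    "[Term]", "id: GO:0000052", "namespace: molecular_function"
  ))
  dag2 <- read_obo_subset(mixed_obo)
  ann2 <- tibble::tibble(protein_id = c("A", "B"),
                         term = c("GO:0000051", "GO:0000052"))
  expect_true(is.na(protein_functional_similarity("A", "B", ann2, dag2)))
})

test_that("rank-sum test is exact when tie-free and small", {
  rep1 <- wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")
  expect_equal(rep1$p_value, 1 / 6)
  expect_match(rep1$method, "exact")

  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2, 2))$p_value, 1)

  set.seed(12)
  x <- rnorm(50) + 3
  y <- rnorm(50)
  expect_lt(wilcoxon_rank_sum(x, y, alternative = "greater")$p_value, 1e-6)
})

test_that("exact P matches enumeration and approximates well at n = 12", {
  set.seed(13)
  for (rep in 1:15) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    vals <- sample(1:100, nx + ny)         # distinct -> tie-free
    x <- vals[seq_len(nx)]
    y <- vals[-seq_len(nx)]
    alt <- sample(c("greater", "less", "two.sided"), 1)
    expect_equal(wilcoxon_rank_sum(x, y, alternative = alt)$p_value,
                 wilcoxon_enum_oracle(x, y, alt), tolerance = 1e-12)
  }
  for (rep in 1:10) {
    vals <- sample(1:500, 24)
    x <- vals[1:12]
    y <- vals[13:24]
    exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
    approx <- wilcoxon_rank_sum(x, y)$p_value   # n = 24: approximate path
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("edge correlations behave like Pearson correlation", {
  net <- net_from_pairs("a", "b", "c", "d")
  expr <- tibble::tibble(
    protein_id = c("a", "b", "c", "d"),
    t1 = c(1, 3, 1, 3), t2 = c(2, 5, 2, 2), t3 = c(3, 7, 3, 1)
  )
  rep <- transcription_pcc_validation(net, expr, n_random = 3, seed = 1)
  pcc <- sort(attr(rep, "x_values"))
  expect_equal(pcc, c(-1, 1))   # (a,b) affine: +1; (c,d) reversed: -1

  short <- expr[, 1:3]
  expect_error(transcription_pcc_validation(net, short, 3, 1),
               "3 time points")
})

test_that("random-network comparisons are seeded and honest on nulls", {
  w <- generate_world(4, small_world_config())
  net <- remove_self_loops(w$truth_network)
  r1 <- compare_with_random(net, w$go, w$go_dag, n_random = 3, seed = 42)
  r2 <- compare_with_random(net, w$go, w$go_dag, n_random = 3, seed = 42)
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(attr(r1, "y_values"), attr(r2, "y_values"))

  ## a complete graph is rewiring-invariant: nothing to detect
  k6 <- complete_net(6)
  expr <- tibble::tibble(protein_id = k6$nodes,
                         t1 = runif(6, 1, 50), t2 = runif(6, 1, 50),
                         t3 = runif(6, 1, 50))
  rep <- transcription_pcc_validation(k6, expr, n_random = 5, seed = 3)
  expect_gt(rep$p_value, 0.05)
})

test_that("similarity distributions skip undefined pairs and stay in [0,1]", {
  w <- generate_world(6, small_world_config())
  net <- remove_self_loops(w$truth_network)
  dist <- network_similarity_distribution(net, w$go, w$go_dag)
  expect_true(all(dist$similarity >= 0 & dist$similarity <= 1))
  expect_gte(attr(dist, "n_skipped"), 0)
  expect_equal(nrow(dist) + attr(dist, "n_skipped"),
               sum(!net$edges$self_loop))
})
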