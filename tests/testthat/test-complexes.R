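uniform_expr <- function(ids, labels = c("t1", "t2", "t3"), value = 10) {
  out <- tibble::tibble(protein_id = ids)
  for (lb in labels) out[[lb]] <- value
  out
}

test_that("time-series networks are one per label", {
  net <- path_net(4)
  expr <- uniform_expr(net$nodes)
  tsn <- build_time_series_networks(net, expr)
  expect_named(tsn, c("t1", "t2", "t3"))
  for (cn in tsn) expect_equal(nrow(cn$edges), 3)

  expr2 <- uniform_expr(net$nodes, labels = c("t1", "t2"))
  expr2$t2[1] <- 0.1                    # v01 inactive only at t2
  tsn2 <- build_time_series_networks(net, expr2)
  expect_true("v01" %in% tsn2$t1$nodes)
  expect_false("v01" %in% tsn2$t2$nodes)
})

test_that("an isolated clique is found as exactly one complex", {
  clique <- complete_net(4)
  net <- merge_networks(clique, net_from_pairs("x1", "x2"))
  tsn <- build_time_series_networks(net, uniform_expr(net$nodes))
  cx <- detect_complexes(tsn)
  expect_equal(nrow(cx$complexes), 1)
  expect_setequal(cx$complexes$members[[1]], clique$nodes)
  expect_equal(cx$complexes$time_labels, "t1,t2,t3")
})

test_that("the greedy acceptance rule traces the 3-path case", {
  net <- path_net(3)
  tsn <- build_time_series_networks(net, uniform_expr(net$nodes,
                                                      labels = "t1"))
  cx <- detect_complexes(tsn, lambda = 1, min_size = 3)
  expect_equal(nrow(cx$complexes), 1)
  expect_setequal(cx$complexes$members[[1]], net$nodes)
})

test_that("fully inactive input yields an empty complex set", {
  net <- complete_net(5)
  expr <- uniform_expr(net$nodes, value = 0.2)
  cx <- detect_complexes(build_time_series_networks(net, expr))
  expect_equal(nrow(cx$complexes), 0)
})

test_that("complexes are deterministic, size-monotone and connected", {
  w <- generate_world(2, small_world_config())
  net <- remove_self_loops(w$truth_network)
  tsn <- build_time_series_networks(net, w$expression)
  cx3 <- detect_complexes(tsn, min_size = 3)
  cx3b <- detect_complexes(tsn, min_size = 3)
  expect_identical(cx3$complexes, cx3b$complexes)

  cx4 <- detect_complexes(tsn, min_size = 4)
  expect_lte(nrow(cx4$complexes), nrow(cx3$complexes))

  for (members in cx3$complexes$members) {
    ok <- any(vapply(tsn, function(cn) {
      all(members %in% cn$nodes) &&
        igraph::is_connected(igraph::induced_subgraph(
          bacppi:::to_igraph(cn), members))
    }, logical(1)))
    expect_true(ok)
  }
})

test_that("entropy scoring summarises complexes against annotations", {
  cx <- detect_complexes(build_time_series_networks(
    complete_net(4), uniform_expr(complete_net(4)$nodes, labels = "t1")))
  ann <- tibble::tibble(protein_id = complete_net(4)$nodes,
                        category = "J", priority = 1L)
  scores <- score_complexes(cx, ann)
  expect_equal(scores$entropy, 0)
  expect_false(scores$all_unknown)
  expect_equal(attr(scores, "low_entropy_fraction"), 1)

  unann <- score_complexes(cx, ann[0, ])
  expect_true(unann$all_unknown)
  expect_equal(unann$entropy, 0)
})

test_that("detected complexes are more function-coherent than random sets", {
  ## module-rich world: planted complexes dominate the network
  cfg <- world_config(
    n_proteins = 100, n_background_pairs = 30, n_reference_noise = 40,
    n_decoy_hits = 20, n_secondary_hits = 10, n_domains = 40, n_ddis = 25,
    n_domain_decoys = 10, n_complexes = 4, complex_size_range = c(5, 8),
    go_terms_per_namespace = 30
  )
  w <- generate_world(8, cfg)
  net <- remove_self_loops(w$truth_network)
  tsn <- build_time_series_networks(net, w$expression)
  scores <- score_complexes(detect_complexes(tsn), w$cog)
  expect_gt(nrow(scores), 0)

  set.seed(88)
  random_entropy <- vapply(seq_len(nrow(scores) * 5), function(i) {
    size <- sample(scores$size, 1)
    functional_entropy(sample(net$nodes, size), w$cog)$entropy
  }, numeric(1))
  expect_lt(median(scores$entropy), median(random_entropy))
})
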