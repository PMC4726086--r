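test_that("channel merging does exact unordered-set algebra", {
  a <- tibble::tibble(protein_a = c("a", "c"), protein_b = c("b", "d"))
  b <- tibble::tibble(protein_a = c("c", "e"), protein_b = c("d", "f"))
  net <- merge_networks(a, b)
  ms <- attr(net, "merge_stats")
  expect_equal(ms[c("n_a", "n_b", "n_shared", "n_union")],
               list(n_a = 2L, n_b = 2L, n_shared = 1L, n_union = 3L))

  disjoint <- merge_networks(random_net(8, 0.4),
                             tibble::tibble(protein_a = "x1",
                                            protein_b = "x2"))
  expect_equal(attr(disjoint, "merge_stats")$n_shared, 0)

  same <- merge_networks(a, a)
  expect_equal(attr(same, "merge_stats")$n_shared, 2)
  expect_equal(nrow(same$edges), 2)

  ## re-merging the merged network with a channel is idempotent
  again <- merge_networks(net, a)
  expect_identical(again$edges[, c("protein_a", "protein_b")],
                   net$edges[, c("protein_a", "protein_b")])
})

test_that("self-loop removal drops loops and stranded nodes", {
  net <- net_from_pairs("a", "a", "a", "b")
  clean <- remove_self_loops(net)
  expect_equal(nrow(clean$edges), 1)
  expect_equal(clean$nodes, c("a", "b"))
  expect_equal(attr(clean, "removal_stats")$n_self_loops_removed, 1)

  only_loop <- remove_self_loops(net_from_pairs("a", "a"))
  expect_equal(length(only_loop$nodes), 0)

  untouched <- remove_self_loops(path_net(3))
  expect_identical(untouched$edges, path_net(3)$edges)
})

test_that("topology matches hand-enumerated toy graphs", {
  tri <- glance(topology_summary(net_from_pairs("a","b","b","c","a","c")))
  expect_equal(tri$clustering_coefficient, 1)
  expect_equal(tri$average_path_length, 1)
  expect_equal(tri$n_components, 1)

  p3 <- topology_summary(path_net(3))
  expect_equal(glance(p3)$average_degree, 4 / 3)
  expect_equal(glance(p3)$clustering_coefficient, 0)
  expect_equal(glance(p3)$average_path_length, 4 / 3)  # (1 + 1 + 2) / 3
  mid <- tidy(p3)[tidy(p3)$degree == 2, ]
  expect_equal(mid$betweenness, 1)                     # 1 pair / 1 possible
  expect_equal(mid$closeness, 2 / 2)
  expect_equal(mid$avg_shortest_path, 1)

  two <- glance(topology_summary(net_from_pairs("a","b","c","d")))
  expect_equal(two$n_components, 2)
  expect_equal(two$average_path_length, 1)

  expect_error(topology_summary(ppi_network()), "empty")
  expect_error(topology_summary(net_from_pairs("a", "a")), "self-loops")
})

test_that("topology agrees with Floyd-Warshall and triangle enumeration", {
  set.seed(31)
  for (rep in 1:5) {
    net <- random_net(sample(10:30, 1), runif(1, 0.1, 0.3))
    topo <- topology_summary(net, include_degree_one = FALSE)
    nodes <- tidy(topo)
    d <- fw_distances(net)

    ## per-node degree and clustering
    a <- adj_matrix(net)
    expect_equal(nodes$degree, unname(rowSums(a))[match(nodes$protein_id,
                                                        rownames(a))])
    expect_equal(nodes$clustering,
                 clustering_oracle(net)[match(nodes$protein_id,
                                              rownames(a))])
    ## per-node average shortest path and closeness
    for (v in nodes$protein_id) {
      dv <- d[v, setdiff(colnames(d), v)]
      reach <- dv[is.finite(dv)]
      if (length(reach)) {
        expect_equal(nodes$avg_shortest_path[nodes$protein_id == v],
                     mean(reach))
        expect_equal(nodes$closeness[nodes$protein_id == v],
                     length(reach) / sum(reach))
      }
    }
    ## network-level path length over connected ordered pairs
    off <- d[upper.tri(d) | lower.tri(d)]
    expect_equal(glance(topo)$average_path_length,
                 mean(off[is.finite(off)]))
    deg <- rowSums(a)
    cc <- clustering_oracle(net)
    expect_equal(glance(topo)$clustering_coefficient,
                 mean(cc[deg >= 2]))
  }
})

test_that("power-law MLE matches the closed form and flags degeneracy", {
  fit <- fit_powerlaw(c(1, 1, 1, 2, 4))
  expect_equal(fit$gamma, 1 + 5 / (log(2) + log(4)), tolerance = 1e-12)
  expect_equal(fit$gamma, 3.405, tolerance = 1e-3)
  expect_error(fit_powerlaw(c(3, 3)), "distinct")
  expect_gt(fit$gamma_discrete, 1)
})

test_that("the Hurwitz zeta helper agrees with an independent zeta", {
  for (s in c(1.5, 2, 2.5, 3.7)) {
    expect_equal(bacppi:::hurwitz_zeta(s, 1), pracma::zeta(s),
                 tolerance = 1e-8)
  }
  ## shift identity: zeta(s, 3) = zeta(s, 1) - 1 - 2^-s
  expect_equal(bacppi:::hurwitz_zeta(2.2, 3),
               bacppi:::hurwitz_zeta(2.2, 1) - 1 - 2^-2.2,
               tolerance = 1e-8)
})

test_that("rewiring preserves degrees, determinism, and triangle rigidity", {
  net <- with(list(), {set.seed(5); random_net(30, 0.15)})
  deg_of <- function(n) {
    sort(table(c(n$edges$protein_a, n$edges$protein_b)))
  }
  for (s in c(1, 2, 3)) {
    rw <- rewire_preserving_degrees(net, seed = s)
    expect_equal(deg_of(rw), deg_of(net))
  }
  expect_identical(rewire_preserving_degrees(net, seed = 4)$edges,
                   rewire_preserving_degrees(net, seed = 4)$edges)
  r1 <- rewire_preserving_degrees(net, seed = 1)$edges
  r2 <- rewire_preserving_degrees(net, seed = 2)$edges
  expect_false(identical(r1, r2))

  tri <- net_from_pairs("a", "b", "b", "c", "a", "c")
  expect_identical(rewire_preserving_degrees(tri, seed = 1)$edges,
                   tri$edges)
  expect_warning(rewire_preserving_degrees(net_from_pairs("a", "b")),
                 "unchanged")
})
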