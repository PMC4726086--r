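toy_expr <- function(ids, ...) {
  vals <- list(...)
  out <- tibble::tibble(protein_id = ids)
  for (lb in names(vals)) out[[lb]] <- vals[[lb]]
  out
}

test_that("activity filtering removes sub-threshold genes and their edges", {
  net <- net_from_pairs("a", "b", "b", "c")
  expr <- toy_expr(c("a", "b", "c"), t1 = c(5, 5, 5), t2 = c(5, 0.5, 5))

  full <- active_subnetwork(net, expr, "t1")
  expect_equal(full$nodes, c("a", "b", "c"))
  expect_equal(nrow(full$edges), 2)

  cut <- active_subnetwork(net, expr, "t2")
  expect_equal(cut$nodes, c("a", "c"))
  expect_equal(nrow(cut$edges), 0)

  none <- active_subnetwork(net, toy_expr(c("a", "b", "c"),
                                          t1 = c(0.1, 0.2, 0)), "t1")
  expect_equal(length(none$nodes), 0)

  ## genes missing from the matrix count as inactive
  partial <- active_subnetwork(net, toy_expr(c("a", "b"),
                                             t1 = c(5, 5)), "t1")
  expect_equal(partial$nodes, c("a", "b"))

  expect_error(active_subnetwork(net, expr, "t9"), "unknown time label")
})

test_that("raising the threshold shrinks the active subnetwork", {
  set.seed(3)
  net <- random_net(20, 0.2)
  expr <- toy_expr(net$nodes, t1 = runif(20, 0, 20))
  lo <- active_subnetwork(net, expr, "t1", threshold = 1)
  hi <- active_subnetwork(net, expr, "t1", threshold = 5)
  expect_true(all(hi$nodes %in% lo$nodes))
  key <- function(n) paste(n$edges$protein_a, n$edges$protein_b)
  expect_true(all(key(hi) %in% key(lo)))
})

test_that("normalized difference follows its closed form", {
  expect_equal(normalized_difference(30, 10), 0.5)
  expect_equal(normalized_difference(7, 7), 0)
  expect_equal(normalized_difference(5, 15), 0.5)
  expect_equal(normalized_difference(50, 150), 0.5)   # scale invariance
  set.seed(4)
  a <- runif(50, 0.1, 100)
  b <- runif(50, 0.1, 100)
  expect_equal(normalized_difference(a, b), normalized_difference(b, a))
  expect_equal(normalized_difference(3.7 * a, 3.7 * b),
               normalized_difference(a, b))
  expect_true(all(normalized_difference(a, b) >= 0 &
                    normalized_difference(a, b) <= 1))
  expect_error(normalized_difference(0, 0), "undefined")
  expect_error(normalized_difference(-1, 2), "non-negative")
})

test_that("difference distributions count pairs per group", {
  net <- net_from_pairs("a", "b")
  net <- ppi_network(net$edges, nodes = c("a", "b", "c"))
  expr <- toy_expr(c("a", "b", "c"), t1 = c(10, 30, 5))
  cond <- active_subnetwork(net, expr, "t1")
  dist <- difference_distributions(cond, expr,
                                   groups = c("control", "all_ppi"))
  expect_equal(sum(dist$group == "control"), 3)
  expect_equal(sum(dist$group == "all_ppi"), 1)
  expect_equal(dist$value[dist$group == "all_ppi"], 0.5)
  med <- attr(dist, "medians")
  expect_equal(med$median[med$group == "all_ppi"], 0.5)

  ## category group with no qualifying edge is flagged empty
  ann <- tibble::tibble(protein_id = "a", category = "E", priority = 1L)
  dist2 <- difference_distributions(cond, expr, ann,
                                    groups = c("all_ppi", "category:E"))
  expect_equal(attr(dist2, "empty_groups"), "category:E")

  ## both-endpoint rule for category subnetworks
  ann2 <- tibble::tibble(protein_id = c("a", "b"), category = "E",
                         priority = 1L)
  dist3 <- difference_distributions(cond, expr, ann2,
                                    groups = "category:E")
  expect_equal(nrow(dist3), 1)
})

test_that("interacting pairs are closer in expression than random pairs", {
  w <- generate_world(7, small_world_config())
  net <- remove_self_loops(w$truth_network)
  cond <- active_subnetwork(net, w$expression, "11h")
  dist <- difference_distributions(cond, w$expression,
                                   groups = c("control", "all_ppi"))
  med <- attr(dist, "medians")
  expect_lt(med$median[med$group == "all_ppi"],
            med$median[med$group == "control"])
})

test_that("without expression signal the group medians coincide", {
  deltas <- vapply(1:8, function(s) {
    w <- generate_world(s, small_world_config(expression_signal = FALSE,
                                              go_signal = FALSE))
    net <- remove_self_loops(w$truth_network)
    cond <- active_subnetwork(net, w$expression, "22h")
    med <- attr(difference_distributions(cond, w$expression), "medians")
    med$median[med$group == "control"] - med$median[med$group == "all_ppi"]
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.05)
})

test_that("local topology comparison is isomorphism-invariant", {
  set.seed(10)
  net <- random_net(25, 0.2)
  expr <- toy_expr(net$nodes, t1 = rep(5, 25), t2 = rep(5, 25))
  c1 <- active_subnetwork(net, expr, "t1")
  c2 <- active_subnetwork(net, expr, "t2")
  same <- compare_local_topology(list(a = c1, b = c2))
  expect_equal(nrow(same), 5)
  expect_true(all(same$p_value == 1))

  ## relabeled copy: identical metric distributions
  perm <- setNames(sprintf("w%02d", seq_along(net$nodes)), net$nodes)
  net2 <- ppi_network(tibble::tibble(
    protein_a = unname(perm[net$edges$protein_a]),
    protein_b = unname(perm[net$edges$protein_b])
  ), nodes = unname(perm))
  expr2 <- toy_expr(net2$nodes, t1 = rep(5, 25))
  c3 <- active_subnetwork(net2, expr2, "t1")
  iso <- compare_local_topology(list(orig = c1, relab = c3))
  expect_true(all(iso$p_value == 1))
})

test_that("a strong density contrast is detected in degrees", {
  set.seed(20)
  dense <- random_net(40, 0.5)
  sparse <- random_net(40, 0.06)
  expr_d <- toy_expr(dense$nodes, t1 = rep(5, 40))
  expr_s <- toy_expr(sparse$nodes, t1 = rep(5, 40))
  cmp <- compare_local_topology(list(
    dense = active_subnetwork(dense, expr_d, "t1"),
    sparse = active_subnetwork(sparse, expr_s, "t1")
  ))
  expect_lt(cmp$p_value[cmp$metric == "degree"], 0.01)

  tiny <- ppi_network(nodes = c("a", "b"))
  tiny_cond <- structure(c(tiny, list(time_label = "t1")),
                         class = c("condition_network", "ppi_network"))
  expect_warning(
    compare_local_topology(list(a = active_subnetwork(dense, expr_d, "t1"),
                                b = active_subnetwork(sparse, expr_s, "t1"),
                                c = tiny_cond)),
    "< 3 nodes"
  )
})
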