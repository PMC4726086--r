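cog_tbl <- function(ids, cats) {
  tibble::tibble(protein_id = ids, category = cats, priority = 1L)
}

test_that("COG heat map reproduces the binomial-null toy value", {
  ## 6 single-label proteins (3 x I-like 'C', 3 x J), 5 edges, 4 between
  ann <- cog_tbl(sprintf("p%d", 1:6), rep(c("C", "J"), each = 3))
  net <- net_from_pairs("p1", "p4", "p1", "p5", "p2", "p4", "p3", "p6",
                        "p1", "p2")
  hm <- cog_heatmap(net, ann)
  expect_equal(hm$n, 6)
  expect_equal(hm$n_interactions, 5)
  expect_equal(hm$observed["C", "J"], 4)
  expect_equal(hm$expected["C", "J"], 3)
  expect_equal(round(hm$z["C", "J"], 4), 0.9129)
})

test_that("heat map counts are conserved and invariant to relabeling", {
  set.seed(61)
  net <- random_net(20, 0.25)
  ids <- net$nodes
  ann <- cog_tbl(ids, sample(c("C", "G", "J", "K"), 20, replace = TRUE))
  hm <- cog_heatmap(net, ann)

  ## single-label world: class-pair counts partition the edges
  upper <- hm$observed[upper.tri(hm$observed, diag = TRUE)]
  expect_equal(sum(upper), hm$n_interactions)
  expect_true(isSymmetric(hm$observed))
  expect_true(isSymmetric(unname(hm$z)) ||
                all(is.na(hm$z) == t(is.na(hm$z))))

  ## every finite cell satisfies the Z definition
  ok <- !is.na(hm$z)
  expect_equal(
    hm$z[ok],
    (hm$observed[ok] - hm$expected[ok]) /
      sqrt(hm$expected[ok] * (1 - hm$expected[ok] / hm$n_interactions))
  )

  ## permuting protein labels leaves the matrix unchanged
  perm <- setNames(sample(ids), ids)
  net2 <- ppi_network(tibble::tibble(
    protein_a = unname(perm[net$edges$protein_a]),
    protein_b = unname(perm[net$edges$protein_b])
  ))
  ann2 <- cog_tbl(unname(perm[ann$protein_id]), ann$category)
  hm2 <- cog_heatmap(net2, ann2)
  expect_equal(hm2$z, hm$z)
})

test_that("multi-label proteins contribute once per category combination", {
  ann <- tibble::tibble(
    protein_id = c("a", "a", "b"),
    category = c("C", "J", "C"),
    priority = c(1L, 2L, 1L)
  )
  hm <- cog_heatmap(net_from_pairs("a", "b"), ann)
  expect_equal(hm$observed["C", "C"], 1)
  expect_equal(hm$observed["C", "J"], 1)
  expect_equal(hm$n_interactions, 1)
})

test_that("Fisher enrichment equals the hypergeometric tail", {
  bg <- sprintf("p%03d", 1:100)
  ann <- cog_tbl(bg[1:10], "G")
  members <- c(bg[1:4], bg[50])       # 4 of 5 in category G
  res <- fisher_enrichment(members, bg, ann)
  expect_equal(res$p_value[res$category == "G"],
               hyper_tail_oracle(4, 10, 5, 100), tolerance = 1e-12)
  expect_equal(round(res$p_value[res$category == "G"], 6),
               round(9.6497e-4, 6), tolerance = 1e-3)
  expect_true(res$enriched[res$category == "G"])

  ## random tables against the oracle
  set.seed(41)
  for (rep in 1:20) {
    n_bg <- sample(30:200, 1)
    bg2 <- sprintf("q%03d", seq_len(n_bg))
    carriers <- sample(bg2, sample(5:20, 1))
    ann2 <- cog_tbl(carriers, "K")
    members2 <- sample(bg2, sample(5:15, 1))
    a <- sum(members2 %in% carriers)
    res2 <- fisher_enrichment(members2, bg2, ann2)
    expect_equal(res2$p_value[res2$category == "K"],
                 hyper_tail_oracle(a, length(carriers), length(members2),
                                   n_bg),
                 tolerance = 1e-9)
  }

  ## depletion direction and degenerate set
  half <- cog_tbl(bg[1:50], "E")
  res3 <- fisher_enrichment(bg[51:55], bg, half)
  expect_gte(res3$p_value[res3$category == "E"], 0.5)
  res4 <- fisher_enrichment(bg, bg, half)
  expect_equal(res4$p_value[res4$category == "E"], 1)
  expect_error(fisher_enrichment(character(), bg, half), "empty")
  expect_error(fisher_enrichment("zz", bg, half), "subset")
})

test_that("functional entropy follows the Shannon formula on primary labels", {
  ann <- cog_tbl(letters[1:4], c("J", "J", "J", "J"))
  expect_equal(functional_entropy(letters[1:4], ann)$entropy, 0)

  ann2 <- cog_tbl(letters[1:4], c("J", "J", "K", "K"))
  expect_equal(functional_entropy(letters[1:4], ann2)$entropy, 1)

  ann3 <- cog_tbl(letters[1:3], c("J", "K", "L"))
  expect_equal(functional_entropy(letters[1:3], ann3)$entropy, log2(3))

  ## unannotated members collapse into one 'unknown' category
  e <- functional_entropy(c("x", "y", "z"), ann3[0, ])
  expect_equal(e$entropy, 0)
  expect_true(e$all_unknown)

  ## only the first-listed category counts
  multi <- tibble::tibble(protein_id = c("a", "a", "b"),
                          category = c("J", "K", "J"),
                          priority = c(1L, 2L, 1L))
  expect_equal(functional_entropy(c("a", "b"), multi)$entropy, 0)
})

test_that("entropy is maximal exactly at uniform composition", {
  set.seed(8)
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    per <- sample(1:4, 1)
    cats <- sample(cog_categories(), k)
    ids <- sprintf("m%02d", seq_len(k * per))
    ann <- cog_tbl(ids, rep(cats, each = per))
    expect_equal(functional_entropy(ids, ann)$entropy, log2(k))

    skewed <- cog_tbl(ids, c(rep(cats[1], per + 1),
                             rep(cats[-1], each = per))[seq_along(ids)])
    if (k > 1 && per > 1) {
      expect_lt(functional_entropy(ids, skewed)$entropy, log2(k))
    }
  }
})

test_that("module-assisted annotation assigns enriched categories", {
  bg <- sprintf("p%02d", 1:40)
  ann <- dplyr::bind_rows(
    cog_tbl(bg[1:4], "J"),
    cog_tbl(bg[5], "S"),                 # uninformative -> assignable
    cog_tbl(bg[10:30], sample(c("K", "E", "G"), 21, replace = TRUE))
  )
  out <- annotate_uncharacterized(list(c(bg[1:4], bg[5])), ann, bg)
  expect_equal(out$protein_id, bg[5])
  expect_equal(out$category, "J")

  ## no enrichment -> no assignment
  none <- annotate_uncharacterized(list(bg[c(10, 15, 20)]), ann, bg)
  expect_equal(nrow(none), 0)

  ## protein in two complexes gets the smaller-P assignment
  ann2 <- dplyr::bind_rows(
    cog_tbl(sprintf("a%d", 1:6), "J"),
    cog_tbl(sprintf("b%d", 1:3), "K"),
    cog_tbl(sprintf("c%d", 1:30), "E")
  )
  bg2 <- c(sprintf("a%d", 1:6), sprintf("b%d", 1:3),
           sprintf("c%d", 1:30), "u1")
  both <- annotate_uncharacterized(
    list(cx1 = c(sprintf("a%d", 1:6), "u1"),
         cx2 = c(sprintf("b%d", 1:3), "u1")),
    ann2, bg2)
  expect_equal(nrow(both), 1)
  expect_equal(both$category, "J")       # 6/39 J beats 3/39 K in tail P
})
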