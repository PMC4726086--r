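# Independent oracles and tiny graph builders shared across the suite.
# Every oracle here is deliberately naive (enumeration, Floyd-Warshall,
# closed-form sums) and never calls the code path it checks.

net_from_pairs <- function(...) {
  p <- c(...)
  ppi_network(tibble::tibble(
    protein_a = p[seq(1, length(p), 2)],
    protein_b = p[seq(2, length(p), 2)]
  ))
}

star_net <- function(k = 4) {
  net_from_pairs(rbind("hub", sprintf("leaf%02d", seq_len(k))))
}

path_net <- function(n) {
  ids <- sprintf("v%02d", seq_len(n))
  net_from_pairs(rbind(ids[-n], ids[-1]))
}

cycle_net <- function(n) {
  ids <- sprintf("v%02d", seq_len(n))
  net_from_pairs(rbind(ids, ids[c(2:n, 1)]))
}

complete_net <- function(n) {
  ids <- sprintf("v%02d", seq_len(n))
  pr <- t(combn(ids, 2))
  ppi_network(tibble::tibble(protein_a = pr[, 1], protein_b = pr[, 2]))
}

random_net <- function(n, p) {
  ids <- sprintf("v%02d", seq_len(n))
  pr <- t(combn(ids, 2))
  keep <- stats::runif(nrow(pr)) < p
  ppi_network(tibble::tibble(protein_a = pr[keep, 1],
                             protein_b = pr[keep, 2]),
              nodes = ids)
}

## dense adjacency matrix over net$nodes
adj_matrix <- function(net) {
  nodes <- net$nodes
  a <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  e <- net$edges[!net$edges$self_loop, ]
  for (i in seq_len(nrow(e))) {
    a[e$protein_a[i], e$protein_b[i]] <- 1
    a[e$protein_b[i], e$protein_a[i]] <- 1
  }
  a
}

## Floyd-Warshall shortest paths
fw_distances <- function(net) {
  a <- adj_matrix(net)
  n <- nrow(a)
  d <- ifelse(a > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

## local clustering by explicit triangle counting
clustering_oracle <- function(net) {
  a <- adj_matrix(net)
  vapply(seq_len(nrow(a)), function(v) {
    nb <- which(a[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(a[nb, nb]) / 2
    2 * links / (k * (k - 1))
  }, numeric(1))
}

## hypergeometric upper tail P(X >= a) for a 2x2 enrichment table
hyper_tail_oracle <- function(a, n_category, n_set, n_background) {
  k <- a:min(n_category, n_set)
  sum(choose(n_category, k) *
        choose(n_background - n_category, n_set - k)) /
    choose(n_background, n_set)
}

## exact Wilcoxon rank-sum by enumerating all group assignments
wilcoxon_enum_oracle <- function(x, y, alternative) {
  nx <- length(x)
  vals <- c(x, y)
  stopifnot(!anyDuplicated(vals))
  u_of <- function(ix) {
    r <- rank(vals)
    sum(r[ix]) - nx * (nx + 1) / 2
  }
  u_obs <- u_of(seq_len(nx))
  sets <- combn(length(vals), nx)
  us <- apply(sets, 2, u_of)
  switch(alternative,
    greater = mean(us >= u_obs),
    less = mean(us <= u_obs),
    two.sided = min(1, 2 * min(mean(us >= u_obs), mean(us <= u_obs)))
  )
}

## DDI prediction by the naive triple loop
ddi_brute_oracle <- function(assignment, ddis) {
  proteins <- unique(assignment$protein_id)
  out <- list()
  for (i in seq_along(proteins)) {
    for (j in i:length(proteins)) {
      X <- proteins[i]; Y <- proteins[j]
      dx <- assignment$domain[assignment$protein_id == X]
      dy <- assignment$domain[assignment$protein_id == Y]
      hit <- FALSE
      for (k in seq_len(nrow(ddis))) {
        m <- ddis$domain_a[k]; n <- ddis$domain_b[k]
        if ((m %in% dx && n %in% dy) || (n %in% dx && m %in% dy)) {
          hit <- TRUE
          break
        }
      }
      if (hit) {
        out[[length(out) + 1]] <- tibble::tibble(
          protein_a = min(X, Y), protein_b = max(X, Y))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(protein_a = character(), protein_b = character()))
  }
  dplyr::arrange(dplyr::bind_rows(out), protein_a, protein_b)
}

## interolog transfer from a known ortholog map (loop over reference edges)
interolog_brute_oracle <- function(map, reference_edges) {
  out <- list()
  for (e in seq_len(nrow(reference_edges))) {
    org <- reference_edges$organism[e]
    ta <- map$query_id[map$subject_organism == org &
                         map$subject_id == reference_edges$protein_a[e]]
    tb <- map$query_id[map$subject_organism == org &
                         map$subject_id == reference_edges$protein_b[e]]
    for (A in ta) {
      for (B in tb) {
        out[[length(out) + 1]] <- tibble::tibble(
          protein_a = min(A, B), protein_b = max(A, B))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(protein_a = character(), protein_b = character()))
  }
  dplyr::distinct(dplyr::arrange(dplyr::bind_rows(out),
                                 protein_a, protein_b))
}

## small OBO files built in code
write_temp_obo <- function(lines) {
  f <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", lines), f)
  f
}

chain_obo <- function() {
  # leaf is_a mid is_a root (biological_process)
  write_temp_obo(c(
    "[Term]", "id: GO:0000001", "namespace: biological_process", "",
    "[Term]", "id: GO:0000002", "namespace: biological_process",
    "is_a: GO:0000001", "",
    "[Term]", "id: GO:0000003", "namespace: biological_process",
    "is_a: GO:0000002"
  ))
}

## root with two leaf children, one namespace
sibling_obo <- function() {
  write_temp_obo(c(
    "[Term]", "id: GO:0000010", "namespace: biological_process", "",
    "[Term]", "id: GO:0000011", "namespace: biological_process",
    "is_a: GO:0000010", "",
    "[Term]", "id: GO:0000012", "namespace: biological_process",
    "is_a: GO:0000010"
  ))
}

small_world_config <- function(...) {
  args <- list(
    n_proteins = 80, n_background_pairs = 40, n_reference_noise = 60,
    n_decoy_hits = 30, n_secondary_hits = 15, n_domains = 60, n_ddis = 60,
    n_domain_decoys = 20, n_complexes = 2, complex_size_range = c(4, 6),
    go_terms_per_namespace = 30
  )
  override <- list(...)
  args[names(override)] <- override
  do.call(world_config, args)
}
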