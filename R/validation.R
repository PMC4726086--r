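## Network quality assessment: GO semantic similarity of interacting
## proteins and transcription-profile correlation, each compared against
## degree-preserving random networks with the Wilcoxon rank-sum test.

## Edge weights of the Wang graph-based semantic similarity measure.
.wang_weights <- c(is_a = 0.8, part_of = 0.6)

## Upward index of a DAG: term -> list of (parent, weight) pairs.
wang_index <- function(dag) {
  if (!inherits(dag, "go_dag")) abort("dag must be a go_dag")
  w <- unname(.wang_weights[dag$parents$relation])
  split(
    data.frame(parent = dag$parents$parent, w = w,
               stringsAsFactors = FALSE),
    dag$parents$term
  )
}

## Wang S-values of `term`: named vector over its ancestor closure,
## S(term) = 1, S(t) = max over paths of the product of edge weights.
wang_svalues <- function(term, idx) {
  s <- setNames(1, term)
  queue <- term
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    up <- idx[[t]]
    if (is.null(up)) next
    for (k in seq_len(nrow(up))) {
      p <- up$parent[k]
      cand <- s[[t]] * up$w[k]
      if (is.na(s[p]) || cand > s[[p]]) {
        s[p] <- cand
        queue <- c(queue, p)
      }
    }
  }
  s
}

#' Wang semantic similarity of two GO terms
#'
#' Graph-based semantic similarity: each term is represented by the S-values
#' of its ancestors (the maximal product of edge weights along any upward
#' path, with weight 0.8 for `is_a` and 0.6 for `part_of`; the term itself
#' has S-value 1). The similarity is
#' `sum over shared ancestors of (S_A + S_B) / (SV(A) + SV(B))`, where SV is
#' the sum of a term's S-values. Terms with no shared ancestor score 0;
#' identical terms score 1.
#'
#' @param term_a,term_b GO term identifiers (must share a namespace).
#' @param dag A `go_dag` from [read_obo_subset()].
#' @return A similarity in `[0, 1]`.
#' @export
go_term_similarity <- function(term_a, term_b, dag) {
  check_terms(c(term_a, term_b), dag)
  if (dag$namespace[[term_a]] != dag$namespace[[term_b]]) {
    abort(sprintf("terms %s and %s are in different namespaces",
                  term_a, term_b))
  }
  wang_pair_similarity(term_a, term_b, wang_index(dag),
                       new.env(parent = emptyenv()))
}

check_terms <- function(terms, dag) {
  missing <- setdiff(terms, dag$terms)
  if (length(missing)) {
    abort(sprintf("term(s) not in the DAG: %s",
                  paste(head(missing, 3), collapse = ", ")))
  }
}

## Cached S-values + pairwise Wang similarity.
svalues_cached <- function(term, idx, cache) {
  s <- cache[[term]]
  if (is.null(s)) {
    s <- wang_svalues(term, idx)
    cache[[term]] <- s
  }
  s
}

wang_pair_similarity <- function(ta, tb, idx, cache) {
  if (ta == tb) return(1)
  sa <- svalues_cached(ta, idx, cache)
  sb <- svalues_cached(tb, idx, cache)
  common <- intersect(names(sa), names(sb))
  if (!length(common)) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

#' GO functional similarity of two proteins
#'
#' Best-match-average (BMA) combination of term similarities: within each GO
#' namespace where both proteins are annotated, the Wang similarity matrix
#' between their term sets is reduced to the average of the mean row maxima
#' and mean column maxima; the protein-level score is the mean over those
#' namespaces. Proteins with no shared annotated namespace have no defined
#' similarity (`NA`).
#'
#' @param protein_a,protein_b Protein identifiers.
#' @param annotations A GO annotation tibble (`protein_id`, `term`), as from
#'   [read_go_annotations()].
#' @param dag A `go_dag`.
#' @return A similarity in `[0, 1]`, or `NA` if undefined.
#' @export
protein_functional_similarity <- function(protein_a, protein_b, annotations,
                                          dag) {
  ann <- as_tibble(annotations)
  idx <- wang_index(dag)
  cache <- new.env(parent = emptyenv())
  terms_of <- function(p) unique(ann$term[ann$protein_id == p])
  protein_similarity_worker(terms_of(protein_a), terms_of(protein_b),
                            dag, idx, cache)
}

protein_similarity_worker <- function(terms_a, terms_b, dag, idx, cache) {
  if (!length(terms_a) || !length(terms_b)) return(NA_real_)
  check_terms(c(terms_a, terms_b), dag)
  ns_a <- dag$namespace[terms_a]
  ns_b <- dag$namespace[terms_b]
  shared_ns <- intersect(unique(ns_a), unique(ns_b))
  if (!length(shared_ns)) return(NA_real_)
  per_ns <- vapply(shared_ns, function(ns) {
    ta <- terms_a[ns_a == ns]
    tb <- terms_b[ns_b == ns]
    m <- matrix(0, length(ta), length(tb))
    for (i in seq_along(ta)) {
      for (j in seq_along(tb)) {
        m[i, j] <- wang_pair_similarity(ta[i], tb[j], idx, cache)
      }
    }
    (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
  }, numeric(1))
  mean(per_ns)
}

#' GO similarity distribution over network edges
#'
#' Computes the protein functional similarity for every edge where it is
#' defined; pairs with no shared annotated namespace are skipped and
#' counted.
#'
#' @param network A self-loop-free `ppi_network` or edge data frame.
#' @param annotations A GO annotation tibble.
#' @param dag A `go_dag`.
#' @return A tibble `protein_a`, `protein_b`, `similarity`; the number of
#'   skipped edges is in attribute `n_skipped`.
#' @export
network_similarity_distribution <- function(network, annotations, dag) {
  network <- as_ppi_network(network)
  edges <- dplyr::filter(network$edges, !.data$self_loop)
  ann <- as_tibble(annotations)
  terms_of <- split(ann$term, ann$protein_id)
  idx <- wang_index(dag)
  cache <- new.env(parent = emptyenv())
  sim <- vapply(seq_len(nrow(edges)), function(e) {
    protein_similarity_worker(
      unique(terms_of[[edges$protein_a[e]]]),
      unique(terms_of[[edges$protein_b[e]]]),
      dag, idx, cache
    )
  }, numeric(1))
  out <- tibble(protein_a = edges$protein_a, protein_b = edges$protein_b,
                similarity = sim) |>
    dplyr::filter(!is.na(.data$similarity))
  attr(out, "n_skipped") <- nrow(edges) - nrow(out)
  out
}

#' Compare network GO similarity with degree-preserving random networks
#'
#' Pools the edge functional similarities of `n_random` degree-preserving
#' rewirings of the network into one null sample (`mode = "pooled"`, the
#' default; `mode = "per_network"` reduces each rewiring to its median) and
#' tests whether the network's edge similarities are stochastically greater
#' with the Wilcoxon rank-sum test.
#'
#' @param network A self-loop-free `ppi_network`.
#' @param annotations A GO annotation tibble.
#' @param dag A `go_dag`.
#' @param n_random Number of random networks (default 100).
#' @param seed Integer seed driving the rewirings; deterministic reports for
#'   a fixed seed.
#' @param mode `"pooled"` or `"per_network"`.
#' @return A `test_report` (one-row tibble: `statistic`, `p_value`,
#'   `alternative`, `n_x`, `n_y`, `method`) whose attributes `x_values` and
#'   `y_values` hold the network and null similarity samples.
#' @export
compare_with_random <- function(network, annotations, dag, n_random = 100,
                                seed = NULL, mode = c("pooled", "per_network")) {
  mode <- match.arg(mode)
  network <- as_ppi_network(network)
  ppi <- network_similarity_distribution(network, annotations, dag)
  if (!nrow(ppi)) abort("no edge with computable GO similarity")
  nulls <- random_edge_values(
    network, n_random, seed,
    function(net) network_similarity_distribution(net, annotations, dag)$similarity
  )
  report_against_null(ppi$similarity, nulls, mode,
                      method = "GO similarity vs degree-preserving null")
}

## Runs `value_fn` on n_random seeded rewirings; returns list of vectors.
random_edge_values <- function(network, n_random, seed, value_fn) {
  run <- function() {
    lapply(seq_len(n_random), function(r) {
      value_fn(rewire_preserving_degrees(network))
    })
  }
  if (is.null(seed)) run() else with_seed(seed, run)
}

report_against_null <- function(x, nulls, mode, method) {
  y <- if (mode == "pooled") {
    unlist(nulls)
  } else {
    vapply(nulls, median, numeric(1), na.rm = TRUE)
  }
  y <- y[!is.na(y)]
  if (!length(y)) abort("null sample is empty")
  rep <- wilcoxon_rank_sum(x, y, alternative = "greater")
  rep$method <- method
  attr(rep, "x_values") <- x
  attr(rep, "y_values") <- y
  rep
}

#' Transcription-correlation validation of a network
#'
#' Computes the Pearson correlation of the RPKM time profiles of every
#' interacting pair and compares the distribution against the pooled edge
#' correlations of `n_random` degree-preserving rewirings (Wilcoxon
#' rank-sum, alternative "greater"). Requires at least 3 time points; pairs
#' where either profile is missing or has zero variance are skipped.
#'
#' @param network A self-loop-free `ppi_network`.
#' @param expression An expression tibble from [read_expression_matrix()].
#' @inheritParams compare_with_random
#' @return A `test_report`; attributes `x_values`/`y_values` hold the edge
#'   correlation samples.
#' @export
transcription_pcc_validation <- function(network, expression, n_random = 100,
                                         seed = NULL,
                                         mode = c("pooled", "per_network")) {
  mode <- match.arg(mode)
  network <- as_ppi_network(network)
  labels <- expression_labels(expression)
  if (length(labels) < 3) {
    abort("need at least 3 time points for profile correlation")
  }
  profiles <- as.matrix(expression[, labels])
  rownames(profiles) <- expression$protein_id
  ppi <- edge_pcc(network, profiles)
  if (!length(ppi)) abort("no edge with computable correlation")
  nulls <- random_edge_values(network, n_random, seed,
                              function(net) edge_pcc(net, profiles))
  report_against_null(ppi, nulls, mode,
                      method = "transcription PCC vs degree-preserving null")
}

## Pearson correlations of edge endpoint profiles; NA pairs dropped.
edge_pcc <- function(network, profiles) {
  edges <- dplyr::filter(as_ppi_network(network)$edges, !.data$self_loop)
  known <- rownames(profiles)
  keep <- edges$protein_a %in% known & edges$protein_b %in% known
  edges <- edges[keep, ]
  if (!nrow(edges)) return(numeric())
  a <- profiles[edges$protein_a, , drop = FALSE]
  b <- profiles[edges$protein_b, , drop = FALSE]
  var_ok <- apply(a, 1, stats::sd) > 0 & apply(b, 1, stats::sd) > 0
  r <- rep(NA_real_, nrow(edges))
  for (e in which(var_ok)) r[e] <- cor(a[e, ], b[e, ])
  r[!is.na(r)]
}

#' Wilcoxon rank-sum test (tidy report)
#'
#' Two-sample rank-sum test with midrank ties. The exact null distribution
#' is used when both samples together have at most 12 observations and no
#' ties; otherwise the normal approximation with tie and continuity
#' correction is applied.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative `"two.sided"` (alias `"two-sided"`), `"greater"`, or
#'   `"less"` (with respect to `x`).
#' @return A `test_report`: one-row tibble `statistic` (the Mann-Whitney U
#'   of `x`), `p_value`, `alternative`, `n_x`, `n_y`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4), alternative = "less")$p_value  # 1/6
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two.sided", "greater",
                                              "less", "two-sided")) {
  alternative <- match.arg(alternative)
  if (alternative == "two-sided") alternative <- "two.sided"
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- !has_ties && (length(x) + length(y)) <= 12
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = exact,
                correct = TRUE)
  )
  p <- ht$p.value
  if (!is.finite(p)) p <- 1   # degenerate null variance (all values tied)
  new_test_report(
    statistic = unname(ht$statistic), p_value = p,
    alternative = alternative, n_x = length(x), n_y = length(y),
    method = if (exact) "Wilcoxon rank-sum (exact)"
             else "Wilcoxon rank-sum (normal approximation)"
  )
}

new_test_report <- function(statistic, p_value, alternative, n_x, n_y,
                            method) {
  out <- tibble(statistic = statistic, p_value = p_value,
                alternative = alternative, n_x = n_x, n_y = n_y,
                method = method)
  class(out) <- c("test_report", class(out))
  out
}

#' @param object A `test_report` with sample attributes.
#' @param ... Unused.
#' @rdname compare_with_random
#' @method autoplot test_report
#' @export
autoplot.test_report <- function(object, ...) {
  xv <- attr(object, "x_values")
  yv <- attr(object, "y_values")
  if (is.null(xv) || is.null(yv)) {
    abort("this report carries no sample distributions to plot")
  }
  df <- dplyr::bind_rows(
    tibble(source = "PPI network", value = xv),
    tibble(source = "random networks", value = yv)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$source)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(
      x = "edge value", y = "density",
      title = sprintf("%s (P = %.3g)", object$method[1], object$p_value[1])
    ) +
    ggplot2::theme_minimal()
}
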