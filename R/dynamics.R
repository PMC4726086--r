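## Condition-specific network dynamics: active subnetworks from RPKM
## profiles, normalized transcription differences of interacting pairs, and
## local-topology comparison across conditions.

#' Condition-specific active subnetwork
#'
#' Removes from the network every gene whose RPKM at the given time point is
#' below `threshold` (genes with no expression record count as below
#' threshold) together with its incident edges, returning the induced
#' subgraph on the active nodes.
#'
#' @param base A `ppi_network` or edge data frame.
#' @param expression An expression tibble from [read_expression_matrix()].
#' @param time_label One of the expression matrix's time labels.
#' @param threshold Minimum RPKM for a gene to stay in the network
#'   (default 1).
#' @return A `condition_network` (a `ppi_network` with fields `time_label`,
#'   `threshold` and `active_nodes`).
#' @export
active_subnetwork <- function(base, expression, time_label, threshold = 1) {
  base <- as_ppi_network(base)
  labels <- expression_labels(expression)
  if (!time_label %in% labels) {
    abort(sprintf("unknown time label '%s' (have: %s)", time_label,
                  paste(labels, collapse = ", ")))
  }
  rpkm <- setNames(expression[[time_label]], expression$protein_id)
  active <- base$nodes[!is.na(rpkm[base$nodes]) &
                         rpkm[base$nodes] >= threshold]
  edges <- dplyr::filter(base$edges,
                         .data$protein_a %in% active,
                         .data$protein_b %in% active)
  net <- ppi_network(edges, nodes = active)
  net$time_label <- time_label
  net$threshold <- threshold
  net$active_nodes <- active
  class(net) <- c("condition_network", class(net))
  net
}

#' @export
print.condition_network <- function(x, ...) {
  cat(sprintf("<condition_network> %s: %d active nodes, %d edges\n",
              x$time_label, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Normalized transcription difference
#'
#' `D_ij = |RPKM_i - RPKM_j| / (RPKM_i + RPKM_j)`: a scale-free dissimilarity
#' of two genes' transcription levels, 0 for identical levels and 1 when one
#' gene is silent. Vectorized; symmetric in its arguments and invariant
#' under joint rescaling (library-size invariance).
#'
#' @param rpkm_i,rpkm_j Non-negative RPKM values (not both zero).
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' normalized_difference(30, 10)  # 0.5
normalized_difference <- function(rpkm_i, rpkm_j) {
  if (any(rpkm_i < 0 | rpkm_j < 0)) abort("RPKM values must be non-negative")
  total <- rpkm_i + rpkm_j
  if (any(total == 0)) {
    abort("normalized difference undefined when both RPKM values are zero")
  }
  abs(rpkm_i - rpkm_j) / total
}

#' Normalized-difference distributions of protein-pair groups
#'
#' Computes the normalized transcription difference D over several groups of
#' protein pairs in a condition network: `"control"` (all unordered pairs of
#' active nodes, subsampled with a fixed seed when more than
#' `max_control_pairs`), `"all_ppi"` (all interacting pairs), and
#' `"category:X"` (interacting pairs whose two endpoints both carry COG
#' category X). Groups without any qualifying pair are reported empty.
#'
#' @param condition A `condition_network` from [active_subnetwork()].
#' @param expression The expression tibble used to build the condition.
#' @param annotations A COG annotation tibble (required for category
#'   groups).
#' @param groups Character vector of group names.
#' @param max_control_pairs Subsampling cap for the control group
#'   (default 1e6).
#' @param seed Seed for control-group subsampling (default 1).
#' @return A tibble `group`, `time_label`, `value`; group medians are in
#'   attribute `medians`, empty groups in attribute `empty_groups`.
#' @export
difference_distributions <- function(condition, expression,
                                     annotations = NULL,
                                     groups = c("control", "all_ppi"),
                                     max_control_pairs = 1e6, seed = 1) {
  if (!inherits(condition, "condition_network")) {
    abort("condition must come from active_subnetwork()")
  }
  rpkm <- setNames(expression[[condition$time_label]],
                   expression$protein_id)
  edges <- dplyr::filter(condition$edges, !.data$self_loop)
  d_of <- function(a, b) normalized_difference(rpkm[a], rpkm[b])
  one_group <- function(gr) {
    if (gr == "control") {
      nodes <- condition$nodes
      if (length(nodes) < 2) return(numeric())
      n_pairs <- length(nodes) * (length(nodes) - 1) / 2
      if (n_pairs > max_control_pairs) {
        pick <- with_seed(seed, function() {
          tibble(
            protein_a = sample(nodes, max_control_pairs, replace = TRUE),
            protein_b = sample(nodes, max_control_pairs, replace = TRUE)
          ) |>
            dplyr::filter(.data$protein_a != .data$protein_b)
        })
        d_of(pick$protein_a, pick$protein_b)
      } else {
        pairs <- combn(nodes, 2)
        d_of(pairs[1, ], pairs[2, ])
      }
    } else if (gr == "all_ppi") {
      if (!nrow(edges)) return(numeric())
      d_of(edges$protein_a, edges$protein_b)
    } else if (startsWith(gr, "category:")) {
      if (is.null(annotations)) {
        abort("category groups require COG annotations")
      }
      letter <- sub("^category:", "", gr)
      carriers <- unique(annotations$protein_id[
        annotations$category == letter])
      sub <- dplyr::filter(edges, .data$protein_a %in% carriers,
                           .data$protein_b %in% carriers)
      if (!nrow(sub)) return(numeric())
      d_of(sub$protein_a, sub$protein_b)
    } else {
      abort(sprintf("unknown group '%s'", gr))
    }
  }
  values <- lapply(groups, one_group)
  out <- purrr::map2_dfr(groups, values, function(gr, v) {
    if (!length(v)) return(NULL)
    tibble(group = gr, time_label = condition$time_label,
           value = unname(v))
  })
  if (is.null(out) || !nrow(out)) {
    out <- tibble(group = character(), time_label = character(),
                  value = numeric())
  }
  attr(out, "medians") <- out |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(median = median(.data$value), .groups = "drop")
  attr(out, "empty_groups") <- groups[lengths(values) == 0]
  out
}

#' Box plot of normalized-difference distributions
#'
#' @param distributions One or more [difference_distributions()] results,
#'   row-bound.
#' @return A ggplot.
#' @export
plot_difference_distributions <- function(distributions) {
  ggplot2::ggplot(distributions,
                  ggplot2::aes(x = .data$time_label, y = .data$value,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::labs(x = "time point", y = "normalized difference D",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Compare local topology metrics across conditions
#'
#' For every pair of condition networks and each of the five local topology
#' metrics (degree, clustering coefficient, average shortest-path length,
#' betweenness and closeness centrality), performs a two-sided Wilcoxon
#' rank-sum test over the node-level values. Conditions with fewer than 3
#' nodes are excluded with a warning.
#'
#' @param conditions A list of `condition_network`s (or `ppi_network`s);
#'   names are used as condition labels, else time labels.
#' @return A tibble `metric`, `condition_x`, `condition_y`, `statistic`,
#'   `p_value`, `n_x`, `n_y`.
#' @export
compare_local_topology <- function(conditions) {
  if (length(conditions) < 2) abort("need at least two conditions")
  labels <- names(conditions) %||%
    vapply(conditions, function(cn) cn$time_label %||% "?", character(1))
  if (is.null(names(conditions))) names(conditions) <- labels
  usable <- vapply(conditions, function(cn) length(cn$nodes) >= 3,
                   logical(1))
  if (any(!usable)) {
    warn(sprintf("excluding condition(s) with < 3 nodes: %s",
                 paste(labels[!usable], collapse = ", ")))
    conditions <- conditions[usable]
    labels <- labels[usable]
  }
  if (length(conditions) < 2) abort("fewer than two usable conditions")
  metrics <- c("degree", "clustering", "avg_shortest_path", "betweenness",
               "closeness")
  node_tables <- lapply(conditions, function(cn) tidy(topology_summary(cn)))
  pairs <- combn(seq_along(conditions), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]
    j <- pairs[2, k]
    purrr::map_dfr(metrics, function(mt) {
      x <- node_tables[[i]][[mt]]
      y <- node_tables[[j]][[mt]]
      x <- x[!is.na(x)]
      y <- y[!is.na(y)]
      rep <- wilcoxon_rank_sum(x, y, alternative = "two.sided")
      tibble(metric = mt, condition_x = labels[i], condition_y = labels[j],
             statistic = rep$statistic, p_value = rep$p_value,
             n_x = rep$n_x, n_y = rep$n_y)
    })
  })
}
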