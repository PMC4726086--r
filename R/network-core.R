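## Merging of evidence channels and topology characterization of the
## resulting PPI network.

#' Merge two prediction channels into one non-redundant network
#'
#' Takes the union of two canonical edge sets (typically the interolog and
#' DDI channels), merging evidence tags and sources per edge, and records
#' the channel overlap: the merged network carries a `merge_stats` attribute
#' with `n_a`, `n_b`, `n_shared` and `n_union` (where
#' `n_union = n_a + n_b - n_shared`).
#'
#' @param channel_a,channel_b Edge data frames (or `ppi_network`s).
#' @return A `ppi_network` containing the union of both channels.
#' @export
merge_networks <- function(channel_a, channel_b) {
  ea <- as_ppi_network(channel_a)$edges
  eb <- as_ppi_network(channel_b)$edges
  key <- function(e) paste(e$protein_a, e$protein_b, sep = "\r")
  shared <- length(intersect(key(ea), key(eb)))
  net <- ppi_network(dplyr::bind_rows(ea, eb))
  stats <- list(n_a = nrow(ea), n_b = nrow(eb), n_shared = shared,
                n_union = nrow(net$edges))
  stopifnot(stats$n_union == stats$n_a + stats$n_b - stats$n_shared)
  attr(net, "merge_stats") <- stats
  net
}

#' Remove homomeric interactions from a network
#'
#' Drops every self-loop (v, v); nodes left without any incident edge are
#' removed from the node set, since homomeric interactions bias the analysis
#' of relationships between distinct interacting proteins. The returned
#' network carries a `removal_stats` attribute with the number of edges and
#' nodes removed.
#'
#' @param network A `ppi_network` or edge data frame.
#' @return A self-loop-free `ppi_network`.
#' @export
remove_self_loops <- function(network) {
  network <- as_ppi_network(network)
  kept <- dplyr::filter(network$edges, !.data$self_loop)
  out <- ppi_network(kept)   # nodes: endpoints of surviving edges only
  attr(out, "removal_stats") <- list(
    n_self_loops_removed = sum(network$edges$self_loop),
    n_nodes_dropped = length(network$nodes) - length(out$nodes)
  )
  out
}

#' Topology summary of a PPI network
#'
#' Computes the network-level and per-node topology statistics used to
#' characterize the predicted network: degree, local clustering coefficient
#' (`2 * triangles / (deg * (deg - 1))`, zero below degree 2), average
#' shortest-path length over reachable nodes, betweenness centrality
#' normalized by `(n-1)(n-2)/2`, and closeness centrality
#' (`reachable / sum of distances`, the within-component convention).
#' Network-level values follow the conventions of the NetworkAnalyzer tool:
#' the average path length averages over connected ordered pairs only, and
#' the clustering coefficient averages local values over nodes of degree at
#' least 2 (set `include_degree_one = TRUE` to average over all nodes,
#' counting low-degree nodes as 0).
#'
#' @param network A self-loop-free `ppi_network` (run [remove_self_loops()]
#'   first; self-loops are an error here).
#' @param include_degree_one Include degree < 2 nodes (as 0) in the network
#'   clustering coefficient. Default `FALSE`.
#' @return A `ppi_topology` object; [glance()] returns the one-row network
#'   summary (`n_nodes`, `n_edges`, `average_degree`, `average_path_length`,
#'   `clustering_coefficient`, `n_components`, `largest_component_nodes`,
#'   `largest_component_edges`), [tidy()] the per-node metric tibble.
#' @export
topology_summary <- function(network, include_degree_one = FALSE) {
  network <- as_ppi_network(network)
  if (length(network$nodes) == 0L) abort("cannot summarise an empty network")
  if (any(network$edges$self_loop)) {
    abort("network contains self-loops; run remove_self_loops() first")
  }
  g <- to_igraph(network)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  d <- igraph::distances(g)
  diag(d) <- Inf                      # drop self-pairs
  reach <- rowSums(is.finite(d))
  sum_d <- ifelse(reach > 0, rowSums(ifelse(is.finite(d), d, 0)), NA_real_)
  per_node <- tibble(
    protein_id = igraph::V(g)$name,
    degree = as.integer(unname(deg)),
    clustering = unname(cc_local),
    avg_shortest_path = unname(ifelse(reach > 0, sum_d / reach, NA_real_)),
    betweenness = if (n > 2) unname(igraph::betweenness(g, normalized = TRUE))
                  else rep(0, n),
    closeness = unname(ifelse(reach > 0, reach / sum_d, 0))
  )
  comp <- igraph::components(g)
  giant <- which.max(comp$csize)
  giant_nodes <- igraph::V(g)$name[comp$membership == giant]
  giant_edges <- igraph::ecount(igraph::induced_subgraph(g, giant_nodes))
  cc_pool <- if (include_degree_one) cc_local else cc_local[deg >= 2]
  finite_d <- d[is.finite(d)]
  summary <- tibble(
    n_nodes = n,
    n_edges = m,
    average_degree = 2 * m / n,
    average_path_length = if (length(finite_d)) mean(finite_d) else NA_real_,
    clustering_coefficient = if (length(cc_pool)) mean(cc_pool) else NA_real_,
    n_components = comp$no,
    largest_component_nodes = max(comp$csize),
    largest_component_edges = giant_edges
  )
  structure(list(summary = summary, nodes = per_node),
            class = "ppi_topology")
}

#' @export
print.ppi_topology <- function(x, ...) {
  cat("<ppi_topology>\n")
  print(x$summary)
  invisible(x)
}

#' @method glance ppi_topology
#' @export
glance.ppi_topology <- function(x, ...) x$summary

#' @method tidy ppi_topology
#' @export
tidy.ppi_topology <- function(x, ...) x$nodes

#' @param object A `ppi_topology` object.
#' @param ... Unused.
#' @rdname topology_summary
#' @method autoplot ppi_topology
#' @export
autoplot.ppi_topology <- function(object, ...) {
  dist <- object$nodes |>
    dplyr::filter(.data$degree > 0) |>
    dplyr::count(.data$degree)
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "number of nodes",
                  title = "Degree distribution") +
    ggplot2::theme_minimal()
}

#' Maximum-likelihood power-law exponent of a degree sequence
#'
#' Estimates the degree exponent gamma of a scale-free network. The primary
#' estimate is the continuous-approximation MLE
#' `gamma = 1 + n / sum(log(k / k_min))` over the tail `k >= k_min`; the
#' discrete MLE, obtained by numerically maximizing the zeta-function
#' likelihood, is reported alongside.
#'
#' @param degrees Numeric vector of degrees (values below `k_min` are
#'   excluded from the tail).
#' @param k_min Lower cut-off of the power-law tail (default 1).
#' @return A `powerlaw_fit` object with fields `gamma` (continuous MLE),
#'   `gamma_discrete`, `k_min` and `n_tail`; [glance()] returns them as a
#'   one-row tibble.
#' @export
#' @examples
#' fit_powerlaw(c(1, 1, 1, 2, 4))$gamma  # 1 + 5 / (log 2 + log 4)
fit_powerlaw <- function(degrees, k_min = 1) {
  stopifnot(k_min >= 1)
  tail <- degrees[degrees >= k_min]
  if (length(tail) < 2 || length(unique(tail)) < 2) {
    abort("need at least two distinct degree values >= k_min")
  }
  log_sum <- sum(log(tail / k_min))
  if (log_sum <= 0) {
    abort("all tail degrees equal k_min; the MLE is undefined")
  }
  n <- length(tail)
  gamma_cont <- 1 + n / log_sum
  ## discrete MLE: maximize -n*log zeta(g, k_min) - g * sum(log k)
  sum_log_k <- sum(log(tail))
  nll <- function(g) n * log(hurwitz_zeta(g, k_min)) + g * sum_log_k
  gamma_disc <- optimise(nll, c(1 + 1e-6, 25))$minimum
  structure(
    list(gamma = gamma_cont, gamma_discrete = gamma_disc,
         k_min = k_min, n_tail = n, degrees = tail),
    class = "powerlaw_fit"
  )
}

## Hurwitz zeta(s, a) = sum_{k>=0} (a+k)^(-s), s > 1, by Euler-Maclaurin.
hurwitz_zeta <- function(s, a, terms = 25L) {
  k <- 0:(terms - 1L)
  x <- a + terms
  sum((a + k)^(-s)) +
    x^(1 - s) / (s - 1) +
    0.5 * x^(-s) +
    s * x^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * x^(-s - 3) / 720
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> gamma = %.3f (continuous MLE), %.3f (discrete MLE); k_min = %d, n_tail = %d\n",
    x$gamma, x$gamma_discrete, x$k_min, x$n_tail
  ))
  invisible(x)
}

#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(gamma = x$gamma, gamma_discrete = x$gamma_discrete,
         k_min = x$k_min, n_tail = x$n_tail)
}

#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("gamma", "gamma_discrete"),
    estimate = c(x$gamma, x$gamma_discrete)
  )
}

#' @param object A `powerlaw_fit` object.
#' @param ... Unused.
#' @rdname fit_powerlaw
#' @method autoplot powerlaw_fit
#' @export
autoplot.powerlaw_fit <- function(object, ...) {
  k <- sort(unique(object$degrees))
  ccdf <- vapply(k, function(x) mean(object$degrees >= x), numeric(1))
  df <- tibble(k = k, ccdf = ccdf)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$ccdf)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(
      data = tibble(k = k,
                    ccdf = (k / object$k_min)^(1 - object$gamma)),
      colour = "red", linetype = "dashed"
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K >= k)",
                  title = sprintf("Power-law fit, gamma = %.2f",
                                  object$gamma)) +
    ggplot2::theme_minimal()
}

#' Degree-preserving randomization of a network
#'
#' Randomizes a simple self-loop-free network by repeated double-edge swaps
#' (pick two edges, exchange their endpoints), rejecting swaps that would
#' create a self-loop or duplicate edge, so the degree sequence is exactly
#' preserved. This is the "random network with the same topology" null model
#' used in network validation. Deterministic for a fixed seed.
#'
#' @param network A self-loop-free `ppi_network` or edge data frame.
#' @param n_swaps Number of attempted swaps (default `10 * n_edges`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A rewired `ppi_network` with the same node set and degree
#'   sequence (edge evidence metadata is not carried over).
#' @export
rewire_preserving_degrees <- function(network, n_swaps = NULL, seed = NULL) {
  network <- as_ppi_network(network)
  if (any(network$edges$self_loop)) {
    abort("rewiring requires a self-loop-free network")
  }
  if (nrow(network$edges) < 2) {
    warn("fewer than 2 edges; returning the network unchanged")
    return(network)
  }
  n_swaps <- n_swaps %||% (10L * nrow(network$edges))
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_rng(old), add = TRUE)
    set.seed(seed)
  }
  g <- igraph::rewire(to_igraph(network),
                      igraph::keeping_degseq(loops = FALSE,
                                             niter = n_swaps))
  as_ppi_network(g)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

## Evaluate fn() under a temporary seed without disturbing the caller's RNG.
with_seed <- function(seed, fn) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  fn()
}
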