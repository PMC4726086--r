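## Protein-complex detection on time-series active subnetworks: a fully
## specified greedy density clustering standing in for the TSN-PCD
## algorithm of the complex-detection literature (same interface — PPIs +
## expression in, parameters: RPKM threshold, lambda, minimum size), with
## functional-category entropy scoring.

#' Build the time-series active subnetworks
#'
#' One [active_subnetwork()] per time label of the expression matrix, in
#' label order.
#'
#' @param base A `ppi_network` or edge data frame.
#' @param expression An expression tibble.
#' @param threshold Minimum RPKM (default 1).
#' @return A named list of `condition_network`s.
#' @export
build_time_series_networks <- function(base, expression, threshold = 1) {
  labels <- expression_labels(expression)
  if (!length(labels)) abort("expression matrix has no time points")
  setNames(
    lapply(labels, function(lb) {
      active_subnetwork(base, expression, lb, threshold)
    }),
    labels
  )
}

#' Detect protein complexes by greedy density clustering
#'
#' A deterministic stand-in for time-series complex detection. Within each
#' time-series subnetwork: (1) the unassigned node of highest degree (ties:
#' lexicographically smaller id) seeds a cluster; (2) the unassigned
#' neighbor `u` of the cluster `C` with the most links into `C` (ties:
#' lexicographic) is added as long as `links(u, C) >= lambda * |C| / 2`;
#' (3) the cluster closes when no candidate qualifies; (4) clusters below
#' `min_size` are dropped. Across time points, clusters with overlap score
#' `|A intersect B|^2 / (|A| * |B|) >= merge_overlap` are merged (union) and
#' reported once, provided the union still induces a connected subgraph in
#' at least one time-series subnetwork — every reported complex satisfies
#' that connectivity invariant.
#'
#' @param tsn A non-empty list of `condition_network`s, as from
#'   [build_time_series_networks()].
#' @param lambda Density acceptance parameter (default 1): a candidate must
#'   bring at least `lambda * |C| / 2` links into the cluster.
#' @param min_size Minimum complex size (default 3).
#' @param merge_overlap Cross-time merge threshold on the overlap score
#'   (default 0.8).
#' @return A `complex_set`: tibble `complex_id`, `members` (list column),
#'   `size`, `time_labels`, plus the parameter record.
#' @export
detect_complexes <- function(tsn, lambda = 1, min_size = 3,
                             merge_overlap = 0.8) {
  if (!length(tsn)) abort("tsn must contain at least one subnetwork")
  clusters <- list()
  provenance <- character()
  for (lb in names(tsn)) {
    found <- greedy_density_clusters(tsn[[lb]], lambda, min_size)
    clusters <- c(clusters, found)
    provenance <- c(provenance, rep(lb, length(found)))
  }
  provenance <- as.list(provenance)
  ## cross-time merging: union clusters with high overlap, keeping the
  ## connectivity invariant (union connected in >= 1 subnetwork)
  merged <- TRUE
  while (merged && length(clusters) > 1) {
    merged <- FALSE
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        a <- clusters[[i]]
        b <- clusters[[j]]
        ov <- length(intersect(a, b))^2 / (length(a) * length(b))
        if (ov >= merge_overlap) {
          u <- sort(union(a, b))
          if (connected_in_any(u, tsn)) {
            clusters[[i]] <- u
            provenance[[i]] <- sort(unique(c(provenance[[i]],
                                             provenance[[j]])))
            clusters[[j]] <- NULL
            provenance[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
      }
      if (merged) break
    }
  }
  ## drop exact duplicates surviving under the overlap threshold
  keys <- vapply(clusters, paste, character(1), collapse = "\r")
  keep <- !duplicated(keys)
  clusters <- clusters[keep]
  provenance <- provenance[keep]
  ord <- order(vapply(clusters, `[`, character(1), 1))
  clusters <- clusters[ord]
  provenance <- provenance[ord]
  out <- tibble(
    complex_id = sprintf("complex_%03d", seq_along(clusters)),
    members = clusters,
    size = lengths(clusters),
    time_labels = vapply(provenance, paste, character(1), collapse = ",")
  )
  structure(
    list(
      complexes = out,
      parameters = list(lambda = lambda, min_size = min_size,
                        merge_overlap = merge_overlap)
    ),
    class = "complex_set"
  )
}

## Greedy density clustering of one subnetwork; returns sorted member sets.
greedy_density_clusters <- function(network, lambda, min_size) {
  network <- as_ppi_network(network)
  nodes <- network$nodes
  if (!length(nodes)) return(list())
  g <- to_igraph(network)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, function(vs) igraph::V(g)$name[vs])
  names(adj) <- igraph::V(g)$name
  deg <- lengths(adj)
  unassigned <- nodes
  found <- list()
  while (length(unassigned)) {
    ## seed: highest degree, ties lexicographic (nodes are sorted)
    seed <- unassigned[order(-deg[unassigned], unassigned)][1]
    cluster <- seed
    unassigned <- setdiff(unassigned, seed)
    repeat {
      neighbors <- unique(unlist(adj[cluster], use.names = FALSE))
      candidates <- intersect(neighbors, unassigned)
      if (!length(candidates)) break
      links <- vapply(candidates,
                      function(u) length(intersect(adj[[u]], cluster)),
                      integer(1))
      best <- candidates[order(-links, candidates)][1]
      if (links[[which(candidates == best)]] < lambda * length(cluster) / 2) {
        break
      }
      cluster <- c(cluster, best)
      unassigned <- setdiff(unassigned, best)
    }
    if (length(cluster) >= min_size) {
      found <- c(found, list(sort(cluster)))
    }
  }
  found
}

## TRUE iff `members` induce a connected subgraph in >= 1 subnetwork.
connected_in_any <- function(members, tsn) {
  for (net in tsn) {
    if (!all(members %in% net$nodes)) next
    sub <- igraph::induced_subgraph(to_igraph(net), members)
    if (igraph::components(sub)$no == 1L) return(TRUE)
  }
  FALSE
}

#' @export
print.complex_set <- function(x, ...) {
  cat(sprintf(
    "<complex_set> %d complexes (lambda = %g, min size = %d); sizes %s\n",
    nrow(x$complexes), x$parameters$lambda, x$parameters$min_size,
    if (nrow(x$complexes)) paste0(min(x$complexes$size), "-",
                                  max(x$complexes$size))
    else "-"
  ))
  invisible(x)
}

#' @method tidy complex_set
#' @export
tidy.complex_set <- function(x, ...) {
  tidyr::unnest(
    dplyr::select(x$complexes, "complex_id", "members"),
    "members"
  ) |>
    dplyr::rename(protein_id = "members")
}

#' @method glance complex_set
#' @export
glance.complex_set <- function(x, ...) {
  tibble(n_complexes = nrow(x$complexes),
         median_size = if (nrow(x$complexes)) median(x$complexes$size)
                       else NA_real_)
}

#' Score complexes by functional-category entropy
#'
#' Computes [functional_entropy()] for every complex; lower entropy means a
#' functionally more homogeneous complex. Complexes whose members are all
#' unannotated get entropy 0 over the single pseudo-category `"unknown"`
#' and are flagged.
#'
#' @param complex_set A `complex_set` from [detect_complexes()].
#' @param annotations A COG annotation tibble.
#' @param low_entropy_cutoff Entropy (bits) below which a complex counts as
#'   functionally homogeneous in the summary (default 1).
#' @return A tibble `complex_id`, `size`, `entropy`, `all_unknown`; the
#'   fraction of low-entropy complexes is in attribute
#'   `low_entropy_fraction`.
#' @export
score_complexes <- function(complex_set, annotations,
                            low_entropy_cutoff = 1) {
  members_list <- complex_members(complex_set)
  out <- purrr::imap_dfr(members_list, function(members, id) {
    ent <- functional_entropy(members, annotations)
    tibble(complex_id = as.character(id), size = ent$n,
           entropy = ent$entropy, all_unknown = ent$all_unknown)
  })
  if (is.null(out) || !nrow(out)) {
    out <- tibble(complex_id = character(), size = integer(),
                  entropy = numeric(), all_unknown = logical())
  }
  attr(out, "low_entropy_fraction") <-
    if (nrow(out)) mean(out$entropy < low_entropy_cutoff) else NA_real_
  out
}
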