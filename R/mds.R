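## Minimum dominating set (MDS) of the PPI network: the smallest node set
## such that every protein is in the set or adjacent to a member — a proxy
## for network controllability. Domination is closed-neighborhood (every
## node dominates itself), so the defining integer program
## x_v + sum_{u in N(v)} x_u >= 1 is satisfiable on isolated nodes.

## Closed neighborhoods as a list of integer index vectors.
closed_neighborhoods <- function(network) {
  network <- as_ppi_network(network)
  nodes <- network$nodes
  idx <- setNames(seq_along(nodes), nodes)
  nb <- vector("list", length(nodes))
  for (v in seq_along(nodes)) nb[[v]] <- v
  e <- dplyr::filter(network$edges, !.data$self_loop)
  ia <- idx[e$protein_a]
  ib <- idx[e$protein_b]
  for (k in seq_along(ia)) {
    nb[[ia[k]]] <- c(nb[[ia[k]]], ib[k])
    nb[[ib[k]]] <- c(nb[[ib[k]]], ia[k])
  }
  list(nodes = nodes, nb = lapply(nb, function(x) sort(unique(x))))
}

new_mds_result <- function(members, method, optimal, network) {
  members <- sort(unique(members))
  if (!verify_dominating(network, members)) {
    abort("internal error: computed set is not dominating")   # nocov
  }
  structure(
    list(members = members, size = length(members), method = method,
         optimal = optimal),
    class = "mds_result"
  )
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> size %d (%s%s)\n", x$size, x$method,
              if (x$optimal) ", provably optimal" else ""))
  invisible(x)
}

#' @method glance mds_result
#' @export
glance.mds_result <- function(x, ...) {
  tibble(size = x$size, method = x$method, optimal = x$optimal)
}

#' @method tidy mds_result
#' @export
tidy.mds_result <- function(x, ...) tibble(protein_id = x$members)

#' Check that a node set dominates a network
#'
#' @param network A `ppi_network` or edge data frame.
#' @param members Character vector of node ids (must all be network nodes).
#' @return `TRUE` iff every node is a member or adjacent to a member.
#' @export
verify_dominating <- function(network, members) {
  network <- as_ppi_network(network)
  unknown <- setdiff(members, network$nodes)
  if (length(unknown)) {
    abort(sprintf("unknown node id(s) in members: %s",
                  paste(head(unknown, 3), collapse = ", ")))
  }
  cn <- closed_neighborhoods(network)
  dominated <- logical(length(cn$nodes))
  for (v in which(cn$nodes %in% members)) dominated[cn$nb[[v]]] <- TRUE
  all(dominated)
}

#' Exact minimum dominating set by integer programming
#'
#' Solves the dominating-set integer program (minimize `sum x_v` subject to
#' `x_v + sum_{u in N(v)} x_u >= 1` for every node, `x` binary) exactly, by
#' implicit branch-and-bound: branch on the closed neighborhood of the
#' currently hardest-to-dominate node, bound with a greedy incumbent and the
#' covering lower bound `ceil(undominated / max coverage)`. The returned set
#' is provably optimal unless the time limit is hit, in which case the best
#' incumbent is returned with `optimal = FALSE`.
#'
#' @param network A self-loop-free `ppi_network` or edge data frame
#'   (self-loop edges are ignored for domination).
#' @param time_limit Wall-clock budget in seconds (default `Inf`).
#' @return An `mds_result` with fields `members`, `size`, `method = "ilp"`,
#'   `optimal`.
#' @export
solve_mds_ilp <- function(network, time_limit = Inf) {
  network <- as_ppi_network(network)
  cn <- closed_neighborhoods(network)
  n <- length(cn$nodes)
  if (n == 0L) return(new_mds_result(character(), "ilp", TRUE, network))
  sol <- mds_branch_bound(cn$nb, as.numeric(time_limit))
  new_mds_result(cn$nodes[sol$members], "ilp", sol$optimal, network)
}

## Greedy cover on index neighborhoods; returns chosen indices.
greedy_cover_indices <- function(nb, n) {
  dominated <- logical(n)
  degree <- lengths(nb)
  chosen <- integer()
  while (!all(dominated)) {
    gain <- vapply(seq_len(n), function(u) sum(!dominated[nb[[u]]]),
                   integer(1))
    ## max new coverage; ties by higher degree, then smaller index
    best <- order(-gain, -degree, seq_len(n))[1]
    chosen <- c(chosen, best)
    dominated[nb[[best]]] <- TRUE
  }
  chosen
}

#' Greedy dominating set
#'
#' Classic greedy baseline: repeatedly pick the node covering the most
#' currently undominated nodes (ties broken by higher degree, then
#' lexicographically smaller id). The result is verified dominating but is
#' not guaranteed minimum.
#'
#' @inheritParams solve_mds_ilp
#' @return An `mds_result` with `method = "greedy"`, `optimal = FALSE`.
#' @export
greedy_mds <- function(network) {
  network <- as_ppi_network(network)
  cn <- closed_neighborhoods(network)
  n <- length(cn$nodes)
  if (n == 0L) {
    res <- new_mds_result(character(), "greedy", FALSE, network)
    return(res)
  }
  ## node order is lexicographic, so the index tie-break is lexicographic
  chosen <- greedy_cover_indices(cn$nb, n)
  new_mds_result(cn$nodes[chosen], "greedy", FALSE, network)
}

#' Exhaustive minimum dominating set (test oracle)
#'
#' Enumerates node subsets in increasing size (lexicographic order within a
#' size, so the reported optimum is the lexicographically first) and returns
#' the smallest dominating set. Only feasible for small graphs; refuses
#' networks above `max_nodes`.
#'
#' @inheritParams solve_mds_ilp
#' @param max_nodes Refusal threshold (default 20).
#' @return An `mds_result` with `method = "exhaustive"`, `optimal = TRUE`.
#' @export
solve_mds_exhaustive <- function(network, max_nodes = 20) {
  network <- as_ppi_network(network)
  cn <- closed_neighborhoods(network)
  n <- length(cn$nodes)
  if (n > max_nodes) {
    abort(sprintf("exhaustive search refused: %d nodes > max_nodes = %d",
                  n, max_nodes))
  }
  if (n == 0L) return(new_mds_result(character(), "exhaustive", TRUE, network))
  masks <- vapply(cn$nb, function(ix) sum(bitwShiftL(1L, ix - 1L)),
                  integer(1))
  full <- sum(bitwShiftL(1L, seq_len(n) - 1L))
  for (k in seq_len(n)) {
    sets <- combn(n, k)
    for (j in seq_len(ncol(sets))) {
      covered <- 0L
      for (v in sets[, j]) covered <- bitwOr(covered, masks[v])
      if (covered == full) {
        return(new_mds_result(cn$nodes[sets[, j]], "exhaustive", TRUE,
                              network))
      }
    }
  }
  new_mds_result(cn$nodes, "exhaustive", TRUE, network)   # nocov
}
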