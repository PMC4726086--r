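#' Canonicalize an interaction edge table
#'
#' Puts every unordered protein pair into canonical order (`protein_a` is the
#' lexicographically smaller identifier), merges duplicate pairs by taking the
#' union of their evidence tags and provenance sources, and flags self-loops.
#' Every function in the package that consumes edges canonicalizes first, so
#' `(A, B)` and `(B, A)` always denote the same interaction.
#'
#' @param edges A data frame with character columns `protein_a` and
#'   `protein_b`, and optionally `evidence` (comma-joined tags such as
#'   `"interolog"` or `"ddi"`) and `sources` (semicolon-joined provenance
#'   strings).
#' @return A tibble with columns `protein_a`, `protein_b`, `evidence`,
#'   `sources`, `self_loop`, one row per unordered pair, sorted by pair.
#' @export
#' @examples
#' canonical_edges(data.frame(protein_a = c("B", "A"), protein_b = c("A", "B")))
canonical_edges <- function(edges) {
  edges <- as_tibble(edges)
  if (!all(c("protein_a", "protein_b") %in% names(edges))) {
    abort("edge table must have columns 'protein_a' and 'protein_b'")
  }
  a <- as.character(edges$protein_a)
  b <- as.character(edges$protein_b)
  if (any(!nzchar(a)) || any(!nzchar(b))) {
    abort("edge table contains an empty protein identifier")
  }
  swap <- a > b
  lo <- ifelse(swap, b, a)
  hi <- ifelse(swap, a, b)
  ev <- if ("evidence" %in% names(edges)) as.character(edges$evidence) else ""
  ev[is.na(ev)] <- ""
  src <- if ("sources" %in% names(edges)) as.character(edges$sources) else ""
  src[is.na(src)] <- ""
  tibble(protein_a = lo, protein_b = hi, evidence = ev, sources = src) |>
    dplyr::group_by(.data$protein_a, .data$protein_b) |>
    dplyr::summarise(
      evidence = join_tags(.data$evidence, ","),
      sources = join_tags(.data$sources, ";"),
      .groups = "drop"
    ) |>
    dplyr::mutate(self_loop = .data$protein_a == .data$protein_b) |>
    dplyr::arrange(.data$protein_a, .data$protein_b)
}

## Union of delimiter-joined tag strings, sorted, empties dropped.
join_tags <- function(x, sep) {
  tags <- unique(unlist(strsplit(x[nzchar(x)], sep, fixed = TRUE)))
  paste(sort(tags), collapse = sep)
}

#' Construct a PPI network
#'
#' A `ppi_network` is an undirected simple graph over protein identifiers:
#' a canonical edge tibble (see [canonical_edges()]) plus the node set, which
#' may include isolated proteins beyond the edge endpoints.
#'
#' @param edges A data frame of interactions (canonicalized on construction),
#'   or `NULL` for an edgeless network.
#' @param nodes Optional character vector of node identifiers; the union of
#'   edge endpoints is always included.
#' @return A `ppi_network` object with fields `edges` (tibble) and `nodes`
#'   (character).
#' @export
#' @examples
#' net <- ppi_network(data.frame(protein_a = "A", protein_b = "B"))
#' net$nodes
ppi_network <- function(edges = NULL, nodes = NULL) {
  edges <- if (is.null(edges) || nrow(as_tibble(edges)) == 0L) {
    tibble(
      protein_a = character(), protein_b = character(),
      evidence = character(), sources = character(), self_loop = logical()
    )
  } else {
    canonical_edges(edges)
  }
  nodes <- sort(unique(c(as.character(nodes %||% character()),
                         edges$protein_a, edges$protein_b)))
  structure(list(edges = edges, nodes = nodes), class = "ppi_network")
}

#' Coerce to a PPI network
#'
#' @param x A `ppi_network`, an edge data frame, or an igraph object.
#' @param ... Unused.
#' @return A `ppi_network`.
#' @export
as_ppi_network <- function(x, ...) UseMethod("as_ppi_network")

#' @export
as_ppi_network.ppi_network <- function(x, ...) x

#' @export
as_ppi_network.data.frame <- function(x, ...) ppi_network(x)

#' @export
as_ppi_network.igraph <- function(x, ...) {
  el <- igraph::as_edgelist(x, names = TRUE)
  ppi_network(
    tibble(protein_a = el[, 1], protein_b = el[, 2]),
    nodes = igraph::V(x)$name
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "<ppi_network> %d nodes, %d edges (%d self-loops)\n",
    length(x$nodes), nrow(x$edges), sum(x$edges$self_loop)
  ))
  ms <- attr(x, "merge_stats")
  if (!is.null(ms)) {
    cat(sprintf(
      "  merged channels: |A| = %d, |B| = %d, shared = %d, union = %d\n",
      ms$n_a, ms$n_b, ms$n_shared, ms$n_union
    ))
  }
  invisible(x)
}

#' @method tidy ppi_network
#' @export
tidy.ppi_network <- function(x, ...) x$edges

#' @method glance ppi_network
#' @export
glance.ppi_network <- function(x, ...) {
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_self_loops = sum(x$edges$self_loop)
  )
}

## igraph view of a network (named vertices, simple undirected graph).
to_igraph <- function(net) {
  net <- as_ppi_network(net)
  igraph::graph_from_data_frame(
    net$edges[, c("protein_a", "protein_b")],
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
}
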