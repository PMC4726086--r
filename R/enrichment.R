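## COG-based enrichment statistics: pairwise category heat map under a
## binomial null, Fisher's exact category enrichment, functional-category
## entropy of complexes, and module-assisted annotation of uncharacterized
## proteins.

## Category sets per protein, restricted to `proteins`, COG-alphabet order.
cog_sets <- function(annotations, proteins) {
  ann <- as_tibble(annotations) |>
    dplyr::filter(.data$protein_id %in% proteins)
  split(ann$category, factor(ann$protein_id, levels = unique(ann$protein_id)))
}

#' COG-pair interaction heat map with Z-scores
#'
#' Counts the interactions observed between every pair of COG functional
#' classes and compares them with a randomized-network null. With `n`
#' annotated proteins in the network and `f_i` of them in class `i`, the
#' probability that a random interaction joins classes `i` and `j` is
#' `P_ij = f_i * f_j / T` for `i != j` and `f_i * (f_i - 1) / 2 / T` for
#' `i = j`, where `T = n * (n - 1) / 2` is the number of protein pairs.
#' Among `N` observed interactions between annotated proteins, the class-pair
#' count `A_ij` is then binomial with mean `N * P_ij` and variance
#' `N * P_ij * (1 - P_ij)`, giving
#' `Z_ij = (A_ij - N * P_ij) / sqrt(N * P_ij * (1 - P_ij))`.
#'
#' Multi-label proteins contribute to every category combination of an edge;
#' each unordered combination is counted once per edge. Only proteins with at
#' least one COG category participate; `P_ij` values of 0 or 1 leave `Z`
#' undefined (`NA`), never infinite.
#'
#' @param network A self-loop-free `ppi_network` or edge data frame.
#' @param annotations A COG annotation tibble (`protein_id`, `category`,
#'   `priority`), as from [read_cog_annotations()].
#' @return A `cog_heatmap` object with matrices `observed` (A), `expected`
#'   (N*P) and `z`, the category vector, and the counts `n` (annotated
#'   proteins) and `n_interactions` (N). [tidy()] returns the long form;
#'   [autoplot()] draws the Z-score heat map.
#' @export
cog_heatmap <- function(network, annotations) {
  network <- as_ppi_network(network)
  if (any(network$edges$self_loop)) {
    abort("heat map requires a self-loop-free network")
  }
  ann <- as_tibble(annotations) |>
    dplyr::filter(.data$protein_id %in% network$nodes)
  annotated <- unique(ann$protein_id)
  n <- length(annotated)
  if (n < 2) abort("need at least two COG-annotated proteins in the network")
  cats <- .cog_letters[.cog_letters %in% unique(ann$category)]
  sets <- split(ann$category, ann$protein_id)
  edges <- dplyr::filter(network$edges,
                         .data$protein_a %in% annotated,
                         .data$protein_b %in% annotated)
  N <- nrow(edges)
  k <- length(cats)
  A <- matrix(0, k, k, dimnames = list(cats, cats))
  for (e in seq_len(N)) {
    ca <- sets[[edges$protein_a[e]]]
    cb <- sets[[edges$protein_b[e]]]
    combos <- unique(tibble(
      i = pmin(rep(ca, each = length(cb)), rep(cb, times = length(ca))),
      j = pmax(rep(ca, each = length(cb)), rep(cb, times = length(ca)))
    ))
    for (r in seq_len(nrow(combos))) {
      A[combos$i[r], combos$j[r]] <- A[combos$i[r], combos$j[r]] + 1
    }
  }
  ## each unordered combo was recorded in one cell; mirror it
  diag_a <- diag(A)
  A <- A + t(A)
  diag(A) <- diag_a
  f <- vapply(cats, function(cc) sum(vapply(sets, function(s) cc %in% s,
                                            logical(1))),
              numeric(1))
  T_pairs <- n * (n - 1) / 2
  P <- outer(f, f) / T_pairs
  diag(P) <- f * (f - 1) / 2 / T_pairs
  expected <- N * P
  z <- matrix(NA_real_, k, k, dimnames = list(cats, cats))
  ok <- P > 0 & P < 1
  z[ok] <- (A[ok] - expected[ok]) / sqrt(N * P[ok] * (1 - P[ok]))
  structure(
    list(categories = cats, observed = A, expected = expected, z = z,
         n = n, n_interactions = N),
    class = "cog_heatmap"
  )
}

#' @export
print.cog_heatmap <- function(x, ...) {
  cat(sprintf(
    "<cog_heatmap> %d categories, %d annotated proteins, %d interactions\n",
    length(x$categories), x$n, x$n_interactions
  ))
  invisible(x)
}

#' @method tidy cog_heatmap
#' @export
tidy.cog_heatmap <- function(x, ...) {
  expand.grid(category_i = x$categories, category_j = x$categories,
              stringsAsFactors = FALSE) |>
    as_tibble() |>
    dplyr::mutate(
      observed = as.vector(x$observed),
      expected = as.vector(x$expected),
      z = as.vector(x$z)
    )
}

#' @method glance cog_heatmap
#' @export
glance.cog_heatmap <- function(x, ...) {
  tibble(n_categories = length(x$categories), n_annotated = x$n,
         n_interactions = x$n_interactions)
}

#' @param object A `cog_heatmap` object.
#' @param ... Unused.
#' @rdname cog_heatmap
#' @method autoplot cog_heatmap
#' @export
autoplot.cog_heatmap <- function(object, ...) {
  df <- tidy(object)
  df$category_i <- factor(df$category_i, levels = object$categories)
  df$category_j <- factor(df$category_j, levels = rev(object$categories))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category_i,
                                   y = .data$category_j,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Z",
                  title = "COG-pair interaction enrichment") +
    ggplot2::theme_minimal()
}

#' Fisher's exact COG enrichment of a protein set
#'
#' One-sided (enrichment direction) Fisher's exact test per COG category,
#' comparing the category's frequency in `member_set` with the rest of the
#' background. Raw P-values drive the `enriched` flag (at `alpha`);
#' Benjamini-Hochberg adjusted P-values are reported alongside.
#'
#' @param member_set Character vector of proteins (subset of `background`).
#' @param background Character vector of background proteins.
#' @param annotations A COG annotation tibble.
#' @param alpha Significance level for the `enriched` flag (default 0.05).
#' @return A tibble `category`, `in_set`, `set_size`, `in_background`,
#'   `bg_size`, `p_value`, `p_adjust`, `enriched`, one row per category
#'   present in the background.
#' @export
fisher_enrichment <- function(member_set, background, annotations,
                              alpha = 0.05) {
  member_set <- unique(member_set)
  background <- unique(background)
  if (!length(member_set)) abort("member_set is empty")
  if (!all(member_set %in% background)) {
    abort("member_set must be a subset of background")
  }
  ann <- as_tibble(annotations) |>
    dplyr::filter(.data$protein_id %in% background) |>
    dplyr::distinct(.data$protein_id, .data$category)
  cats <- .cog_letters[.cog_letters %in% unique(ann$category)]
  n_set <- length(member_set)
  n_bg <- length(background)
  rows <- purrr::map_dfr(cats, function(cc) {
    with_cat <- ann$protein_id[ann$category == cc]
    a <- sum(member_set %in% with_cat)
    K <- length(with_cat)
    tab <- matrix(c(a, n_set - a, K - a, n_bg - n_set - (K - a)), 2, 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(category = cc, in_set = a, set_size = n_set,
           in_background = K, bg_size = n_bg, p_value = p)
  })
  rows |>
    dplyr::mutate(
      p_adjust = p.adjust(.data$p_value, method = "BH"),
      enriched = .data$p_value < alpha
    )
}

#' Functional-category entropy of a protein complex
#'
#' Shannon entropy (bits) of the COG category composition of a complex:
#' with `n_i` members of which `F_ij` carry primary category `j`,
#' `entropy = -sum_j (F_ij / n_i) * log2(F_ij / n_i)`. Each member
#' contributes exactly its primary (first-listed) category, or `"unknown"`
#' when unannotated, so the counts sum to the member count. Lower entropy
#' means greater functional homogeneity; 0 means all members share one
#' category.
#'
#' @param members Non-empty character vector of complex members.
#' @param annotations A COG annotation tibble.
#' @return A `complex_entropy` object with fields `n` (member count),
#'   `counts` (tibble `category`, `count`) and `entropy` (bits).
#' @export
#' @examples
#' ann <- tibble::tibble(protein_id = c("a", "b", "c", "d"),
#'                       category = c("J", "J", "K", "K"), priority = 1L)
#' functional_entropy(c("a", "b", "c", "d"), ann)$entropy  # 1 bit
functional_entropy <- function(members, annotations) {
  members <- unique(members)
  if (!length(members)) abort("members is empty")
  primary <- as_tibble(annotations) |>
    dplyr::filter(.data$priority == 1L) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE)
  cat_of <- setNames(primary$category, primary$protein_id)
  labels <- unname(cat_of[members])
  labels[is.na(labels)] <- "unknown"
  counts <- tibble(category = labels) |>
    dplyr::count(.data$category, name = "count") |>
    dplyr::arrange(.data$category)
  p <- counts$count / length(members)
  structure(
    list(n = length(members), counts = counts,
         entropy = -sum(p * log2(p)),
         all_unknown = all(labels == "unknown")),
    class = "complex_entropy"
  )
}

#' @export
print.complex_entropy <- function(x, ...) {
  cat(sprintf("<complex_entropy> %d members, entropy %.3f bits%s\n",
              x$n, x$entropy,
              if (x$all_unknown) " (all members unannotated)" else ""))
  invisible(x)
}

#' Annotate uncharacterized proteins from enriched complexes
#'
#' For each complex, the COG categories enriched by [fisher_enrichment()]
#' (raw P below `alpha`) are assigned to member proteins whose own COG
#' annotation is absent or uninformative (only S, "function unknown", or R,
#' "general function prediction only"). Within a complex the category with
#' the smallest P wins; a protein belonging to several enriched complexes
#' receives the assignment with the smallest P overall. Proteins in no
#' enriched complex stay unannotated.
#'
#' @param complexes A list of member character vectors, or a `complex_set`
#'   from [detect_complexes()].
#' @param annotations A COG annotation tibble.
#' @param background Character vector of background proteins for the
#'   enrichment test (e.g. all network nodes).
#' @param alpha Raw-P significance level (default 0.05).
#' @return A tibble `protein_id`, `category`, `p_value`, `complex_id` with
#'   one row per newly annotated protein.
#' @export
annotate_uncharacterized <- function(complexes, annotations, background,
                                     alpha = 0.05) {
  members_list <- complex_members(complexes)
  ann <- as_tibble(annotations)
  informative <- ann |>
    dplyr::filter(!.data$category %in% c("S", "R")) |>
    dplyr::pull("protein_id") |>
    unique()
  out <- purrr::imap_dfr(members_list, function(members, i) {
    members <- intersect(members, background)
    if (length(members) < 1) return(NULL)
    enr <- fisher_enrichment(members, background, ann, alpha = alpha) |>
      dplyr::filter(.data$enriched) |>
      dplyr::arrange(.data$p_value)
    if (!nrow(enr)) return(NULL)
    targets <- setdiff(members, informative)
    if (!length(targets)) return(NULL)
    tibble(protein_id = targets, category = enr$category[1],
           p_value = enr$p_value[1], complex_id = as.character(i))
  })
  if (!nrow(out)) {
    return(tibble(protein_id = character(), category = character(),
                  p_value = numeric(), complex_id = character()))
  }
  out |>
    dplyr::arrange(.data$p_value) |>
    dplyr::distinct(.data$protein_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$protein_id)
}

## Normalize the various complex containers to a list of member vectors.
complex_members <- function(complexes) {
  if (inherits(complexes, "complex_set")) {
    out <- complexes$complexes$members
    names(out) <- complexes$complexes$complex_id
    out
  } else if (is.data.frame(complexes)) {
    out <- complexes$members
    names(out) <- complexes$complex_id
    out
  } else {
    complexes
  }
}
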